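# Glycosite-restricted peptide search space: FASTA in, tryptic candidates
# with sequons, static modifications and pseudo-reverse decoys out.

#' Read a protein FASTA file
#'
#' Accepts UniProt-style headers (`>sp|P12345|NAME ...`, the accession is the
#' second pipe field) and plain identifiers.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `protein_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers found in ", path, call. = FALSE)
  idx <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1), 1)
  piped <- grepl("\\|", ids)
  ids[piped] <- vapply(strsplit(ids[piped], "|", fixed = TRUE), function(x) {
    if (length(x) >= 2) x[[2]] else x[[1]]
  }, character(1))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0, character(1), collapse = "")
  tibble::tibble(protein_id = ids, sequence = toupper(unname(seqs)))
}

write_fasta <- function(proteins, path) {
  lines <- unlist(purrr::map2(proteins$protein_id, proteins$sequence, function(id, s) {
    c(paste0(">", id), substring(s, seq(1, nchar(s), 60),
                                 pmin(seq(60, nchar(s) + 59, 60), nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Tryptic digestion of a protein
#'
#' Cleaves C-terminal to K or R except when the next residue is P, emitting
#' every product with 0 to `max_missed` missed cleavages. Coordinates are
#' 1-based inclusive protein positions.
#'
#' @param sequence Protein sequence (20 amino-acid alphabet).
#' @param max_missed Maximum missed cleavages (default 2).
#' @param min_length,max_length Peptide length bounds applied to the output.
#' @return Tibble with columns `sequence`, `start`, `end`, `missed_cleavages`.
#' @examples
#' digest_protein("AKRPCK")
#' @export
digest_protein <- function(sequence, max_missed = 2L, min_length = 1L,
                           max_length = Inf) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(AA_RESIDUE_MASS))
  if (length(bad) > 0) {
    stop("non-amino-acid character ", sQuote(chars[bad[1]]),
         " at position ", bad[1], call. = FALSE)
  }
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | chars[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  bounds <- unique(bounds)
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    for (m in 0:max_missed) {
      j <- i + 1L + m
      if (j > length(bounds)) break
      s <- bounds[i] + 1L
      e <- bounds[j]
      len <- e - s + 1L
      if (len < min_length || len > max_length) next
      out[[length(out) + 1L]] <- tibble::tibble(
        sequence = paste0(chars[s:e], collapse = ""),
        start = s, end = e, missed_cleavages = m
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Find N-glycosylation sequons
#'
#' Returns protein-coordinate positions of every N in an N-X-S/T motif
#' (X any residue except proline) within the peptide. When `protein_context`
#' is supplied, motifs whose X/S-T positions extend past the peptide
#' C-terminus are resolved against the full protein sequence.
#'
#' @param peptide Peptide sequence.
#' @param protein_offset 1-based position of the peptide's first residue in
#'   the protein.
#' @param protein_context Optional full protein sequence.
#' @return Integer vector of protein positions (empty if none).
#' @examples
#' find_sequons("ITDIENGSLANIPR")
#' @export
find_sequons <- function(peptide, protein_offset = 1L, protein_context = NULL) {
  stopifnot(nchar(peptide) > 0)
  window <- peptide
  if (!is.null(protein_context)) {
    ext_end <- min(nchar(protein_context), protein_offset + nchar(peptide) + 1L)
    window <- substr(protein_context, protein_offset, ext_end)
  }
  hits <- stringr::str_locate_all(window, "(?=N[^P](S|T))")[[1]]
  pos <- hits[, 1]
  pos <- pos[pos <= nchar(peptide)]  # the N itself must lie in the peptide
  as.integer(pos + protein_offset - 1L)
}

#' Neutral peptide mass with modifications
#'
#' Residue masses plus water plus modification deltas. In TMT mode the
#' N-terminal tag (+229.162932 Da) is always applied and, by default, every
#' lysine also carries a tag; carbamidomethylation (+57.021464 Da) is applied
#' on every cysteine.
#'
#' @param sequence Peptide sequence.
#' @param tmt Apply the TMT N-terminal label (default TRUE).
#' @param tmt_k Label lysines with TMT (default TRUE).
#' @param carbamidomethyl Apply static carbamidomethylation on C (default TRUE).
#' @param variable_mods Named counts of additional modifications drawn from
#'   `"oxidation"` and `"acetyl"`.
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_neutral_mass <- function(sequence, tmt = TRUE, tmt_k = TRUE,
                                 carbamidomethyl = TRUE, variable_mods = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(AA_RESIDUE_MASS))
  if (length(bad) > 0) {
    stop("non-amino-acid character ", sQuote(chars[bad[1]]),
         " at position ", bad[1], call. = FALSE)
  }
  mass <- sum(AA_RESIDUE_MASS[chars]) + WATER_MASS
  if (carbamidomethyl) mass <- mass + sum(chars == "C") * MOD_MASS[["carbamidomethyl"]]
  if (tmt) mass <- mass + MOD_MASS[["tmt10"]]
  if (tmt && tmt_k) mass <- mass + sum(chars == "K") * MOD_MASS[["tmt10"]]
  if (!is.null(variable_mods)) {
    unknown <- setdiff(names(variable_mods), names(MOD_MASS))
    if (length(unknown) > 0) {
      stop("unknown modification ", sQuote(unknown[1]), call. = FALSE)
    }
    mass <- mass + sum(unlist(variable_mods) * MOD_MASS[names(variable_mods)])
  }
  unname(mass)
}

#' Pseudo-reverse decoy peptides
#'
#' Reverses each target sequence while keeping the C-terminal residue fixed,
#' preserving tryptic mass and charge properties. Because reversal destroys
#' N-X-S/T motifs, a sequon-bearing target's decoy stays in the glycopeptide
#' search space with nominal attachment sites at its N residues (the glycan
#' attachment position does not affect the precursor or fragment masses
#' being competed); this keeps the target and decoy glycopeptide spaces the
#' same size, which an unbiased target-decoy competition requires.
#'
#' @param candidates Tibble of target candidates (as from
#'   [build_peptide_index()]); must be non-empty.
#' @return Tibble of the same shape, flagged `is_decoy = TRUE`.
#' @export
make_decoys <- function(candidates) {
  if (nrow(candidates) == 0) stop("no target candidates to reverse", call. = FALSE)
  rev_keep_cterm <- function(s) {
    n <- nchar(s)
    if (n <= 2) return(s)
    paste0(paste(rev(strsplit(substr(s, 1, n - 1), "")[[1]]), collapse = ""),
           substr(s, n, n))
  }
  dec <- candidates
  dec$sequence <- vapply(candidates$sequence, rev_keep_cterm, character(1),
                         USE.NAMES = FALSE)
  if ("sequon_positions" %in% names(dec)) {
    had_sequon <- lengths(candidates$sequon_positions) > 0
    dec$sequon_positions <- purrr::pmap(
      list(dec$sequence, dec$start, had_sequon), function(s, st, keep) {
        if (!keep) return(integer(0))
        n_pos <- stringr::str_locate_all(s, "N")[[1]][, 1]
        if (length(n_pos) == 0) return(st)  # nominal site at peptide start
        as.integer(n_pos + st - 1L)
      })
  }
  dec$is_decoy <- TRUE
  dec
}

#' Build the glycopeptide search index from a protein table
#'
#' Digests every protein, keeps peptides within the length and mass bounds,
#' computes neutral masses (TMT + carbamidomethylation statics), records
#' sequon positions, and appends pseudo-reverse decoys. Candidates without a
#' sequon form the global-proteome space (`has_sequon = FALSE`); glycopeptide
#' searches use the sequon-bearing subset.
#'
#' @param proteins Tibble with `protein_id`, `sequence` (as from [read_fasta()]).
#' @param max_missed Missed-cleavage cap (default 2).
#' @param min_length,max_length Peptide length bounds (defaults 6 and 45).
#' @param min_mass,max_mass Neutral mass bounds in Da (defaults 600 and 6000).
#' @param decoys Append pseudo-reverse decoys (default TRUE).
#' @return Tibble with columns `protein_id`, `sequence`, `start`, `end`,
#'   `missed_cleavages`, `sequon_positions` (list), `has_sequon`,
#'   `neutral_mass`, `is_decoy`.
#' @export
build_peptide_index <- function(proteins, max_missed = 2L, min_length = 6L,
                                max_length = 45L, min_mass = 600,
                                max_mass = 6000, decoys = TRUE) {
  idx <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    pep <- digest_protein(proteins$sequence[i], max_missed = max_missed,
                          min_length = min_length, max_length = max_length)
    if (nrow(pep) == 0) return(pep)
    pep$protein_id <- proteins$protein_id[i]
    pep$sequon_positions <- purrr::map2(pep$sequence, pep$start, function(s, st) {
      find_sequons(s, protein_offset = st, protein_context = proteins$sequence[i])
    })
    pep
  })
  if (nrow(idx) == 0) stop("digestion produced no candidates", call. = FALSE)
  idx$neutral_mass <- vapply(idx$sequence, peptide_neutral_mass, numeric(1),
                             USE.NAMES = FALSE)
  idx <- idx[idx$neutral_mass >= min_mass & idx$neutral_mass <= max_mass, ]
  idx$has_sequon <- lengths(idx$sequon_positions) > 0
  idx$is_decoy <- FALSE
  idx <- dplyr::distinct(idx, .data$protein_id, .data$sequence, .data$start,
                         .keep_all = TRUE)
  if (decoys) {
    dec <- make_decoys(idx)
    dec$neutral_mass <- vapply(dec$sequence, peptide_neutral_mass, numeric(1),
                               USE.NAMES = FALSE)
    dec$has_sequon <- lengths(dec$sequon_positions) > 0
    dec$protein_id <- paste0("DECOY_", dec$protein_id)
    idx <- dplyr::bind_rows(idx, dec)
  }
  dplyr::arrange(tibble::as_tibble(idx), .data$neutral_mass)
}
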