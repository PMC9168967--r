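# Intact glycopeptide identification from dual-energy spectrum pairs.
# High-energy scan -> peptide (b/y ions, hypergeometric-tail score);
# low-energy scan -> glycan core and branches (Y/B ions, intensity-weighted
# coverage score with diagnostic-ion gating); assembly under the 10 ppm
# precursor mass constraint; target-decoy FDR independently at the peptide
# and glycan levels.

#' Identification settings
#'
#' @param precursor_tol_ppm Precursor tolerance (default 10).
#' @param fragment_tol_ppm Fragment tolerance (default 20).
#' @param oxonium_min_matches,oxonium_top_n Oxonium screen settings.
#' @param diagnostic_bonus Glycan score bonus per branch whose intact
#'   decorated oxonium ion is matched (default 0.1).
#' @param decoy_shift Mass shift (Da) applied per branch motif to build decoy
#'   glycan hypotheses (default 17.0027).
#' @param max_structures Cap on structures scored per composition.
#' @return List of settings.
#' @export
ident_config <- function(precursor_tol_ppm = 10, fragment_tol_ppm = 20,
                         oxonium_min_matches = 2L, oxonium_top_n = 10L,
                         diagnostic_bonus = 0.1, decoy_shift = 17.0027,
                         max_structures = 200L) {
  as.list(environment())
}

# Sorted residue masses of every glycan composition containing the plain
# core (within the default count caps); used to prefilter peptide candidates
# to those whose precursor-minus-peptide remainder is explainable.
glycan_mass_table <- function() {
  if (!is.null(.glyco_cache[["gmass"]])) return(.glyco_cache[["gmass"]])
  m <- MONOSACCHARIDE_MASS
  grid <- expand.grid(n = 2:8, h = 3:12, f = 0:3, s = 0:3)
  masses <- sort(unique(grid$n * m[["HexNAc"]] + grid$h * m[["Hex"]] +
                          grid$f * m[["Fuc"]] + grid$s * m[["NeuAc"]]))
  .glyco_cache[["gmass"]] <- masses
  masses
}

# TRUE for each value of `x` lying within tol_da of some entry of the sorted
# vector `table`.
near_any <- function(x, table, tol_da) {
  if (length(x) == 0) return(logical(0))
  lo <- findInterval(x, table)
  hi <- pmin(lo + 1L, length(table))
  lo <- pmax(lo, 1L)
  pmin(abs(table[lo] - x), abs(table[hi] - x)) <= tol_da
}

# Theoretical singly charged b/y ions for a TMT-labeled peptide (statics:
# TMT N-terminus and K, carbamidomethyl C). Cached per sequence.
peptide_fragment_mz <- function(sequence) {
  key <- paste0("pepfrag:", sequence)
  if (!is.null(.glyco_cache[[key]])) return(.glyco_cache[[key]])
  chars <- strsplit(sequence, "")[[1]]
  res <- AA_RESIDUE_MASS[chars]
  res <- res + ifelse(chars == "C", MOD_MASS[["carbamidomethyl"]], 0) +
    ifelse(chars == "K", MOD_MASS[["tmt10"]], 0)
  n <- length(res)
  out <- list(
    b = cumsum(res)[-n] + MOD_MASS[["tmt10"]] + PROTON_MASS,
    y = rev(cumsum(rev(res)))[-1] + WATER_MASS + PROTON_MASS
  )
  .glyco_cache[[key]] <- out
  out
}

# -log10 hypergeometric tail probability of observing >= k matches when
# n_theo theoretical ions are drawn against n_obs observed peaks spread over
# n_bins resolvable m/z bins.
hypergeom_score <- function(k, n_theo, n_obs, n_bins) {
  if (k <= 0) return(0)
  p <- stats::phyper(k - 1, n_obs, max(n_bins - n_obs, 1), n_theo,
                     lower.tail = FALSE)
  -log10(max(p, 1e-300))
}

#' Match peptide candidates against a high-energy scan
#'
#' Scores each candidate by its matched b/y ion count using a
#' hypergeometric-tail probability (surrogate for proprietary search-engine
#' scores), and ranks descending. Ties are broken by smaller precursor error,
#' then lexicographic sequence, so results are deterministic.
#'
#' @param high_peaks Peak tibble of the high-energy scan.
#' @param candidates Peptide candidate tibble (rows of a
#'   [build_peptide_index()]).
#' @param precursor_neutral_mass Precursor neutral mass in Da.
#' @param config An [ident_config()].
#' @return Candidate tibble with `n_matched`, `peptide_score`,
#'   `precursor_error_ppm`, sorted best first (zero rows when no candidate
#'   matches any ion).
#' @export
match_peptide <- function(high_peaks, candidates, precursor_neutral_mass,
                          config = ident_config()) {
  if (nrow(candidates) == 0) return(candidates)
  obs <- high_peaks$mz
  rng <- range(obs)
  n_bins <- max(1000, round((rng[2] - rng[1]) / 0.02))
  scored <- candidates
  scored$n_matched <- vapply(candidates$sequence, function(s) {
    frag <- peptide_fragment_mz(s)
    theo <- c(frag$b, frag$y)
    sum(!is.na(match_peaks(obs, theo, config$fragment_tol_ppm)))
  }, integer(1))
  scored$peptide_score <- vapply(seq_len(nrow(scored)), function(i) {
    frag <- peptide_fragment_mz(scored$sequence[i])
    hypergeom_score(scored$n_matched[i], length(frag$b) + length(frag$y),
                    nrow(high_peaks), n_bins)
  }, numeric(1))
  scored$precursor_error_ppm <- NA_real_
  scored <- scored[scored$n_matched > 0, ]
  scored[order(-scored$peptide_score, scored$sequence), ]
}

#' Infer the core motif from low-energy Y ions
#'
#' Tests the core Y-ion ladder (peptide / +HexNAc / +HexNAc2 / +Hex1..3)
#' against the low-energy scan. Core fucose is called when a Fuc-shifted
#' ladder ion is matched — unique evidence, since no branch motif
#' contributes a bare Fuc. A matched bisect-shifted ion (trimannosyl core
#' plus HexNAc, composition N3H3) is reported as `bisect_candidate` only:
#' a GlcNAc antenna stub produces exactly the same Y composition, so the
#' plain-vs-bisecting reading is resolved later, during full-structure
#' assembly, by the package's parsimony convention. The returned `kind` is
#' therefore always `plain` or `core_fucosylated`.
#'
#' @param low_peaks Peak tibble of the low-energy scan.
#' @param peptide_mass Neutral peptide mass (from the peptide match).
#' @param charges Y-ion charges tested (default 1:2).
#' @param config An [ident_config()].
#' @return List with `kind`, `bisect_candidate`, `n_matched`, `evidence`
#'   (matched Y tibble); errors if not even the bare core ladder is found.
#' @export
infer_core <- function(low_peaks, peptide_mass, charges = 1:2,
                       config = ident_config()) {
  obs <- sort(low_peaks$mz)
  ladder_for <- function(kind) {
    s <- glycan_structure(kind, character())
    y <- theoretical_y_ions(s, peptide_mass, charges)
    y$matched <- !is.na(match_peaks(obs, y$mz, config$fragment_tol_ppm))
    y
  }
  plain <- ladder_for("plain")
  if (!any(plain$matched)) {
    stop("no core Y-ion ladder found; glycan unidentifiable", call. = FALSE)
  }
  fuc <- ladder_for("core_fucosylated")
  fuc_ok <- any(fuc$matched & grepl("F1", fuc$composition))
  bis <- ladder_for(if (fuc_ok) "fucosylated_bisecting" else "bisecting")
  bis_candidate <- any(bis$matched & grepl("^N3H3", bis$composition))
  kind <- if (fuc_ok) "core_fucosylated" else "plain"
  y <- if (fuc_ok) fuc else plain
  list(kind = kind, bisect_candidate = bis_candidate,
       n_matched = sum(y$matched), evidence = y[y$matched, ])
}

# Diagnostic B-ion gating masks for a structure: every LacdiNAc-family
# branch needs a matched HexNAc2-containing B ion (HexNAc >= 2, Hex == 0);
# every LacNAc-family branch needs a matched HexNAc1Hex1-containing ion.
diagnostic_gate <- function(structure, matched_b_comps, library) {
  fams <- purrr::map_chr(structure$branches, ~ lib_row(library, .x)$family)
  if (length(fams) == 0) return(list(ok = TRUE, confirmed = 0L))
  comps <- purrr::map(matched_b_comps, parse_composition)
  has_lac2 <- any(purrr::map_lgl(comps, ~ .x[["HexNAc"]] >= 2 && .x[["Hex"]] == 0))
  has_lacnac <- any(purrr::map_lgl(comps, ~ .x[["HexNAc"]] >= 1 && .x[["Hex"]] >= 1))
  ok <- TRUE
  if (any(fams == "LacdiNAc") && !has_lac2) ok <- FALSE
  if (any(fams == "LacNAc") && !has_lacnac) ok <- FALSE
  list(ok = ok, confirmed = sum(
    (fams == "LacdiNAc") * has_lac2 + (fams == "LacNAc") * has_lacnac +
      (!fams %in% c("LacdiNAc", "LacNAc"))
  ))
}

# Score one structure (target or +decoy_shift-per-branch decoy hypothesis)
# against a low-energy scan.
score_structure <- function(structure, low_peaks, peptide_mass, charges,
                            library, config, decoy = FALSE) {
  if (is.unsorted(low_peaks$mz)) {
    low_peaks <- low_peaks[order(low_peaks$mz), ]
  }
  b <- theoretical_b_ions(structure, library)
  ycomp <- structure_y_compositions(structure, library)
  shift <- if (decoy) config$decoy_shift else 0
  b_mz <- b$mz + shift
  obs <- low_peaks$mz
  b_hit <- match_peaks(obs, b_mz, config$fragment_tol_ppm)
  y_hit_idx <- integer(0)
  n_y_theo <- 0L
  n_y_match <- 0L
  for (z in charges) {
    y_mz <- (peptide_mass + ycomp$glycan_mass +
               ifelse(ycomp$glycan_mass > 0, shift, 0) + z * PROTON_MASS) / z
    hit <- match_peaks(obs, y_mz, config$fragment_tol_ppm)
    n_y_theo <- n_y_theo + length(y_mz)
    n_y_match <- n_y_match + sum(!is.na(hit))
    y_hit_idx <- c(y_hit_idx, hit[!is.na(hit)])
  }
  matched_idx <- unique(c(b_hit[!is.na(b_hit)], y_hit_idx))
  frac_theo <- (sum(!is.na(b_hit)) + n_y_match) / (length(b_mz) + n_y_theo)
  frac_int <- sum(low_peaks$intensity[matched_idx]) / sum(low_peaks$intensity)
  gate <- diagnostic_gate(structure, b$composition[!is.na(b_hit)], library)
  # intact decorated oxonium per branch for the diagnostic bonus; only
  # multi-residue oxonium ions count (single residues are produced by the
  # core of every glycan and carry no branch information)
  n_diag <- 0L
  for (br in structure$branches) {
    row <- lib_row(library, br)
    residues <- c(row$chain[[1]], row$decorations[[1]])
    if (length(residues) < 2) next
    mz <- oxonium_mz(comp_from_residues(residues)) + shift
    if (!is.na(match_peaks(obs, mz, config$fragment_tol_ppm))) n_diag <- n_diag + 1L
  }
  list(
    score = if (!gate$ok) -Inf else
      0.5 * frac_theo + 0.5 * frac_int + config$diagnostic_bonus * n_diag,
    n_b_matched = sum(!is.na(b_hit)), n_y_matched = n_y_match,
    matched_b = b$composition[!is.na(b_hit)],
    gate_ok = gate$ok, n_diagnostic = n_diag
  )
}

#' Infer branch multisets from the low-energy scan
#'
#' Enumerates branch multisets from the library whose summed composition
#' equals the residual (precursor glycan composition minus core), scores each
#' by matched B-ion coverage, and applies the diagnostic gating: a LacdiNAc
#' motif may appear in an accepted multiset only when a HexNAc2-containing B
#' ion is matched; a LacNAc motif requires a HexNAc1Hex1-containing ion.
#'
#' @param low_peaks Peak tibble of the low-energy scan.
#' @param residual A [glycan_comp()] (precursor composition minus core),
#'   or its string form.
#' @param library Branch library.
#' @param config An [ident_config()].
#' @return Tibble with `branches` (list), `score`, `gate_ok`, best first.
#'   Zero rows when the residual is not expressible in the library.
#' @export
infer_branches <- function(low_peaks, residual, library = default_branch_library(),
                           config = ident_config()) {
  if (is.character(residual)) residual <- parse_composition(residual)
  # reuse the structure enumerator with a bare plain core then strip it
  probe <- comp_add(residual, parse_composition("N2H3"))
  structs <- enumerate_structures(probe, library)
  structs <- purrr::keep(structs, ~ .x$core == "plain")
  if (length(structs) == 0) {
    return(tibble::tibble(branches = list(), score = numeric(), gate_ok = logical()))
  }
  obs <- sort(low_peaks$mz)
  rows <- purrr::map_dfr(structs, function(s) {
    b <- theoretical_b_ions(s, library)
    hit <- match_peaks(obs, b$mz, config$fragment_tol_ppm)
    gate <- diagnostic_gate(s, b$composition[!is.na(hit)], library)
    tibble::tibble(branches = list(s$branches),
                   score = sum(!is.na(hit)) / nrow(b),
                   gate_ok = gate$ok)
  })
  rows <- rows[rows$gate_ok, ]
  rows[order(-rows$score, purrr::map_chr(rows$branches, paste, collapse = ",")), ]
}

#' Assemble and score the glycan for one spectrum pair
#'
#' Given the winning peptide, decomposes the precursor-minus-peptide mass
#' remainder into candidate glycan compositions, enumerates all structures
#' for each, scores target and mass-shifted decoy hypotheses against the
#' low-energy scan, and returns the best assembly. The glycan score is an
#' intensity-weighted matched-ion fraction plus a diagnostic-ion bonus per
#' confirmed branch; structures failing diagnostic gating are rejected
#' outright.
#'
#' @param low_peaks Peak tibble of the low-energy scan.
#' @param peptide_mass Neutral mass of the matched peptide.
#' @param precursor_neutral_mass Precursor neutral mass.
#' @param precursor_charge Precursor charge (bounds Y-ion charges).
#' @param library Branch library.
#' @param config An [ident_config()].
#' @return One-row tibble with structure, scores and evidence, or zero rows
#'   when no composition within tolerance is expressible.
#' @export
assemble_and_score <- function(low_peaks, peptide_mass, precursor_neutral_mass,
                               precursor_charge = 3L,
                               library = default_branch_library(),
                               config = ident_config()) {
  remainder <- precursor_neutral_mass - peptide_mass
  empty <- tibble::tibble()
  if (remainder <= 0) return(empty)
  tol_ppm_eff <- config$precursor_tol_ppm * precursor_neutral_mass / remainder
  comps <- find_compositions(remainder, tol_ppm = tol_ppm_eff)
  comps <- comps[vapply(comps$composition, function(cc) {
    v <- parse_composition(cc); v[["HexNAc"]] >= 2 && v[["Hex"]] >= 3
  }, logical(1)), , drop = FALSE]
  if (nrow(comps) == 0) return(empty)
  charges <- 1:min(2L, precursor_charge)
  best <- NULL
  # deterministic tie-break for score-equal (hence ion-indistinguishable)
  # assemblies, e.g. bisecting GlcNAc vs a bare GlcNAc antenna: fewer
  # branches first (reads an unassignable core-proximal HexNAc as
  # bisecting), then the simpler core, then library order (motifs are listed
  # in decreasing prior plausibility), then canonical text
  priority_key <- function(s) {
    idx <- sort(match(s$branches, library$name))
    sprintf("%02d|%d|%s|%s", length(idx), match(s$core, core_motifs()$kind),
            paste(sprintf("%02d", idx), collapse = ","), s$canonical)
  }
  consider <- function(cand) {
    sc <- cand$sc
    if (is.infinite(sc$score)) return(invisible())
    if (is.null(best) || sc$score > best$sc$score ||
        (sc$score == best$sc$score && !cand$decoy && best$decoy) ||
        (sc$score == best$sc$score && cand$decoy == best$decoy &&
           priority_key(cand$structure) < priority_key(best$structure))) {
      best <<- cand
    }
    invisible()
  }
  for (cc in comps$composition) {
    structs <- enumerate_structures(cc, library)
    if (length(structs) > config$max_structures) {
      structs <- structs[seq_len(config$max_structures)]
    }
    target_scores <- numeric(length(structs))
    for (si in seq_along(structs)) {
      sc <- score_structure(structs[[si]], low_peaks, peptide_mass, charges,
                            library, config, decoy = FALSE)
      target_scores[si] <- sc$score
      consider(list(structure = structs[[si]], composition = cc,
                    decoy = FALSE, sc = sc))
    }
    # decoy hypotheses compete only against the leading target assemblies
    ord <- order(-target_scores)
    decoy_si <- utils::head(ord[is.finite(target_scores[ord])], 3L)
    if (length(decoy_si) == 0) decoy_si <- utils::head(ord, 10L)
    for (si in decoy_si) {
      sc <- score_structure(structs[[si]], low_peaks, peptide_mass, charges,
                            library, config, decoy = TRUE)
      consider(list(structure = structs[[si]], composition = cc,
                    decoy = TRUE, sc = sc))
    }
  }
  if (is.null(best)) return(empty)
  tibble::tibble(
    glycan_structure = best$structure$canonical,
    glycan_composition = best$composition,
    glycan_score = best$sc$score,
    glycan_decoy = best$decoy,
    n_b_matched = best$sc$n_b_matched,
    n_y_matched = best$sc$n_y_matched,
    n_diagnostic = best$sc$n_diagnostic,
    matched_b = list(best$sc$matched_b)
  )
}

#' Identify glycopeptides in a paired dual-energy run
#'
#' Runs the full engine over every spectrum pair: oxonium screen, peptide
#' matching against the sequon-bearing index (targets and decoys compete),
#' glycan assembly and scoring, reporter extraction. One PSM per pair.
#'
#' @param pairs Pair tibble from [pair_spectra()].
#' @param index Peptide index from [build_peptide_index()].
#' @param library Branch library.
#' @param config An [ident_config()].
#' @param progress Print a progress message every 200 pairs.
#' @return PSM tibble; one row per identified pair with peptide, site,
#'   structure, scores, decoy flags, evidence counts and reporter channels.
#' @export
identify_pairs <- function(pairs, index, library = default_branch_library(),
                           config = ident_config(), progress = FALSE) {
  glyco_idx <- index[index$has_sequon, ]
  idx_mass <- glyco_idx$neutral_mass
  min_glycan <- composition_mass(parse_composition("N2H3"))
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (progress && i %% 200L == 0L) message("pair ", i, "/", nrow(pairs))
    low <- pairs$low_peaks[[i]]
    high <- pairs$high_peaks[[i]]
    if (!oxonium_screen(low, config$oxonium_min_matches,
                        config$oxonium_top_n)$pass) next
    neutral <- pairs$precursor_neutral_mass[i]
    tol_da <- neutral * config$precursor_tol_ppm * 1e-6
    remainder <- neutral - idx_mass
    cand <- glyco_idx[remainder >= min_glycan - tol_da &
                        near_any(remainder, glycan_mass_table(), tol_da), ]
    if (nrow(cand) == 0) next
    ranked <- match_peptide(high, cand, neutral, config)
    hit <- NULL
    for (r in seq_len(min(nrow(ranked), 5L))) {
      g <- assemble_and_score(low, ranked$neutral_mass[r], neutral,
                              pairs$precursor_charge[i], library, config)
      if (nrow(g) > 0) {
        hit <- dplyr::bind_cols(ranked[r, ], g)
        break
      }
    }
    if (is.null(hit)) next
    reporters <- extract_reporters(high)
    site <- hit$sequon_positions[[1]]
    out[[i]] <- tibble::tibble(
      pair_id = pairs$pair_id[i],
      low_scan = pairs$low_scan[i], high_scan = pairs$high_scan[i],
      protein_id = hit$protein_id, peptide = hit$sequence,
      site = site[1], site_ambiguous = length(site) > 1,
      peptide_score = hit$peptide_score,
      peptide_decoy = hit$is_decoy,
      glycan_structure = hit$glycan_structure,
      glycan_composition = hit$glycan_composition,
      glycan_score = hit$glycan_score, glycan_decoy = hit$glycan_decoy,
      n_b_matched = hit$n_b_matched, n_y_matched = hit$n_y_matched,
      n_diagnostic = hit$n_diagnostic,
      matched_b = hit$matched_b,
      precursor_error_ppm = (hit$neutral_mass +
        composition_mass(parse_composition(hit$glycan_composition)) - neutral) /
        neutral * 1e6,
      `129C` = reporters[["129C"]], `130C` = reporters[["130C"]],
      `130N` = reporters[["130N"]], `131` = reporters[["131"]]
    )
  }
  dplyr::bind_rows(out)
}

#' Target-decoy FDR filtering
#'
#' Estimates the score threshold at which the decoy-based FDR estimate
#' (#decoys above threshold / #targets above threshold) first drops to
#' `alpha`, independently per level. The accepted set contains targets at or
#' above the threshold.
#'
#' @param psms PSM tibble from [identify_pairs()].
#' @param level `"peptide"` or `"glycan"` (chooses score and decoy columns).
#' @param alpha FDR level (default 0.01).
#' @return An `fdr_result` list: `level`, `alpha`, `threshold`,
#'   `estimated_fdr`, `n_accepted`, `accepted` (tibble of passing targets).
#' @export
fdr_filter <- function(psms, level = c("peptide", "glycan"), alpha = 0.01) {
  level <- match.arg(level)
  score <- psms[[paste0(level, "_score")]]
  decoy <- psms[[paste0(level, "_decoy")]]
  if (!any(decoy)) stop("no ", level, "-level decoys present; FDR not estimable",
                        call. = FALSE)
  cuts <- sort(unique(score))
  fdr_at <- vapply(cuts, function(s) {
    sum(decoy & score >= s) / max(1, sum(!decoy & score >= s))
  }, numeric(1))
  ok <- which(fdr_at <= alpha)
  if (length(ok) == 0) {
    threshold <- Inf
  } else {
    threshold <- cuts[min(ok)]
  }
  accepted <- psms[!decoy & score >= threshold, , drop = FALSE]
  est <- if (is.infinite(threshold)) NA_real_ else
    sum(decoy & score >= threshold) / max(1, nrow(accepted))
  structure(list(level = level, alpha = alpha, threshold = threshold,
                 estimated_fdr = est, n_accepted = nrow(accepted),
                 accepted = accepted),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("<fdr_result> level=", x$level, " alpha=", x$alpha,
      " threshold=", signif(x$threshold, 4),
      " accepted=", x$n_accepted,
      " est. FDR=", signif(x$estimated_fdr, 3), "\n", sep = "")
  invisible(x)
}

#' Apply dual-level FDR filtering
#'
#' Filters PSMs at `alpha` independently at the peptide and the glycan level
#' and returns the targets passing both, plus the two `fdr_result` objects.
#'
#' @inheritParams fdr_filter
#' @return List with `accepted` (tibble), `peptide` and `glycan`
#'   (`fdr_result`s).
#' @export
apply_dual_fdr <- function(psms, alpha = 0.01) {
  filter_or_pass <- function(level) {
    tryCatch(fdr_filter(psms, level, alpha), error = function(e) {
      # a level with zero decoy wins has an FDR estimate of 0 at any cutoff
      message("no ", level, "-level decoys; accepting all targets at this level")
      structure(list(level = level, alpha = alpha, threshold = -Inf,
                     estimated_fdr = 0, n_accepted = NA_integer_,
                     accepted = NULL),
                class = "fdr_result")
    })
  }
  pep <- filter_or_pass("peptide")
  gly <- filter_or_pass("glycan")
  keep <- !psms$peptide_decoy & !psms$glycan_decoy &
    psms$peptide_score >= pep$threshold & psms$glycan_score >= gly$threshold
  list(accepted = psms[keep, , drop = FALSE], peptide = pep, glycan = gly)
}
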