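# Ground-truthed synthetic study generator. Emulates the pooled four-channel
# TMT design of the liver-cancer glycoproteomic study: one channel per group
# (129C = HCC paracancer, 130C = ICC paracancer, 130N = HCC tumor,
# 131 = ICC tumor), dual-energy spectrum pairs per glycopeptide PSM, and a
# LacdiNAc glycopeptide class elevated two- to five-fold in the ICC channel
# while essentially unchanged in HCC.

#' Write a generated study to disk as plain-text files
#'
#' Writes the proteome FASTA, the glycoproteome run (internal JSON layout),
#' the proteome PSM reporter table and the ground-truth manifest (TSV) into
#' a directory.
#'
#' @param study A study list from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(study$proteins, file.path(dir, "proteome.fasta"))
  write_run(study$glyco_run, file.path(dir, "glyco_run.json"))
  write_tsv_report(study$proteome_psms, file.path(dir, "proteome_psms.tsv"))
  m <- study$manifest
  m$low_scans <- vapply(m$low_scans, paste, character(1), collapse = ";")
  write_tsv_report(m, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Synthetic study design
#'
#' Parameters of the generated study. Defaults mirror the pooled design the
#' analysis targets: 200 glycopeptides with at least 5 PSMs each, a LacdiNAc
#' class (15% of glycopeptides) of which 96% are elevated in ICC with
#' fold changes drawn uniformly from [2, 5] (HCC fold ~ 1), multiplicative
#' log-normal reporter noise (sigma 0.1), Poisson noise peaks and 3 ppm m/z
#' jitter.
#'
#' @param n_glycopeptides Number of distinct glycopeptides (default 200).
#' @param n_proteins Proteome size (default 30).
#' @param lacdinac_fraction Fraction of glycopeptides carrying a LacdiNAc
#'   branch (default 0.15).
#' @param lacdinac_elevated_prob Probability a LacdiNAc glycopeptide is
#'   elevated in ICC (default 0.96).
#' @param lacdinac_fold_range ICC/ICCP fold-change range for elevated
#'   LacdiNAc glycopeptides (default c(2, 5)).
#' @param background_change_prob Probability a non-LacdiNAc glycopeptide is
#'   differentially glycosylated (default 0.15).
#' @param background_fold_range Fold-change magnitude range for background
#'   changes (default c(2, 4)).
#' @param protein_change_prob Probability a protein shows a protein-level
#'   expression change in the ICC arm (default 0.1).
#' @param psm_range Min/max PSM replication per glycopeptide (default c(5, 8)).
#' @param base_abundance_meanlog,base_abundance_sdlog Log-normal base reporter
#'   abundance (defaults log(1e5) and 0.8).
#' @param reporter_sigma Multiplicative log-normal reporter noise sigma
#'   (default 0.1).
#' @param noise_peaks_lambda Poisson mean number of noise peaks per scan
#'   (default 30).
#' @param mz_jitter_ppm Gaussian m/z jitter, ppm (default 3).
#' @param loading_bias Per-channel multiplicative loading bias in channel
#'   order 129C, 130C, 130N, 131 (default all 1).
#' @param decoy_spike_fraction Fraction of extra spectrum pairs generated
#'   from shuffled peptides absent from the database (default 0).
#' @param plant_fixture Plant the reference glycopeptide ITDIENGSLANIPR into
#'   the proteome (default TRUE).
#' @param noise Master switch; FALSE zeroes all noise sources (default TRUE).
#' @return A `study_design` list.
#' @export
study_design <- function(n_glycopeptides = 200L, n_proteins = 30L,
                         lacdinac_fraction = 0.15, lacdinac_elevated_prob = 0.96,
                         lacdinac_fold_range = c(2, 5),
                         background_change_prob = 0.15,
                         background_fold_range = c(2, 4),
                         protein_change_prob = 0.1,
                         psm_range = c(5L, 8L),
                         base_abundance_meanlog = log(1e5),
                         base_abundance_sdlog = 0.8,
                         reporter_sigma = 0.1, noise_peaks_lambda = 30,
                         mz_jitter_ppm = 3, loading_bias = c(1, 1, 1, 1),
                         decoy_spike_fraction = 0, plant_fixture = TRUE,
                         noise = TRUE) {
  design <- as.list(environment())
  if (!noise) {
    design$reporter_sigma <- 0
    design$noise_peaks_lambda <- 0
    design$mz_jitter_ppm <- 0
  }
  structure(design, class = "study_design")
}

# Random protein sequences with controlled K/R density and planted sequons.
#' Generate a synthetic proteome
#'
#' Random protein sequences (tryptic K/R density ~ 8%) with N-X-S/T sequons
#' planted so every protein contributes glycopeptide candidates. With
#' `plant_fixture`, protein SYN0001 contains the tryptic glycopeptide
#' ITDIENGSLANIPR. Deterministic per seed.
#'
#' @param n_proteins Number of proteins.
#' @param seed Integer seed.
#' @param mean_length Mean protein length (default 240).
#' @param plant_fixture Plant the reference peptide (default TRUE).
#' @return Tibble with `protein_id`, `sequence`.
#' @export
generate_proteome <- function(n_proteins, seed = 1L, mean_length = 240L,
                              plant_fixture = TRUE) {
  set.seed(seed)
  aas <- setdiff(names(AA_RESIDUE_MASS), c("K", "R"))
  make_protein <- function() {
    len <- max(80L, stats::rpois(1, mean_length))
    chars <- sample(aas, len, replace = TRUE)
    # tryptic sites roughly every 12 residues
    cuts <- seq(10L, len - 5L, by = 12L)
    chars[cuts] <- sample(c("K", "R"), length(cuts), replace = TRUE)
    # plant a sequon mid-peptide in about half the tryptic segments
    seg_starts <- c(1L, cuts + 1L)
    for (s in seg_starts[seq(1, length(seg_starts), by = 2L)]) {
      p <- s + 3L
      if (p + 2L <= len && !chars[p + 2L] %in% c("K", "R")) {
        chars[p] <- "N"
        if (chars[p + 1L] == "P") chars[p + 1L] <- "A"
        chars[p + 2L] <- sample(c("S", "T"), 1)
      }
    }
    paste0(chars, collapse = "")
  }
  seqs <- vapply(seq_len(n_proteins), function(i) make_protein(), character(1))
  if (plant_fixture && n_proteins >= 1) {
    seqs[1] <- paste0(substr(seqs[1], 1, 30), "K", "ITDIENGSLANIPR", "A",
                      substr(seqs[1], 32, nchar(seqs[1])))
  }
  tibble::tibble(
    protein_id = sprintf("SYN%04d", seq_len(n_proteins)),
    sequence = seqs
  )
}

# Pool of glycan structures used by the generator, split into LacdiNAc
# carriers and others (complex, bisecting, core-fucosylated, oligo-mannose).
structure_pool <- function(library) {
  mk <- function(core, branches) glycan_structure(core, branches, library)
  lacdinac <- list(
    mk("core_fucosylated", c("LacdiNAc+NeuAc", "LacNAc")),        # N5H4F1S1
    mk("plain", c("LacdiNAc", "LacNAc+NeuAc")),
    mk("plain", c("LacdiNAc", "LacdiNAc")),
    mk("core_fucosylated", c("LacdiNAc", "LacNAc")),
    mk("bisecting", c("LacdiNAc", "LacNAc")),
    mk("plain", c("LacdiNAc+Fuc", "LacNAc+NeuAc")),
    mk("core_fucosylated", c("LacdiNAc+NeuAc", "LacNAc+NeuAc")),
    mk("plain", c("LacdiNAc+NeuAc", "LacdiNAc"))
  )
  other <- list(
    mk("plain", c("LacNAc", "LacNAc")),
    mk("plain", c("LacNAc+NeuAc", "LacNAc")),
    mk("plain", c("LacNAc+NeuAc", "LacNAc+NeuAc")),
    mk("core_fucosylated", c("LacNAc", "LacNAc")),
    mk("core_fucosylated", c("LacNAc+NeuAc", "LacNAc+NeuAc")),
    mk("bisecting", c("LacNAc", "LacNAc")),
    mk("fucosylated_bisecting", c("LacNAc+NeuAc", "LacNAc")),
    mk("plain", c("LacNAc", "LacNAc", "LacNAc")),
    mk("core_fucosylated", c("LacNAc+NeuAc", "LacNAc", "LacNAc")),
    mk("plain", c("LacNAc+Fuc", "LacNAc+NeuAc")),
    mk("bisecting", c("LacNAc")),
    mk("plain", c("Man", "Man")),                                  # Man5
    mk("plain", c("Man2", "Man2")),                                # Man7
    mk("plain", c("Man2", "Man2", "Man2")),                        # Man9
    mk("bisecting", c("Man"))
  )
  list(lacdinac = lacdinac, other = other)
}

group_folds_to_channels <- function(fold_icc, fold_hcc, fold_iccp = 1, fold_hccp = 1) {
  c(`129C` = fold_hccp, `130C` = fold_iccp, `130N` = fold_hcc, `131` = fold_icc)
}

#' Simulate one dual-energy spectrum pair
#'
#' The high-energy scan carries peptide b/y ions (glycan reduced to
#' peptide+HexNAc Y1 stubs), the TMT reporter region with peaks proportional
#' to the channel abundances, and noise; the low-energy scan carries the
#' structure's theoretical B and Y ions plus oxonium screen ions and noise.
#' The precursor m/z is the glycopeptide neutral mass with ppm jitter.
#'
#' @param peptide Peptide sequence.
#' @param structure A `glycan_structure`.
#' @param abundances Named channel abundance vector (129C, 130C, 130N, 131).
#' @param design A [study_design()].
#' @param scan_id_base First scan id (low scan = base, high scan = base + 1).
#' @param rt Retention time of the pair, seconds.
#' @param charge Precursor charge (default 3).
#' @param library Branch library.
#' @return Two-row run tibble (low scan then high scan).
#' @export
simulate_pair <- function(peptide, structure, abundances, design,
                          scan_id_base = 1L, rt = 100, charge = 3L,
                          library = default_branch_library()) {
  stopifnot(all(abundances > 0))
  pep_mass <- peptide_neutral_mass(peptide)
  glycan_mass <- composition_mass(structure$composition)
  neutral <- pep_mass + glycan_mass
  jit <- function(mz) {
    if (design$mz_jitter_ppm <= 0) return(mz)
    mz * (1 + stats::rnorm(length(mz), 0, design$mz_jitter_ppm) * 1e-6)
  }
  noise_peaks <- function() {
    n <- if (design$noise_peaks_lambda > 0) stats::rpois(1, design$noise_peaks_lambda) else 0L
    if (n == 0) return(tibble::tibble(mz = numeric(), intensity = numeric()))
    tibble::tibble(mz = stats::runif(n, 150, 2200),
                   intensity = stats::rexp(n, rate = 1 / 200))
  }
  prec_mz <- jit((neutral + charge * PROTON_MASS) / charge)

  # low-energy scan: glycan B + Y ions, oxonium screen ions
  b <- theoretical_b_ions(structure, library)
  y <- theoretical_y_ions(structure, pep_mass, charges = 1:2, library = library)
  # oxonium/B ions dominate low-energy HCD spectra of glycopeptides
  low_mz <- c(jit(b$mz), jit(y$mz), DEFAULT_OXONIUM_MZ[["HexNAc_f138"]],
              DEFAULT_OXONIUM_MZ[["HexNAc_f168"]])
  low_int <- c(stats::runif(nrow(b), 8000, 20000),
               stats::runif(nrow(y), 1000, 5000),
               stats::runif(2, 8000, 16000))
  np <- noise_peaks()
  low <- new_ms2_spectrum(scan_id_base, "low", prec_mz, charge, rt,
                          c(low_mz, np$mz), c(low_int, np$intensity))

  # high-energy scan: peptide b/y ladder, Y0/Y1 stubs, reporters
  chars <- strsplit(peptide, "")[[1]]
  res <- AA_RESIDUE_MASS[chars]
  res <- res + ifelse(chars == "C", MOD_MASS[["carbamidomethyl"]], 0) +
    ifelse(chars == "K", MOD_MASS[["tmt10"]], 0)
  n <- length(res)
  b_ions <- cumsum(res)[-n] + MOD_MASS[["tmt10"]] + PROTON_MASS
  y_ions <- rev(cumsum(rev(res)))[-1] + WATER_MASS + PROTON_MASS
  stubs <- c(pep_mass + PROTON_MASS, pep_mass + MONOSACCHARIDE_MASS[["HexNAc"]] + PROTON_MASS,
             (pep_mass + 2 * PROTON_MASS) / 2,
             (pep_mass + MONOSACCHARIDE_MASS[["HexNAc"]] + 2 * PROTON_MASS) / 2)
  rep_noise <- function(x) {
    if (design$reporter_sigma <= 0) return(x)
    x * stats::rlnorm(length(x), 0, design$reporter_sigma)
  }
  reporters <- rep_noise(abundances * design$loading_bias)
  rep_mz <- TMT10_REPORTER_MZ[names(abundances)]
  high_mz <- c(jit(c(b_ions, y_ions, stubs)), rep_mz)
  high_int <- c(stats::runif(length(b_ions) + length(y_ions), 1000, 9000),
                stats::runif(length(stubs), 500, 3000), reporters)
  np2 <- noise_peaks()
  high <- new_ms2_spectrum(scan_id_base + 1L, "high", prec_mz, charge, rt + 0.5,
                           c(high_mz, np2$mz), c(high_int, np2$intensity))
  dplyr::bind_rows(low, high)
}

#' Generate a full synthetic study
#'
#' Produces a synthetic proteome FASTA table, a glycoproteome run of paired
#' dual-energy MS2 scans, a proteome PSM reporter table (for scaling factors
#' and protein-level ratios), and a ground-truth manifest with every
#' glycopeptide's structure and true channel abundances. Fully deterministic
#' per seed.
#'
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @param library Branch library.
#' @return List with elements `proteins`, `glyco_run`, `proteome_psms`,
#'   `manifest`, `design`.
#' @export
generate_study <- function(design = study_design(), seed = 1L,
                           library = default_branch_library()) {
  set.seed(seed)
  proteins <- generate_proteome(design$n_proteins, seed = seed + 1L,
                                plant_fixture = design$plant_fixture)
  set.seed(seed + 2L)
  index <- build_peptide_index(proteins, decoys = FALSE)
  glyco_space <- index[index$has_sequon & index$missed_cleavages == 0L &
                         nchar(index$sequence) <= 30L, ]
  if (nrow(glyco_space) == 0) stop("no glycopeptide candidates in proteome")

  pool <- structure_pool(library)
  n <- design$n_glycopeptides
  n_lac <- round(n * design$lacdinac_fraction)

  # distinct (peptide, site, structure) keys
  pick <- glyco_space[sample.int(nrow(glyco_space), n, replace = n > nrow(glyco_space)), ]
  is_lac <- seq_len(n) <= n_lac
  structs <- vector("list", n)
  structs[is_lac] <- sample(pool$lacdinac, n_lac, replace = TRUE)
  structs[!is_lac] <- sample(pool$other, n - n_lac, replace = TRUE)
  key <- paste(pick$sequence, purrr::map_chr(structs, "canonical"))
  keep <- !duplicated(key)
  pick <- pick[keep, ]; structs <- structs[keep]; is_lac <- is_lac[keep]
  n <- nrow(pick)

  # protein-level expression folds (ICC arm only; HCC arm quiet).
  # Directions are balanced so that total-intensity normalization remains
  # valid, the working assumption of global scaling factors.
  p_changed <- stats::runif(design$n_proteins) < design$protein_change_prob
  p_dir <- sample(c(1, -1), design$n_proteins, replace = TRUE)
  prot_fold_icc <- stats::setNames(
    ifelse(p_changed, stats::runif(design$n_proteins, 2, 3)^p_dir, 1),
    proteins$protein_id
  )

  # true glycosylation-level folds
  fold_icc <- rep(1, n); fold_hcc <- rep(1, n)
  elev <- is_lac & stats::runif(n) < design$lacdinac_elevated_prob
  fold_icc[elev] <- stats::runif(sum(elev), design$lacdinac_fold_range[1],
                                 design$lacdinac_fold_range[2])
  bg <- !is_lac & stats::runif(n) < design$background_change_prob
  bg_arm <- sample(c("icc", "hcc", "both"), n, replace = TRUE,
                   prob = c(0.4, 0.3, 0.3))
  bg_dir <- sample(c(1, -1), n, replace = TRUE, prob = c(0.7, 0.3))
  bg_fold <- stats::runif(n, design$background_fold_range[1],
                          design$background_fold_range[2])^bg_dir
  fold_icc[bg & bg_arm != "hcc"] <- bg_fold[bg & bg_arm != "hcc"]
  fold_hcc[bg & bg_arm != "icc"] <- bg_fold[bg & bg_arm != "icc"]

  psm_count <- sample(design$psm_range[1]:design$psm_range[2], n, replace = TRUE)
  base <- stats::rlnorm(n, design$base_abundance_meanlog, design$base_abundance_sdlog)

  scans <- vector("list", 2L * sum(psm_count))
  scan_rows <- list()
  scan_id <- 1L
  manifest <- vector("list", n)
  rt <- 0
  charges <- sample(3:4, n, replace = TRUE)
  for (i in seq_len(n)) {
    pf <- prot_fold_icc[[pick$protein_id[i]]]
    ch_fold <- group_folds_to_channels(fold_icc[i] * pf, fold_hcc[i])
    abund <- base[i] * ch_fold
    ids <- integer(psm_count[i])
    for (k in seq_len(psm_count[i])) {
      rt <- rt + 2
      pair <- simulate_pair(pick$sequence[i], structs[[i]], abund, design,
                            scan_id_base = scan_id, rt = rt,
                            charge = charges[i], library = library)
      scan_rows[[length(scan_rows) + 1L]] <- pair
      ids[k] <- scan_id
      scan_id <- scan_id + 2L
    }
    site <- pick$sequon_positions[[i]][1]
    manifest[[i]] <- tibble::tibble(
      glycopeptide_id = i,
      protein_id = pick$protein_id[i],
      peptide = pick$sequence[i],
      site = site,
      structure = structs[[i]]$canonical,
      composition = serialize_composition(structs[[i]]$composition),
      has_lacdinac = is_lac[i],
      psm_count = psm_count[i],
      abund_129C = abund[["129C"]], abund_130C = abund[["130C"]],
      abund_130N = abund[["130N"]], abund_131 = abund[["131"]],
      true_icc_iccp = unname(abund[["131"]] / abund[["130C"]]),
      true_hcc_hccp = unname(abund[["130N"]] / abund[["129C"]]),
      true_icc_hcc = unname(abund[["131"]] / abund[["130N"]]),
      true_iccp_hccp = unname(abund[["130C"]] / abund[["129C"]]),
      glyco_fold_icc = fold_icc[i], glyco_fold_hcc = fold_hcc[i],
      protein_fold_icc = pf,
      low_scans = list(ids),
      spiked = FALSE
    )
  }

  # decoy-spike: pairs generated from shuffled peptides absent from the index
  spike_rows <- list()
  n_spike <- round(design$decoy_spike_fraction * sum(psm_count))
  if (n_spike > 0) {
    all_seqs <- unique(index$sequence)
    for (k in seq_len(n_spike)) {
      i <- sample.int(n, 1)
      pep <- pick$sequence[i]
      repeat {
        mid <- sample(seq_len(nchar(pep) - 1L))
        shuf <- paste0(paste(strsplit(substr(pep, 1, nchar(pep) - 1L), "")[[1]][mid],
                             collapse = ""),
                       substr(pep, nchar(pep), nchar(pep)))
        if (!shuf %in% all_seqs) break
      }
      rt <- rt + 2
      pair <- simulate_pair(shuf, structs[[i]],
                            base[i] * group_folds_to_channels(1, 1), design,
                            scan_id_base = scan_id, rt = rt,
                            charge = charges[i], library = library)
      scan_rows[[length(scan_rows) + 1L]] <- pair
      spike_rows[[length(spike_rows) + 1L]] <- tibble::tibble(
        low_scan = scan_id, shuffled_peptide = shuf)
      scan_id <- scan_id + 2L
    }
  }

  glyco_run <- dplyr::bind_rows(scan_rows)

  # proteome PSM reporter table: 3 PSMs per protein, protein fold in the
  # ICC channel, loading bias and reporter noise applied
  prot_rows <- purrr::map_dfr(seq_len(design$n_proteins), function(p) {
    pbase <- stats::rlnorm(1, design$base_abundance_meanlog, design$base_abundance_sdlog)
    ch_fold <- group_folds_to_channels(prot_fold_icc[[p]], 1)
    purrr::map_dfr(1:3, function(k) {
      x <- pbase * ch_fold * design$loading_bias
      if (design$reporter_sigma > 0) x <- x * stats::rlnorm(4, 0, design$reporter_sigma)
      tibble::tibble(protein_id = proteins$protein_id[p],
                     psm_id = paste0(proteins$protein_id[p], "_", k),
                     `129C` = x[[1]], `130C` = x[[2]], `130N` = x[[3]], `131` = x[[4]])
    })
  })

  list(
    proteins = proteins,
    glyco_run = glyco_run,
    proteome_psms = prot_rows,
    manifest = dplyr::bind_rows(manifest),
    spiked_scans = if (length(spike_rows) > 0) dplyr::bind_rows(spike_rows) else
      tibble::tibble(low_scan = integer(), shuffled_peptide = character()),
    protein_folds = tibble::tibble(protein_id = proteins$protein_id,
                                   fold_icc = unname(prot_fold_icc),
                                   fold_hcc = 1),
    design = design
  )
}
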