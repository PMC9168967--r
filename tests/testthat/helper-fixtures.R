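# Shared fixtures, built once per test session. Problem sizes are scaled to
# keep the suite responsive while preserving the statistical structure the
# pipeline assumes (see the methods vignette for the choices).

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

run_study_pipeline <- function(design, seed, alpha = 0.01) {
  st <- generate_study(design, seed = seed)
  idx <- build_peptide_index(st$proteins)
  pairs <- suppressMessages(pair_spectra(st$glyco_run))
  psms <- identify_pairs(pairs, idx)
  fdr <- suppressMessages(apply_dual_fdr(psms, alpha))
  list(study = st, index = idx, pairs = pairs, psms = psms, fdr = fdr)
}

# exact-recovery fraction of manifest (peptide, site, structure) triples
recovery_fraction <- function(study, accepted) {
  m <- study$manifest
  found <- unique(paste(accepted$peptide, accepted$site, accepted$glycan_structure))
  mean(paste(m$peptide, m$site, m$structure) %in% found)
}

small_noise_free <- function() {
  memo_fixture("small_noise_free", function() {
    run_study_pipeline(
      study_design(n_glycopeptides = 25L, n_proteins = 10L, noise = FALSE),
      seed = 11L)
  })
}

small_noisy <- function() {
  memo_fixture("small_noisy", function() {
    run_study_pipeline(
      study_design(n_glycopeptides = 40L, n_proteins = 12L), seed = 7L)
  })
}

default_study_noisy <- function() {
  memo_fixture("default_study_noisy", function() {
    run_study_pipeline(study_design(), seed = 1L)
  })
}

default_study_noise_off <- function() {
  memo_fixture("default_study_noise_off", function() {
    run_study_pipeline(study_design(noise = FALSE), seed = 1L)
  })
}

# paired-isomer fixture: same composition N5H4, LacdiNAc-bearing vs
# bisecting LacNAc assembly, simulated without noise
isomer_pair_fixture <- function() {
  memo_fixture("isomer_pair", function() {
    lib <- default_branch_library()
    design <- study_design(noise = FALSE)
    pep <- "ITDIENGSLANIPR"
    s_lac <- glycan_structure("plain", c("LacdiNAc", "LacNAc"), lib)
    s_iso <- glycan_structure("bisecting", c("LacNAc", "GlcNAc"), lib)
    abund <- c(`129C` = 1e5, `130C` = 1e5, `130N` = 1e5, `131` = 1e5)
    set.seed(5)
    run <- dplyr::bind_rows(
      simulate_pair(pep, s_lac, abund, design, scan_id_base = 1L, rt = 10),
      simulate_pair(pep, s_iso, abund, design, scan_id_base = 3L, rt = 20)
    )
    list(run = run, peptide = pep, lacdinac = s_lac, isomer = s_iso,
         library = lib)
  })
}

# Reference worked-example dataset: the four between-group ratios of 26 quantified
# LacdiNAc-bearing glycopeptides (ICC/ICCP, HCC/HCCP, ICC/HCC, ICCP/HCCP)
lacdinac_reference_ratios <- function() {
  m <- matrix(c(
    2.21, 1.30, 1.56, 0.92,   2.33, 1.39, 1.69, 1.01,
    3.08, 1.46, 2.00, 0.94,   3.75, 1.50, 2.30, 0.92,
    4.28, 1.80, 3.04, 1.28,   2.73, 1.42, 2.09, 1.08,
    2.85, 1.17, 2.25, 0.93,   4.11, 1.44, 2.51, 0.88,
    3.86, 1.29, 2.63, 0.88,   2.91, 1.09, 2.76, 1.04,
    6.02, 1.77, 2.89, 0.85,   4.83, 1.46, 3.11, 0.95,
    1.55, 0.78, 1.62, 0.82,   3.55, 1.17, 2.62, 0.86,
    3.81, 1.14, 2.89, 0.86,   4.69, 1.33, 2.95, 0.83,
    6.62, 1.47, 4.00, 0.89,   7.39, 1.75, 4.39, 1.04,
    14.87, 1.67, 9.85, 1.11,  10.94, 1.62, 7.42, 1.10,
    6.33, 1.80, 3.53, 1.00,   2.80, 1.22, 2.54, 1.11,
    7.84, 1.32, 6.01, 1.01,   4.39, 1.37, 4.14, 1.29,
    9.29, 1.86, 6.69, 1.34,   11.44, 1.95, 6.63, 1.13
  ), ncol = 4, byrow = TRUE)
  colnames(m) <- c("icc_iccp", "hcc_hccp", "icc_hcc", "iccp_hccp")
  tibble::as_tibble(m)
}
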