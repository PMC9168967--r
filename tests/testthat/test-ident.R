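test_that("peptide matching ranks the true peptide first on clean spectra", {
  st <- small_noise_free()
  m <- st$study$manifest
  expect_true("ITDIENGSLANIPR" %in% st$index$sequence)
  # closed loop: every accepted PSM carries the manifest peptide of its scan
  gp_of_scan <- stats::setNames(rep(seq_len(nrow(m)), lengths(m$low_scans)),
                                unlist(m$low_scans))
  acc <- st$fdr$accepted
  truth <- m$peptide[gp_of_scan[as.character(acc$low_scan)]]
  expect_identical(acc$peptide, unname(truth))
  # a spectrum with no b/y matches yields a no-match result
  junk <- tibble::tibble(mz = c(50.1, 60.2), intensity = c(1, 1))
  ranked <- match_peptide(junk, st$index[1:5, ], 3000)
  expect_equal(nrow(ranked), 0)
  # identical candidates score identically and rank deterministically
  frag <- glycostruct:::peptide_fragment_mz(st$index$sequence[1])
  peaks <- tibble::tibble(mz = frag$b, intensity = rep(1, length(frag$b)))
  r1 <- match_peptide(peaks, st$index[c(1, 1), ], 3000)
  expect_true(nrow(r1) == 2 && !is.unsorted(-r1$peptide_score))
})

test_that("core inference reads the Y-ion ladder and Fuc/bisect shifts", {
  lib <- default_branch_library()
  design <- study_design(noise = FALSE)
  pep <- "ITDIENGSLANIPR"
  pm <- peptide_neutral_mass(pep)
  set.seed(4)
  mk_low <- function(structure) {
    simulate_pair(pep, structure, c(`129C` = 1, `130C` = 1, `130N` = 1, `131` = 1),
                  design, scan_id_base = 1L)$peaks[[1]]
  }
  cf <- infer_core(mk_low(glycan_structure("core_fucosylated", "LacNAc", lib)), pm)
  expect_identical(cf$kind, "core_fucosylated")
  expect_true(any(grepl("F1", cf$evidence$composition)))
  pl <- infer_core(mk_low(glycan_structure("plain", "Man", lib)), pm)
  expect_identical(pl$kind, "plain")
  expect_false(pl$bisect_candidate)  # no N-initiated ion beyond the core
  bi <- infer_core(mk_low(glycan_structure("bisecting", "LacdiNAc", lib)), pm)
  expect_identical(bi$kind, "plain")  # parsimony; bisect resolved at assembly
  expect_true(bi$bisect_candidate)
  expect_error(infer_core(tibble::tibble(mz = 100, intensity = 1), pm),
               "unidentifiable")
})

test_that("branch inference requires diagnostic B ions for LacdiNAc and LacNAc", {
  lib <- default_branch_library()
  # spectrum carrying 407.17/698.26/495.18/366.14: sialylated LacdiNAc + LacNAc
  mzs <- c(407.166, 698.261, 495.182, 366.140, 204.087, 163.060)
  peaks <- tibble::tibble(mz = mzs, intensity = rep(100, length(mzs)))
  got <- infer_branches(peaks, "N3H1S1", lib)
  expect_gt(nrow(got), 0)
  expect_setequal(got$branches[[1]], c("LacdiNAc+NeuAc", "LacNAc"))
  # empty residual: the empty multiset, trivially maximal
  none <- infer_branches(peaks, glycan_comp(), lib)
  expect_equal(nrow(none), 1)
  expect_length(none$branches[[1]], 0)
  # isomeric residual with 366.14 but no 407.17: LacdiNAc-free multiset wins
  peaks2 <- tibble::tibble(mz = c(366.140, 204.087, 529.20, 163.060),
                           intensity = rep(100, 4))
  got2 <- infer_branches(peaks2, "N3H1", lib)
  expect_gt(nrow(got2), 0)
  expect_false(any(grepl("LacdiNAc", unlist(got2$branches))))
})

test_that("LacdiNAc/LacNAc isomers are discriminated with zero cross-assignments", {
  fx <- isomer_pair_fixture()
  idx <- tibble::tibble(
    protein_id = "FIX", sequence = fx$peptide, start = 1L,
    end = nchar(fx$peptide), missed_cleavages = 0L,
    sequon_positions = list(find_sequons(fx$peptide)),
    neutral_mass = peptide_neutral_mass(fx$peptide),
    has_sequon = TRUE, is_decoy = FALSE
  )
  pairs <- suppressMessages(pair_spectra(fx$run))
  psms <- identify_pairs(pairs, idx)
  expect_equal(nrow(psms), 2)
  lac <- psms[psms$low_scan == 1, ]
  iso <- psms[psms$low_scan == 3, ]
  expect_identical(lac$glycan_structure, fx$lacdinac$canonical)
  expect_identical(iso$glycan_structure, fx$isomer$canonical)
  # the LacdiNAc call cites a HexNAc2-containing B ion; the isomer must not
  # be assigned any LacdiNAc branch
  cited <- any(vapply(lac$matched_b[[1]], function(cc) {
    v <- parse_composition(cc)
    v[["HexNAc"]] >= 2 && v[["Hex"]] == 0
  }, logical(1)))
  expect_true(cited)
  expect_false(grepl("LacdiNAc", iso$glycan_structure))
})

test_that("glycan scores are monotone under removal of matched ions", {
  fx <- isomer_pair_fixture()
  cfg <- ident_config()
  pm <- peptide_neutral_mass(fx$peptide)
  low <- fx$run$peaks[[1]]
  full <- glycostruct:::score_structure(fx$lacdinac, low, pm, 1:2, fx$library, cfg)
  # drop the HexNAc2 diagnostic peak: score must not increase
  pruned <- low[abs(low$mz - 407.166) > 0.05, ]
  less <- glycostruct:::score_structure(fx$lacdinac, pruned, pm, 1:2, fx$library, cfg)
  expect_true(is.infinite(less$score) || less$score <= full$score)
  # drop a Y ion instead
  pruned2 <- low[seq_len(nrow(low)) != which.max(low$mz), ]
  less2 <- glycostruct:::score_structure(fx$lacdinac, pruned2, pm, 1:2, fx$library, cfg)
  expect_lte(less2$score, full$score)
})

test_that("accepted PSMs satisfy composition closure at 10 ppm", {
  st <- small_noisy()
  acc <- st$fdr$accepted
  expect_gt(nrow(acc), 0)
  expect_true(all(abs(acc$precursor_error_ppm) <= 10 + 3 * 3))  # tolerance + jitter
  pep_mass <- vapply(acc$peptide, peptide_neutral_mass, numeric(1), USE.NAMES = FALSE)
  gly_mass <- vapply(acc$glycan_composition, function(cc) {
    composition_mass(parse_composition(cc))
  }, numeric(1), USE.NAMES = FALSE)
  pair_mass <- st$pairs$precursor_neutral_mass[match(acc$pair_id, st$pairs$pair_id)]
  expect_true(all(abs(pep_mass + gly_mass - pair_mass) / pair_mass * 1e6 <= 25))
  # every LacdiNAc assignment cites a HexNAc2-containing B ion
  lac <- acc[grepl("LacdiNAc", acc$glycan_structure), ]
  cited <- vapply(lac$matched_b, function(b) {
    any(vapply(b, function(cc) {
      v <- parse_composition(cc); v[["HexNAc"]] >= 2 && v[["Hex"]] == 0
    }, logical(1)))
  }, logical(1))
  expect_true(all(cited))
})

test_that("FDR thresholds agree with a brute-force cutoff scan", {
  # separable scores: all targets above all decoys
  psms <- tibble::tibble(
    peptide_score = c(rep(10, 6), rep(1, 4)),
    peptide_decoy = c(rep(FALSE, 6), rep(TRUE, 4))
  )
  r <- fdr_filter(psms, "peptide", alpha = 0.01)
  expect_equal(r$n_accepted, 6)
  expect_true(r$threshold > 1 && r$threshold <= 10)
  # interleaved scores against the brute-force oracle
  set.seed(21)
  for (i in 1:10) {
    sc <- round(stats::rnorm(60, mean = rep(c(5, 3), each = 30)), 2)
    dec <- rep(c(FALSE, TRUE), each = 30)
    ps <- tibble::tibble(glycan_score = sc, glycan_decoy = dec)
    r2 <- fdr_filter(ps, "glycan", alpha = 0.05)
    expect_equal(r2$threshold, oracle_fdr_threshold(sc, dec, 0.05))
  }
  expect_error(fdr_filter(tibble::tibble(peptide_score = 1,
                                         peptide_decoy = FALSE), "peptide"),
               "decoys")
})

test_that("empirical FDR with spiked junk spectra stays near the nominal level", {
  res <- memo_fixture("spike_seed1", function() {
    run_study_pipeline(
      study_design(n_glycopeptides = 60L, n_proteins = 15L,
                   decoy_spike_fraction = 0.1), seed = 1L)
  })
  acc <- res$fdr$accepted
  emp <- mean(acc$low_scan %in% res$study$spiked_scans$low_scan)
  expect_lte(emp, 0.02)
  expect_gte(recovery_fraction(res$study, acc), 0.95)
})
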