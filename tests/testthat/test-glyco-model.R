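test_that("composition masses and oxonium m/z reproduce reference values", {
  expect_equal(composition_mass(glycan_comp()), 0)
  # additivity over a grid of random compositions
  set.seed(1)
  for (i in 1:20) {
    a <- glycan_comp(sample(0:4, 1), sample(0:5, 1), sample(0:2, 1), sample(0:2, 1))
    b <- glycan_comp(sample(0:4, 1), sample(0:5, 1), sample(0:2, 1), sample(0:2, 1))
    expect_equal(composition_mass(comp_add(a, b)),
                 composition_mass(a) + composition_mass(b))
  }
  # diagnostic oxonium ions at 2 dp
  expect_equal(round(oxonium_mz(glycan_comp(HexNAc = 2)), 2), 407.17)
  expect_equal(round(oxonium_mz(glycan_comp(HexNAc = 1, NeuAc = 1)), 2), 495.18)
  expect_equal(round(oxonium_mz(glycan_comp(HexNAc = 2, NeuAc = 1)), 2), 698.26)
  # independent-summation oracle values
  expect_equal(oxonium_mz(glycan_comp(HexNAc = 2, Fuc = 1)), 553.2239,
               tolerance = 1e-6)
  expect_equal(composition_mass(parse_composition("N5H4F1S1")), 2100.7615,
               tolerance = 1e-6)
  expect_error(composition_mass(c(HexNAc = -1, Hex = 0, Fuc = 0, NeuAc = 0)),
               "non-negative")
  expect_error(oxonium_mz(glycan_comp()), "empty")
})

test_that("composition strings parse and serialize with round-trip identity", {
  cmp <- parse_composition("N5H4F1S1")
  expect_equal(unclass(cmp), c(HexNAc = 5L, Hex = 4L, Fuc = 1L, NeuAc = 1L),
               ignore_attr = TRUE)
  expect_equal(unclass(parse_composition("N2H3")),
               c(HexNAc = 2L, Hex = 3L, Fuc = 0L, NeuAc = 0L),
               ignore_attr = TRUE)
  expect_identical(serialize_composition(parse_composition("N4H5F1")), "N4H5F1")
  for (s in c("N2H3", "N5H4F1S1", "H5", "N1S2")) {
    expect_identical(serialize_composition(parse_composition(s)), s)
  }
  expect_error(parse_composition("N2X3"), "X")
  expect_error(parse_composition("garbage"), "malformed")
})

test_that("the default branch library has 12 motifs with the stated families", {
  lib <- default_branch_library()
  expect_equal(nrow(lib), 12)
  expect_setequal(unique(lib$family), c("GlcNAc", "LacNAc", "LacdiNAc", "Mannose"))
  # LacdiNAc-family motifs contain two consecutive HexNAc; LacNAc HexNAc-Hex
  for (i in which(lib$family == "LacdiNAc")) {
    expect_identical(lib$chain[[i]][1:2], c("HexNAc", "HexNAc"))
  }
  for (i in which(lib$family == "LacNAc")) {
    expect_identical(lib$chain[[i]][1:2], c("HexNAc", "Hex"))
  }
})

test_that("structures have canonical, permutation-invariant, round-tripping encodings", {
  lib <- default_branch_library()
  a <- glycan_structure("core_fucosylated", c("LacNAc", "LacdiNAc+NeuAc"), lib)
  b <- glycan_structure("core_fucosylated", c("LacdiNAc+NeuAc", "LacNAc"), lib)
  expect_identical(a$canonical, b$canonical)
  expect_identical(parse_structure(a$canonical, lib)$canonical, a$canonical)
  expect_identical(serialize_composition(structure_composition(a)), "N5H4F1S1")
  # composition equals core plus branch sum
  core_plus <- comp_add(parse_composition("N2H3F1"),
                        comp_add(parse_composition("N1H1"),
                                 parse_composition("N2S1")))
  expect_equal(unclass(structure_composition(a)), unclass(core_plus),
               ignore_attr = TRUE)
  expect_error(glycan_structure("plain", rep("LacNAc", 5), lib), "antennae")
  expect_error(parse_structure("notastructure", lib), "malformed")
})

test_that("structure enumeration is exact, duplicate-free and matches brute force", {
  lib <- default_branch_library()
  expect_length(enumerate_structures("N2H3", lib), 1)
  expect_gte(length(enumerate_structures("N4H5F1", lib)), 7)
  canon_n5h4 <- purrr::map_chr(enumerate_structures("N5H4", lib), "canonical")
  expect_true(any(grepl("LacdiNAc", canon_n5h4)))
  expect_true(any(grepl("^bisecting", canon_n5h4) & grepl("LacNAc", canon_n5h4)))
  # every structure's composition equals the input exactly; no duplicates
  for (comp in c("N4H5F1", "N5H4", "N3H4", "N2H5")) {
    st <- enumerate_structures(comp, lib)
    expect_false(any(duplicated(purrr::map_chr(st, "canonical"))))
    for (s in st) {
      expect_identical(serialize_composition(structure_composition(s)), comp)
    }
    expect_setequal(purrr::map_chr(st, "canonical"), oracle_enumerate(comp, lib))
  }
  # smaller than any core: empty set, not an error
  expect_length(enumerate_structures("N1H1", lib), 0)
})

test_that("theoretical B ions cover branch sub-fragments and diagnostics", {
  lib <- default_branch_library()
  s <- glycan_structure("core_fucosylated", c("LacdiNAc+NeuAc", "LacNAc"), lib)
  b <- theoretical_b_ions(s, lib)
  got <- round(b$mz, 2)
  expect_true(all(c(407.17, 495.18, 698.26, 366.14, 204.09) %in% got))
  expect_false(any(duplicated(b$composition)))
  expect_false(is.unsorted(b$mz))
  # bare core: only single-residue oxonium ions
  bare <- theoretical_b_ions(glycan_structure("plain", character(), lib), lib)
  expect_setequal(bare$composition, c("N1", "H1"))
  # brute-force prefix oracle on a bisecting biantennary disialylated glycan
  s2 <- glycan_structure("bisecting", c("LacNAc+NeuAc", "LacNAc+NeuAc"), lib)
  b2 <- theoretical_b_ions(s2, lib)
  expect_setequal(b2$composition,
                  c("N1", "H1", "N1H1", "H1S1", "S1", "N1H1S1"))
})

test_that("theoretical Y ions include the core ladder and match the mass oracle", {
  lib <- default_branch_library()
  pep <- 1740.957303  # ITDIENGSLANIPR + TMT, independent calculator
  s <- glycan_structure("core_fucosylated", c("LacdiNAc+NeuAc", "LacNAc"), lib)
  y <- theoretical_y_ions(s, pep, charges = 2:3, library = lib)
  # oracle values for two reference glycopeptide Y ions at z = 3
  expect_true(any(abs(y$mz - 1184.5484) < 1e-3))  # peptide+N5H4F1
  expect_true(any(abs(y$mz - 1227.5626) < 1e-3))  # peptide+N5H3F1S1
  expect_true("N4H3F1S1" %in% y$composition)
  y1 <- theoretical_y_ions(s, pep, charges = 1, library = lib)
  expect_equal(min(y1$mz), pep + 1.007276, tolerance = 1e-6)  # Y0
  expect_true("N2H3F1" %in% y1$composition)  # peptide+core+Fuc
  expect_error(theoretical_y_ions(s, -5), "positive")
  # B/Y complementarity: fragment plus retained remainder equals the glycan
  total <- composition_mass(structure_composition(s))
  ycomp <- glycostruct:::structure_y_compositions(s, lib)
  b <- theoretical_b_ions(s, lib)
  for (i in seq_len(nrow(b))) {
    fmass <- composition_mass(parse_composition(b$composition[i]))
    expect_lte(fmass, total + 1e-9)
  }
  expect_true(any(abs((total - ycomp$glycan_mass) -
                        composition_mass(parse_composition("N2S1"))) < 1e-9))
})

test_that("feature classification derives subtype, counts and flags from structure", {
  lib <- default_branch_library()
  man5 <- glycan_structure("plain", c("Man", "Man"), lib)
  f <- classify_features(man5, lib)
  expect_identical(f$subtype, "oligo_mannose")
  expect_identical(f$n_fucose, 0L)
  sialyl_lacdinac <- glycan_structure("core_fucosylated", c("LacdiNAc+NeuAc", "LacNAc"), lib)
  f2 <- classify_features(sialyl_lacdinac, lib)
  expect_true(f2$has_lacdinac && f2$has_core_fucose)
  expect_identical(f2$n_sialic, 1L)
  expect_identical(f2$subtype, "complex")
  tri <- glycan_structure("core_fucosylated",
                          c("LacNAc+Fuc", "LacNAc+Fuc", "LacNAc"), lib)
  f3 <- classify_features(tri, lib)
  expect_identical(f3$n_fucose, 3L)
  expect_true(f3$antenna_fucose)
  expect_identical(f3$n_antennae, 3L)
  # n_fucose always equals the composition fucose count
  for (s in enumerate_structures("N4H5F1", lib)) {
    expect_identical(classify_features(s, lib)$n_fucose,
                     structure_composition(s)[["Fuc"]])
  }
})
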