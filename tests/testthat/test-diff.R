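ratio_tbl <- function(ii, hh, ih, pp, nii = NULL, nhh = NULL) {
  t <- tibble::tibble(ratio_icc_iccp = ii, ratio_hcc_hccp = hh,
                      ratio_icc_hcc = ih, ratio_iccp_hccp = pp)
  if (!is.null(nii)) t$norm_icc_iccp <- nii
  if (!is.null(nhh)) t$norm_hcc_hccp <- nhh
  t
}

test_that("the fold-change decision tree reproduces the worked examples", {
  # quantified LacdiNAc glycopeptide on ASPN: ICC-specific increase
  r <- categorize_glycopeptides(ratio_tbl(2.21, 1.30, 1.56, 0.92))
  expect_identical(as.character(r$category), "icc_specific_up")
  expect_identical(as.character(categorize_glycopeptides(
    ratio_tbl(1, 1, 1, 1))$category), "unchanged")
  # fourfold glycopeptide fully explained by fourfold protein expression
  r2 <- categorize_glycopeptides(ratio_tbl(4, 1, 4, 1, nii = 1, nhh = 1))
  expect_identical(as.character(r2$category), "protein_level_only")
  r3 <- categorize_glycopeptides(ratio_tbl(3, 3, 1, 1))
  expect_identical(as.character(r3$category), "common_up")
  r4 <- categorize_glycopeptides(ratio_tbl(1, 1, 1, 4))
  expect_identical(as.character(r4$category), "paracancer_differs")
  r5 <- categorize_glycopeptides(ratio_tbl(3, 1/3, 9, 1))
  expect_identical(as.character(r5$category), "opposite")
  expect_error(categorize_glycopeptides(ratio_tbl(NA, 1, 1, 1)), "missing")
})

test_that("categories partition ratio space and mirror under direction flips", {
  set.seed(14)
  mirror <- c(common_up = "common_down", common_down = "common_up",
              icc_specific_up = "icc_specific_down",
              icc_specific_down = "icc_specific_up",
              hcc_specific_up = "hcc_specific_down",
              hcc_specific_down = "hcc_specific_up",
              opposite = "opposite", unchanged = "unchanged",
              paracancer_differs = "paracancer_differs",
              protein_level_only = "protein_level_only")
  for (i in 1:300) {
    ii <- stats::rlnorm(1, 0, 1); hh <- stats::rlnorm(1, 0, 1)
    pp <- stats::rlnorm(1, 0, 0.5)
    ih <- ii / hh * pp
    prot <- stats::rlnorm(1, 0, 0.5)
    t <- ratio_tbl(ii, hh, ih, pp, nii = ii / prot, nhh = hh / prot)
    got <- as.character(categorize_glycopeptides(t)$category)
    # exactly one label, agreeing with the independent rule oracle
    expect_length(got, 1)
    expect_false(is.na(got))
    expect_identical(got, oracle_categorize(ii, hh, ih, pp, ii / prot, hh / prot, 2))
    # direction flip mirrors the label
    tf <- ratio_tbl(1/ii, 1/hh, 1/ih, 1/pp, nii = prot/ii, nhh = prot/hh)
    expect_identical(as.character(categorize_glycopeptides(tf)$category),
                     unname(mirror[got]))
  }
})

test_that("most reference LacdiNAc ratios categorize as ICC-specific increases", {
  t1 <- lacdinac_reference_ratios()
  q <- tibble::tibble(ratio_icc_iccp = t1$icc_iccp, ratio_hcc_hccp = t1$hcc_hccp,
                      ratio_icc_hcc = t1$icc_hcc, ratio_iccp_hccp = t1$iccp_hccp)
  got <- categorize_glycopeptides(q)$category
  expect_gte(sum(got == "icc_specific_up"), 24)
  expect_equal(sum(got %in% c("hcc_specific_up", "common_up")), 0)
})

test_that("feature frequencies report percentages that sum to 100 per partition", {
  st <- small_noisy()
  sf <- proteome_scaling_factors(st$study$proteome_psms)
  quant <- aggregate_glycopeptides(apply_scaling(st$fdr$accepted, sf), 5)
  catq <- categorize_glycopeptides(add_structure_features(quant))
  ff <- feature_frequencies(catq)
  sums <- stats::aggregate(percent ~ feature + category, data = ff, FUN = sum)
  expect_true(all(abs(sums$percent - 100) < 1e-9))
  # an empty category yields no rows, not a division error
  expect_false("paracancer_differs" %in% as.character(ff$category) &&
                 any(is.na(ff$percent)))
  # LacdiNAc share of the ICC-specific increases matches the design intent
  lac <- ff[ff$feature == "has_lacdinac" & ff$category == "icc_specific_up" &
              ff$value == "TRUE", ]
  if (nrow(lac) > 0) expect_gte(lac$percent, 50)
})

test_that("PCA of channel profiles has the stated spectral properties", {
  q <- tibble::tibble(med_129C = c(1, 2, 4, 8), med_130C = c(1, 2, 4, 8),
                      med_130N = c(2, 4, 8, 16), med_131 = c(8, 4, 2, 1))
  p <- pca_glycopeptides(q)
  expect_true(all(diff(p$explained_variance) < 1e-9))
  expect_equal(sum(p$explained_variance), 1)
  # identical channels coincide in PC space
  c129 <- as.numeric(p$coordinates[p$coordinates$channel == "129C", -(1:2)])
  c130c <- as.numeric(p$coordinates[p$coordinates$channel == "130C", -(1:2)])
  expect_equal(c129, c130c, tolerance = 1e-9)
  # rank-1 matrix: PC1 explains everything
  r1 <- tibble::tibble(med_129C = c(2, 4), med_130C = c(4, 8),
                       med_130N = c(8, 16), med_131 = c(16, 32))
  expect_equal(pca_glycopeptides(r1)$explained_variance[1], 1)
  expect_error(pca_glycopeptides(tibble::tibble(
    med_129C = c(1, 1), med_130C = c(1, 1),
    med_130N = c(1, 1), med_131 = c(1, 1))), "constant")
  # the ICC channel separates in the default synthetic study
  st <- small_noisy()
  sf <- proteome_scaling_factors(st$study$proteome_psms)
  quant <- aggregate_glycopeptides(apply_scaling(st$fdr$accepted, sf), 5)
  ps <- pca_glycopeptides(quant)
  co <- as.matrix(ps$coordinates[, c("PC1", "PC2")])
  d_icc <- min(sqrt(rowSums((co[-4, , drop = FALSE] -
                               matrix(co[4, ], 3, 2, byrow = TRUE))^2)))
  d_rest <- max(stats::dist(co[-4, ]))
  expect_gt(d_icc, d_rest)
})

test_that("hierarchical clustering recovers planted block structure", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(-1, -1, 1, 1))
  cl <- cluster_fold_changes(m)
  # identical rows merge first at height 0
  expect_equal(cl$row_hclust$height[1], 0)
  expect_setequal(rownames(m)[-cl$row_hclust$merge[1, ]], c("a", "b"))
  # block-structured matrix: blocks become clades
  set.seed(30)
  blocks <- rbind(matrix(stats::rnorm(20, 5), 5), matrix(stats::rnorm(20, -5), 5))
  rownames(blocks) <- paste0("r", 1:10)
  cl2 <- cluster_fold_changes(blocks)
  cut <- stats::cutree(cl2$row_hclust, 2)
  expect_equal(length(unique(cut[1:5])), 1)
  expect_equal(length(unique(cut[6:10])), 1)
  expect_false(cut[1] == cut[6])
  bad <- m; bad[1, 1] <- NaN
  expect_error(cluster_fold_changes(bad), "a")
  # quantified LacdiNAc ratios cluster apart from an unchanged control row
  t1 <- as.matrix(lacdinac_reference_ratios())
  mat <- log2(rbind(t1, control = c(1, 1, 1, 1)))
  rownames(mat) <- c(paste0("lacdinac_", seq_len(nrow(t1))), "control")
  cl3 <- cluster_fold_changes(mat)
  grp <- stats::cutree(cl3$row_hclust, 2)
  # the strongly elevated LacdiNAc rows sit in a different clade than the
  # unchanged control
  expect_false(grp[["lacdinac_19"]] == grp[["control"]])
  expect_false(grp[["lacdinac_20"]] == grp[["control"]])
})

test_that("plot and tidier helpers return well-formed objects", {
  st <- small_noisy()
  sf <- proteome_scaling_factors(st$study$proteome_psms)
  quant <- aggregate_glycopeptides(apply_scaling(st$fdr$accepted, sf), 5)
  catq <- categorize_glycopeptides(add_structure_features(quant))
  ff <- feature_frequencies(catq)
  expect_s3_class(plot_feature_frequencies(ff), "ggplot")
  expect_s3_class(plot_pca(pca_glycopeptides(quant)), "ggplot")
  fc <- log2(as.matrix(quant[1:5, c("ratio_icc_iccp", "ratio_hcc_hccp",
                                    "ratio_icc_hcc", "ratio_iccp_hccp")]))
  rownames(fc) <- quant$peptide[1:5]
  expect_s3_class(plot_fold_change_heatmap(cluster_fold_changes(fc)), "ggplot")
  g <- glance(st$fdr$peptide)
  expect_identical(g$level, "peptide")
  td <- tidy(parse_structure("core_fucosylated(LacNAc,LacdiNAc+NeuAc)"))
  expect_true(td$has_lacdinac)
  expect_identical(td$composition, "N5H4F1S1")
})
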