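# Differential site-specific glycosylation: fold-change categorization into
# common vs tumor-specific alterations, structural feature frequency
# summaries, and PCA / hierarchical-clustering matrices.

DIFF_LABELS <- c("paracancer_differs", "protein_level_only", "common_up",
                 "common_down", "icc_specific_up", "icc_specific_down",
                 "hcc_specific_up", "hcc_specific_down", "opposite",
                 "unchanged")

categorize_one <- function(icc_iccp, hcc_hccp, icc_hcc, iccp_hccp,
                           norm_icc_iccp, norm_hcc_hccp, cutoff,
                           require_tumor_contrast) {
  if (any(is.na(c(icc_iccp, hcc_hccp, icc_hcc, iccp_hccp)))) {
    stop("missing ratio; all four comparisons are required", call. = FALSE)
  }
  inside <- function(r) r < cutoff & r > 1 / cutoff
  up <- function(r) r >= cutoff
  down <- function(r) r <= 1 / cutoff
  # (i) paracancer baselines differ
  if (!inside(iccp_hccp)) return("paracancer_differs")
  icc_changed <- !inside(icc_iccp)
  hcc_changed <- !inside(hcc_hccp)
  # (ii) change entirely at protein expression level: every changed
  # tumor/paracancer arm has its normalized glycosylation inside the band
  if ((icc_changed || hcc_changed) &&
      (!icc_changed || inside(norm_icc_iccp)) &&
      (!hcc_changed || inside(norm_hcc_hccp))) {
    return("protein_level_only")
  }
  # (iii) common alterations
  if (up(icc_iccp) && up(hcc_hccp)) return("common_up")
  if (down(icc_iccp) && down(hcc_hccp)) return("common_down")
  # (v) opposite directions
  if ((up(icc_iccp) && down(hcc_hccp)) || (down(icc_iccp) && up(hcc_hccp))) {
    return("opposite")
  }
  # (iv) tumor-type-specific alterations
  if (xor(icc_changed, hcc_changed) &&
      (!require_tumor_contrast || !inside(icc_hcc))) {
    if (icc_changed) return(if (up(icc_iccp)) "icc_specific_up" else "icc_specific_down")
    return(if (up(hcc_hccp)) "hcc_specific_up" else "hcc_specific_down")
  }
  "unchanged"
}

#' Categorize quantified glycopeptides by fold change
#'
#' Applies the twofold-cutoff decision tree to each glycopeptide's four
#' between-group ratios: (i) glycopeptides whose paracancer baselines differ
#' (ICCP/HCCP outside the band) are set aside; (ii) changes explained
#' entirely by protein expression (normalized glycosylation inside the band
#' while the glycopeptide ratio is outside) are labelled
#' `protein_level_only`; (iii) both tumor/paracancer ratios beyond the cutoff
#' give `common_up`/`common_down`; (iv) exactly one arm changed gives the
#' tumor-specific labels; (v) arms changed in opposite directions give
#' `opposite`; everything else is `unchanged`. Labels are exhaustive and
#' mutually exclusive.
#'
#' @param quant Tibble with ratio columns (`ratio_*`) and, if available,
#'   normalized-glycosylation columns (`norm_*`, see
#'   [add_normalized_glycosylation()]); without them the glycopeptide ratios
#'   are used as their own normalization (no protein-level exclusion).
#' @param cutoff Fold-change cutoff (default 2).
#' @param require_tumor_contrast Additionally require the ICC/HCC ratio to
#'   exceed the cutoff for the tumor-specific labels (default FALSE).
#' @return `quant` with a `category` factor column.
#' @export
categorize_glycopeptides <- function(quant, cutoff = 2,
                                     require_tumor_contrast = FALSE) {
  norm_icc <- quant[["norm_icc_iccp"]] %||% quant$ratio_icc_iccp
  norm_hcc <- quant[["norm_hcc_hccp"]] %||% quant$ratio_hcc_hccp
  quant$category <- factor(vapply(seq_len(nrow(quant)), function(i) {
    categorize_one(quant$ratio_icc_iccp[i], quant$ratio_hcc_hccp[i],
                   quant$ratio_icc_hcc[i], quant$ratio_iccp_hccp[i],
                   norm_icc[i], norm_hcc[i], cutoff, require_tumor_contrast)
  }, character(1)), levels = DIFF_LABELS)
  quant
}

#' Structural feature frequencies per category
#'
#' Counts and percentages of glycan feature classes (subtype, core kind,
#' LacdiNAc / core-fucose / bisecting flags, antennarity, fucose and sialic
#' acid counts) within each fold-change category. Percentages sum to 100
#' within each category x feature partition; empty categories yield zero
#' rows rather than division errors.
#'
#' @param categorized Tibble from [categorize_glycopeptides()] whose rows
#'   carry feature columns (as added by [add_structure_features()]).
#' @param features Character vector of feature column names to summarise.
#' @return Long tibble: `category`, `feature`, `value`, `n`, `percent`.
#' @export
feature_frequencies <- function(categorized,
                                features = c("subtype", "core_kind",
                                             "has_lacdinac", "has_core_fucose",
                                             "has_bisecting", "n_antennae",
                                             "n_fucose", "n_sialic")) {
  purrr::map_dfr(features, function(f) {
    tab <- dplyr::count(categorized, .data$category, value = as.character(.data[[f]]))
    tab <- dplyr::mutate(dplyr::group_by(tab, .data$category),
                         percent = 100 * .data$n / sum(.data$n))
    dplyr::ungroup(dplyr::mutate(tab, feature = f, .before = "value"))
  })
}

#' Attach structural feature columns to a quantified table
#'
#' Parses each row's canonical structure and binds the [classify_features()]
#' vector (subtype, core kind, counts and flags).
#'
#' @param quant Tibble with a `glycan_structure` column of canonical strings.
#' @param library Branch library.
#' @return `quant` with the feature columns appended.
#' @export
add_structure_features <- function(quant, library = default_branch_library()) {
  feats <- purrr::map_dfr(quant$glycan_structure, function(s) {
    classify_features(parse_structure(s, library), library)
  })
  dplyr::bind_cols(quant, feats)
}

#' Principal component analysis of channel intensity profiles
#'
#' Log-transforms and centers the glycopeptide x channel median-intensity
#' matrix and computes sample (channel) coordinates in PC space. Deterministic
#' up to sign; explained variances are non-increasing and sum to the total.
#'
#' @param quant Tibble with per-channel median columns `med_129C`, `med_130C`,
#'   `med_130N`, `med_131` (at least 2 rows).
#' @return List with `coordinates` (tibble: channel, group, PC columns) and
#'   `explained_variance` (fractions).
#' @export
pca_glycopeptides <- function(quant) {
  med <- c("med_129C", "med_130C", "med_130N", "med_131")
  mat <- log2(as.matrix(quant[, med]))
  if (nrow(mat) < 2) stop("need at least 2 glycopeptides for PCA", call. = FALSE)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (all(apply(mat, 2, stats::sd) == 0)) {
    stop("constant intensity matrix; PCA undefined", call. = FALSE)
  }
  # samples (channels) as observations, glycopeptides as variables
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- tibble::as_tibble(pc$x[, seq_len(min(3, ncol(pc$x))), drop = FALSE])
  coords <- dplyr::bind_cols(
    tibble::tibble(channel = CHANNEL_COLS,
                   group = unname(STUDY_CHANNELS[CHANNEL_COLS])),
    coords
  )
  list(coordinates = coords, explained_variance = ev)
}

#' Hierarchical clustering of log2 fold changes
#'
#' Two-way agglomerative clustering of the log2 fold-change matrix using
#' Euclidean distance (average linkage by default). Row and column orders
#' are deterministic.
#'
#' @param fc_matrix Numeric matrix of log2 fold changes (rows = glycopeptides,
#'   columns = comparisons); must be finite.
#' @param method Linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return List with `row_hclust`, `col_hclust`, `matrix` (reordered).
#' @export
cluster_fold_changes <- function(fc_matrix, method = "average") {
  bad <- which(!is.finite(fc_matrix), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    keys <- unique(rownames(fc_matrix)[bad[, 1]] %||% as.character(bad[, 1]))
    stop("non-finite fold changes for: ", paste(keys, collapse = ", "),
         call. = FALSE)
  }
  rh <- stats::hclust(stats::dist(fc_matrix, method = "euclidean"), method = method)
  ch <- stats::hclust(stats::dist(t(fc_matrix), method = "euclidean"), method = method)
  list(row_hclust = rh, col_hclust = ch,
       matrix = fc_matrix[rh$order, ch$order, drop = FALSE])
}
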