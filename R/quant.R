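# TMT reporter quantification: proteome-derived channel scaling, PSM ->
# glycopeptide aggregation by medians over >= 5 PSMs, between-group ratios
# and normalized glycosylation (glycopeptide ratio / protein ratio).

CHANNEL_COLS <- c("129C", "130C", "130N", "131")

#' Proteome-derived channel scaling factors
#'
#' Computes one multiplicative factor per channel from the global-proteome
#' PSM reporter totals: `factor(c) = mean(totals) / total(c)`. After scaling,
#' per-channel proteome totals are equal; the glycopeptide run re-uses these
#' factors.
#'
#' @param proteome_psms Tibble with reporter columns `129C`, `130C`, `130N`,
#'   `131` (one row per proteome PSM).
#' @return Named numeric vector of per-channel factors.
#' @examples
#' psms <- tibble::tibble(`129C` = 100, `130C` = 200, `130N` = 100, `131` = 100)
#' proteome_scaling_factors(psms) # 1.25 0.625 1.25 1.25
#' @export
proteome_scaling_factors <- function(proteome_psms) {
  totals <- vapply(CHANNEL_COLS, function(ch) {
    sum(proteome_psms[[ch]], na.rm = TRUE)
  }, numeric(1))
  if (any(totals <= 0) || any(!is.finite(totals))) {
    stop("zero or missing total intensity in a channel; cannot derive scaling",
         call. = FALSE)
  }
  mean(totals) / totals
}

#' Apply channel scaling factors to a PSM table
#'
#' @param psms Tibble with the four reporter channel columns.
#' @param factors Named factors from [proteome_scaling_factors()].
#' @return The tibble with scaled reporter columns.
#' @export
apply_scaling <- function(psms, factors) {
  for (ch in CHANNEL_COLS) psms[[ch]] <- psms[[ch]] * factors[[ch]]
  psms
}

# channel -> group: 129C=HCCP, 130C=ICCP, 130N=HCC, 131=ICC
add_ratio_columns <- function(agg) {
  agg$ratio_icc_iccp <- unname(agg$med_131 / agg$med_130C)
  agg$ratio_hcc_hccp <- unname(agg$med_130N / agg$med_129C)
  agg$ratio_icc_hcc <- unname(agg$med_131 / agg$med_130N)
  agg$ratio_iccp_hccp <- unname(agg$med_130C / agg$med_129C)
  agg
}

#' Aggregate PSMs to quantified glycopeptides
#'
#' Groups FDR-passing PSMs by glycopeptide key (protein, peptide, site,
#' canonical structure), drops keys with fewer than `min_psm` PSMs, takes the
#' per-channel median over PSMs (missing channels are excluded from that
#' channel's median, not imputed as zero), and derives the four between-group
#' ratios ICC/ICCP, HCC/HCCP, ICC/HCC, ICCP/HCCP from the medians.
#'
#' @param psms Scaled, FDR-passing PSM tibble (reporter columns present).
#' @param min_psm Minimum PSMs per glycopeptide (default 5).
#' @return Tibble keyed by glycopeptide with `psm_count`, per-channel medians
#'   `med_*` and ratio columns.
#' @export
aggregate_glycopeptides <- function(psms, min_psm = 5L) {
  grouped <- dplyr::group_by(psms, .data$protein_id, .data$peptide,
                             .data$site, .data$glycan_structure)
  agg <- dplyr::summarise(
    grouped,
    glycan_composition = dplyr::first(.data$glycan_composition),
    psm_count = dplyr::n(),
    med_129C = stats::median(.data$`129C`, na.rm = TRUE),
    med_130C = stats::median(.data$`130C`, na.rm = TRUE),
    med_130N = stats::median(.data$`130N`, na.rm = TRUE),
    med_131 = stats::median(.data$`131`, na.rm = TRUE),
    .groups = "drop"
  )
  agg <- agg[agg$psm_count >= min_psm, , drop = FALSE]
  add_ratio_columns(agg)
}

#' Protein-level quantification from the proteome run
#'
#' Protein abundance per channel is the median over the protein's
#' (non-glycosylated) PSMs of the scaled reporter intensities; the same four
#' between-group ratios are derived.
#'
#' @param proteome_psms Scaled proteome PSM tibble with `protein_id` and the
#'   reporter columns.
#' @return Tibble with one row per protein: medians and ratio columns.
#' @export
protein_quant <- function(proteome_psms) {
  grouped <- dplyr::group_by(proteome_psms, .data$protein_id)
  agg <- dplyr::summarise(
    grouped,
    psm_count = dplyr::n(),
    med_129C = stats::median(.data$`129C`, na.rm = TRUE),
    med_130C = stats::median(.data$`130C`, na.rm = TRUE),
    med_130N = stats::median(.data$`130N`, na.rm = TRUE),
    med_131 = stats::median(.data$`131`, na.rm = TRUE),
    .groups = "drop"
  )
  add_ratio_columns(agg)
}

#' Normalized glycosylation ratio
#'
#' Divides a glycopeptide's between-group ratio by its parent protein's
#' expression ratio, isolating the change attributable to glycosylation.
#'
#' @param glycopeptide_ratio Numeric vector of glycopeptide ratios.
#' @param protein_ratio Matching protein ratios (must be positive).
#' @return Numeric vector of normalized ratios.
#' @examples
#' normalized_glycosylation(4.0, 2.0) # 2.0
#' @export
normalized_glycosylation <- function(glycopeptide_ratio, protein_ratio) {
  if (any(!is.na(protein_ratio) & protein_ratio <= 0)) {
    stop("protein ratio must be positive", call. = FALSE)
  }
  glycopeptide_ratio / protein_ratio
}

#' Join glycopeptide and protein ratios
#'
#' Adds normalized-glycosylation columns (`norm_*`) to a quantified
#' glycopeptide table by dividing each ratio by the parent protein's ratio.
#' Glycopeptides whose protein was not quantified in the proteome run keep
#' their unnormalized ratios and are flagged `protein_quantified = FALSE`.
#'
#' @param quant Tibble from [aggregate_glycopeptides()].
#' @param proteins Tibble from [protein_quant()].
#' @return `quant` with `norm_icc_iccp`, `norm_hcc_hccp`, `norm_icc_hcc`,
#'   `norm_iccp_hccp` and `protein_quantified` columns.
#' @export
add_normalized_glycosylation <- function(quant, proteins) {
  prot <- proteins[, c("protein_id", "ratio_icc_iccp", "ratio_hcc_hccp",
                       "ratio_icc_hcc", "ratio_iccp_hccp")]
  names(prot)[-1] <- paste0("prot_", names(prot)[-1])
  out <- dplyr::left_join(quant, prot, by = "protein_id")
  out$protein_quantified <- !is.na(out$prot_ratio_icc_iccp)
  for (cmp in c("icc_iccp", "hcc_hccp", "icc_hcc", "iccp_hccp")) {
    g <- out[[paste0("ratio_", cmp)]]
    p <- out[[paste0("prot_ratio_", cmp)]]
    out[[paste0("norm_", cmp)]] <- ifelse(out$protein_quantified,
                                          normalized_glycosylation(g, p), g)
  }
  out
}
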