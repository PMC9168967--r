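# broom-style tidiers for fitted/filtered result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an FDR filtering result
#'
#' @param x An `fdr_result` from [fdr_filter()].
#' @param ... Unused.
#' @return The accepted PSM tibble with the level's threshold attached.
#' @export
tidy.fdr_result <- function(x, ...) {
  out <- x$accepted %||% tibble::tibble()
  out$fdr_level <- x$level
  out$score_threshold <- x$threshold
  out
}

#' @rdname tidy.fdr_result
#' @return For `glance()`: a one-row summary (level, alpha, threshold,
#'   estimated FDR, number accepted).
#' @export
glance.fdr_result <- function(x, ...) {
  tibble::tibble(level = x$level, alpha = x$alpha, threshold = x$threshold,
                 estimated_fdr = x$estimated_fdr, n_accepted = x$n_accepted)
}

#' Tidy a glycan structure
#'
#' @param x A `glycan_structure`.
#' @param ... Unused.
#' @return One-row tibble: canonical form, composition and feature vector.
#' @export
tidy.glycan_structure <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(canonical = x$canonical,
                   composition = serialize_composition(x$composition),
                   mass = composition_mass(x$composition)),
    classify_features(x)
  )
}
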