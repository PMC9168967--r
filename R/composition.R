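#' Glycan compositions
#'
#' A glycan composition is a named integer vector counting the four
#' monosaccharides HexNAc, Hex, Fuc and NeuAc. The compact text form follows
#' the N/H/F/S convention used in glycoproteomics reports: `"N5H4F1S1"`
#' means HexNAc5 Hex4 Fuc1 NeuAc1; absent letters mean zero.
#'
#' @param HexNAc,Hex,Fuc,NeuAc Non-negative integer counts.
#' @return A named integer vector of length 4 with class `glycan_comp`.
#' @examples
#' glycan_comp(HexNAc = 2, Hex = 3)
#' parse_composition("N5H4F1S1")
#' @export
glycan_comp <- function(HexNAc = 0, Hex = 0, Fuc = 0, NeuAc = 0) {
  counts <- c(HexNAc = HexNAc, Hex = Hex, Fuc = Fuc, NeuAc = NeuAc)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("invalid composition: counts must be non-negative integers", call. = FALSE)
  }
  structure(as.integer(counts),
            names = c("HexNAc", "Hex", "Fuc", "NeuAc"),
            class = "glycan_comp")
}

comp_add <- function(a, b) {
  glycan_comp(a[["HexNAc"]] + b[["HexNAc"]], a[["Hex"]] + b[["Hex"]],
              a[["Fuc"]] + b[["Fuc"]], a[["NeuAc"]] + b[["NeuAc"]])
}

comp_subtract <- function(a, b) {
  d <- unclass(a) - unclass(b)
  if (any(d < 0)) return(NULL)
  glycan_comp(d[["HexNAc"]], d[["Hex"]], d[["Fuc"]], d[["NeuAc"]])
}

#' @export
print.glycan_comp <- function(x, ...) {
  cat("<glycan composition> ", serialize_composition(x), "  (",
      format(composition_mass(x), nsmall = 4), " Da)\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a glycan composition
#'
#' Sum of residue (dehydrated) monosaccharide masses. The mass of the empty
#' composition is zero; mass is additive over compositions.
#'
#' @param comp A [glycan_comp()] or named count vector.
#' @return Mass in Da.
#' @examples
#' composition_mass(parse_composition("N2H3"))
#' @export
composition_mass <- function(comp) {
  counts <- comp[names(MONOSACCHARIDE_MASS)]
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("invalid composition: counts must be non-negative", call. = FALSE)
  }
  sum(counts * MONOSACCHARIDE_MASS)
}

#' Oxonium (B ion) m/z for a glycan fragment
#'
#' B ions retain the non-reducing end of the glycan and are observed as
#' protonated dehydrated fragments, so the m/z is simply the residue-mass sum
#' plus `charge` protons, divided by the charge. The HexNAc2 B ion computes
#' to 407.17 (2 dp), the key diagnostic for LacdiNAc branches.
#'
#' @param fragment A non-empty [glycan_comp()].
#' @param charge Positive integer charge (B ions are usually singly charged).
#' @return m/z in Th.
#' @examples
#' oxonium_mz(glycan_comp(HexNAc = 2))          # 407.17
#' oxonium_mz(glycan_comp(HexNAc = 2, NeuAc = 1)) # 698.26
#' @export
oxonium_mz <- function(fragment, charge = 1L) {
  if (sum(fragment) == 0) stop("empty fragment has no oxonium ion", call. = FALSE)
  if (charge < 1) stop("charge must be a positive integer", call. = FALSE)
  (composition_mass(fragment) + charge * PROTON_MASS) / charge
}

#' @rdname glycan_comp
#' @param text Composition string such as `"N4H5F1"`.
#' @export
parse_composition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  if (!nzchar(txt)) stop("empty composition string", call. = FALSE)
  tokens <- stringr::str_match_all(txt, "([A-Za-z])(\\d+)")[[1]]
  consumed <- paste0(tokens[, 1], collapse = "")
  if (!identical(consumed, txt)) {
    stop("malformed composition string: ", sQuote(text), call. = FALSE)
  }
  key <- c(N = "HexNAc", H = "Hex", F = "Fuc", S = "NeuAc")
  counts <- c(HexNAc = 0L, Hex = 0L, Fuc = 0L, NeuAc = 0L)
  for (i in seq_len(nrow(tokens))) {
    letter <- tokens[i, 2]
    if (!letter %in% names(key)) {
      stop("unknown monosaccharide letter ", sQuote(letter), " in ",
           sQuote(text), call. = FALSE)
    }
    counts[[key[[letter]]]] <- counts[[key[[letter]]]] + as.integer(tokens[i, 3])
  }
  glycan_comp(counts[["HexNAc"]], counts[["Hex"]], counts[["Fuc"]], counts[["NeuAc"]])
}

#' @rdname glycan_comp
#' @param comp A [glycan_comp()].
#' @export
serialize_composition <- function(comp) {
  letters <- c(HexNAc = "N", Hex = "H", Fuc = "F", NeuAc = "S")
  nz <- names(letters)[comp[names(letters)] > 0]
  if (length(nz) == 0) return("")
  paste0(letters[nz], comp[nz], collapse = "")
}

#' Enumerate glycan compositions matching a residue mass
#'
#' Finds all compositions (within the configured count caps) whose residue
#' mass matches `mass` within `tol_ppm`. Used to decompose the precursor
#' minus peptide mass remainder into candidate glycan compositions.
#'
#' @param mass Target residue mass in Da.
#' @param tol_ppm Relative tolerance in ppm (default 10, the precursor
#'   tolerance used throughout).
#' @param max_counts Named caps per monosaccharide.
#' @return A tibble with columns `composition` (string) and `mass`.
#' @export
find_compositions <- function(mass, tol_ppm = 10,
                              max_counts = c(HexNAc = 8L, Hex = 12L,
                                             Fuc = 3L, NeuAc = 3L)) {
  tol <- mass * tol_ppm * 1e-6
  out <- list()
  m <- MONOSACCHARIDE_MASS
  for (s in 0:max_counts[["NeuAc"]]) {
    for (f in 0:max_counts[["Fuc"]]) {
      for (n in 0:max_counts[["HexNAc"]]) {
        rest <- mass - s * m[["NeuAc"]] - f * m[["Fuc"]] - n * m[["HexNAc"]]
        if (rest < -tol) break
        h <- round(rest / m[["Hex"]])
        if (h < 0 || h > max_counts[["Hex"]]) next
        total <- s * m[["NeuAc"]] + f * m[["Fuc"]] + n * m[["HexNAc"]] + h * m[["Hex"]]
        if (abs(total - mass) <= tol) {
          out[[length(out) + 1L]] <- tibble::tibble(
            composition = serialize_composition(glycan_comp(n, h, f, s)),
            mass = total
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(composition = character(), mass = numeric()))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}
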