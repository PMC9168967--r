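#' Monoisotopic mass constants
#'
#' Residue (dehydrated) monoisotopic masses of the four monosaccharides
#' handled by the package, plus the proton and water masses used throughout.
#' With these values the protonated HexNAc2 oxonium ion computes to
#' m/z 407.17 at two decimals, the conventional diagnostic for
#' LacdiNAc-containing branches.
#'
#' @format Named numeric vectors, masses in Da.
#' @name mass-constants
NULL

#' @rdname mass-constants
#' @export
MONOSACCHARIDE_MASS <- c(
  HexNAc = 203.079373,
  Hex    = 162.052824,
  Fuc    = 146.057909,
  NeuAc  = 291.095417
)

#' @rdname mass-constants
#' @export
PROTON_MASS <- 1.007276

#' @rdname mass-constants
#' @export
WATER_MASS <- 18.010565

# Monoisotopic amino-acid residue masses (I/L share a mass but are kept as
# distinct letters; reports flag them as indistinguishable).
AA_RESIDUE_MASS <- c(
  G = 57.021464,  A = 71.037114,  S = 87.032028,  P = 97.052764,
  V = 99.068414,  T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

# Modification deltas (Da)
MOD_MASS <- c(
  carbamidomethyl = 57.021464,  # static on C
  tmt10           = 229.162932, # N-terminus (static) and K
  oxidation       = 15.9949,    # variable on M
  acetyl          = 42.010565   # variable on protein N-terminus
)

#' TMT 10-plex reporter ion m/z values
#'
#' Monoisotopic singly charged reporter ion m/z for the 10-plex reagents.
#' The four channels used by the liver-cancer study design are 129C
#' (HCC paracancer), 130C (ICC paracancer), 130N (HCC tumor) and
#' 131 (ICC tumor).
#'
#' @export
TMT10_REPORTER_MZ <- c(
  `126`  = 126.127726,
  `127N` = 127.124761,
  `127C` = 127.131081,
  `128N` = 128.128116,
  `128C` = 128.134436,
  `129N` = 129.131471,
  `129C` = 129.137790,
  `130N` = 130.134825,
  `130C` = 130.141145,
  `131`  = 131.138180
)

#' Study channels and group mapping
#'
#' Channel order is fixed everywhere in the package to avoid mapping bugs:
#' 129C, 130C, 130N, 131 corresponding to groups HCCP, ICCP, HCC, ICC
#' (P suffix = paracancer tissue).
#'
#' @export
STUDY_CHANNELS <- c(`129C` = "HCCP", `130C` = "ICCP", `130N` = "HCC", `131` = "ICC")

#' Default oxonium screening list
#'
#' Low-mass glycan oxonium ions (m/z, singly charged) used by the
#' two-of-top-ten spectrum screen: the HexNAc fragment series, the
#' HexNAc1Hex1 ion, the NeuAc pair and the LacdiNAc-diagnostic HexNAc2 ion.
#'
#' @export
DEFAULT_OXONIUM_MZ <- c(
  HexNAc_f126 = 126.055, HexNAc_f138 = 138.055, HexNAc_f168 = 168.066,
  HexNAc_f186 = 186.076, HexNAc = 204.087, HexNAcHex = 366.140,
  NeuAc_mH2O = 274.092, NeuAc = 292.103, HexNAc2 = 407.166
)
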