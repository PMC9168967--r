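# Independent oracles: deliberately written with different algorithms than
# the package implementation so they can serve as cross-checks.

# residue masses restated independently (from the standard monoisotopic table)
ORACLE_RES <- c(HexNAc = 203.0793725, Hex = 162.0528234,
                Fuc = 146.0579088, NeuAc = 291.0954165)
ORACLE_PROTON <- 1.00727646

oracle_comp_mass <- function(n = 0, h = 0, f = 0, s = 0) {
  n * ORACLE_RES[["HexNAc"]] + h * ORACLE_RES[["Hex"]] +
    f * ORACLE_RES[["Fuc"]] + s * ORACLE_RES[["NeuAc"]]
}

# brute-force structure enumeration: grid over per-motif counts, filtered by
# exact composition match (independent of the recursive enumerator)
oracle_enumerate <- function(comp_str, library, max_antennae = 4,
                             max_mannose = 6) {
  comp <- parse_composition(comp_str)
  total <- sum(comp)
  cores <- core_motifs()
  bc <- lapply(library$composition, parse_composition)
  res <- character(0)
  for (ci in seq_len(nrow(cores))) {
    ccomp <- parse_composition(cores$composition[ci])
    resid <- unclass(comp) - unclass(ccomp)
    if (any(resid < 0)) next
    caps <- vapply(bc, function(b) {
      nz <- which(unclass(b) > 0)
      if (length(nz) == 0) return(0L)
      as.integer(min(resid[nz] %/% unclass(b)[nz]))
    }, integer(1))
    grid <- do.call(expand.grid, lapply(caps, function(k) 0:k))
    for (g in seq_len(nrow(grid))) {
      counts <- as.integer(grid[g, ])
      tot <- Reduce(`+`, Map(function(b, k) unclass(b) * k, bc, counts),
                    accumulate = FALSE)
      if (!all(tot == resid)) next
      ant <- sum(counts[library$family != "Mannose"])
      man <- sum(counts[library$family == "Mannose"])
      if (ant > max_antennae || man > max_mannose) next
      res <- c(res, paste0(cores$kind[ci], "(",
                           paste(sort(rep(library$name, counts)), collapse = ","),
                           ")"))
    }
  }
  sort(unique(res))
}

# regex-based tryptic digestion oracle (0 missed cleavages)
oracle_tryptic_fragments <- function(sequence) {
  pieces <- strsplit(gsub("(?<=[KR])(?!P)", "\n", sequence, perl = TRUE), "\n")[[1]]
  pieces[nzchar(pieces)]
}

# full-protein regex oracle for sequon positions
oracle_sequons <- function(protein) {
  hits <- gregexpr("(?=N[^P][ST])", protein, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

# brute-force FDR threshold: scan every observed score as a cutoff
oracle_fdr_threshold <- function(score, decoy, alpha) {
  cand <- sort(unique(score))
  for (s in cand) {
    fdr <- sum(decoy & score >= s) / max(1, sum(!decoy & score >= s))
    if (fdr <= alpha) return(s)
  }
  Inf
}

# independent rule-by-rule categorization oracle (flat if-chain, no helper
# reuse from the package)
oracle_categorize <- function(r_ii, r_hh, r_ih, r_pp, n_ii, n_hh, cutoff) {
  out_band <- function(r) r >= cutoff || r <= 1 / cutoff
  if (out_band(r_pp)) return("paracancer_differs")
  ic <- out_band(r_ii); hc <- out_band(r_hh)
  if ((ic || hc) && (!ic || !out_band(n_ii)) && (!hc || !out_band(n_hh))) {
    return("protein_level_only")
  }
  if (r_ii >= cutoff && r_hh >= cutoff) return("common_up")
  if (r_ii <= 1 / cutoff && r_hh <= 1 / cutoff) return("common_down")
  if ((r_ii >= cutoff && r_hh <= 1 / cutoff) ||
      (r_ii <= 1 / cutoff && r_hh >= cutoff)) return("opposite")
  if (ic && !hc) return(if (r_ii >= cutoff) "icc_specific_up" else "icc_specific_down")
  if (hc && !ic) return(if (r_hh >= cutoff) "hcc_specific_up" else "hcc_specific_down")
  "unchanged"
}
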