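# MS2 run handling. A run is a tibble with one row per scan:
#   scan_id, energy ("low"/"high"), precursor_mz, precursor_charge, rt,
#   peaks (list column of tibbles with mz, intensity sorted by mz).
# The on-disk formats are an internal JSON layout (canonical, written by the
# generator) and mzML (read through mzR when installed).

new_ms2_spectrum <- function(scan_id, energy, precursor_mz, precursor_charge,
                             rt, mz, intensity) {
  ord <- order(mz)
  tibble::tibble(
    scan_id = as.integer(scan_id), energy = energy,
    precursor_mz = precursor_mz, precursor_charge = as.integer(precursor_charge),
    rt = rt,
    peaks = list(tibble::tibble(mz = mz[ord], intensity = intensity[ord]))
  )
}

#' Read an MS2 run
#'
#' @param path Path to a run file.
#' @param format `"json"` (the package's internal scan layout, the format
#'   written by [write_run()]) or `"mzML"` (requires the mzR package).
#'   Guessed from the file extension by default.
#' @return Run tibble ordered by scan id. Scans without precursor information
#'   are skipped with a warning. Scans lacking an explicit collision-energy
#'   tag are assigned low/high by the alternating-scan heuristic (with a
#'   warning).
#' @export
read_run <- function(path, format = c("auto", "json", "mzML")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML" else "json"
  }
  if (format == "mzML") return(read_run_mzml(path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  scans <- purrr::compact(purrr::map(raw$scans, function(s) {
    if (is.null(s$precursor_mz) || is.null(s$precursor_charge)) {
      warning("scan ", s$scan_id, " lacks precursor information; skipped",
              call. = FALSE)
      return(NULL)
    }
    new_ms2_spectrum(s$scan_id, s$energy %||% NA_character_, s$precursor_mz,
                     s$precursor_charge, s$rt %||% NA_real_,
                     as.numeric(s$mz), as.numeric(s$intensity))
  }))
  run <- dplyr::arrange(dplyr::bind_rows(scans), .data$scan_id)
  fill_energy_tags(run)
}

read_run_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  hdr <- hdr[hdr$msLevel == 2L, , drop = FALSE]
  scans <- purrr::map(seq_len(nrow(hdr)), function(i) {
    row <- hdr[i, ]
    if (is.na(row$precursorMZ) || row$precursorMZ <= 0) {
      warning("scan ", row$acquisitionNum, " lacks precursor information; skipped",
              call. = FALSE)
      return(NULL)
    }
    pk <- mzR::peaks(h, row$seqNum)
    energy <- if (!is.null(row$collisionEnergy) && !is.na(row$collisionEnergy)) {
      if (row$collisionEnergy <= 25) "low" else "high"
    } else NA_character_
    new_ms2_spectrum(row$acquisitionNum, energy, row$precursorMZ,
                     row$precursorCharge, row$retentionTime,
                     pk[, 1], pk[, 2])
  })
  run <- dplyr::arrange(dplyr::bind_rows(purrr::compact(scans)), .data$scan_id)
  fill_energy_tags(run)
}

fill_energy_tags <- function(run) {
  if (nrow(run) == 0 || !any(is.na(run$energy))) return(run)
  warning("collision-energy tags missing; assigning by alternating-scan heuristic",
          call. = FALSE)
  run$energy[is.na(run$energy)] <-
    ifelse(seq_len(nrow(run))[is.na(run$energy)] %% 2L == 1L, "low", "high")
  run
}

#' Write an MS2 run in the internal JSON layout
#'
#' @param run Run tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  scans <- purrr::map(seq_len(nrow(run)), function(i) {
    pk <- run$peaks[[i]]
    list(scan_id = run$scan_id[i], energy = run$energy[i],
         precursor_mz = run$precursor_mz[i],
         precursor_charge = run$precursor_charge[i],
         rt = run$rt[i], mz = pk$mz, intensity = pk$intensity)
  })
  jsonlite::write_json(list(scans = scans), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pair low- and high-energy scans of the same precursor
#'
#' Greedy pairing: low-energy scans are taken in scan order and matched to
#' the unclaimed high-energy scan nearest in retention time whose precursor
#' m/z agrees within `ppm_tol` and whose charge is equal. Unpaired scans are
#' dropped (counts reported via message).
#'
#' @param run Run tibble.
#' @param ppm_tol Precursor m/z agreement tolerance in ppm (default 10).
#' @return Tibble with columns `pair_id`, `precursor_mz`, `precursor_charge`,
#'   `precursor_neutral_mass`, `rt`, `low_scan`, `high_scan`, `low_peaks`,
#'   `high_peaks`.
#' @export
pair_spectra <- function(run, ppm_tol = 10) {
  lows <- run[run$energy == "low", ]
  highs <- run[run$energy == "high", ]
  taken <- rep(FALSE, nrow(highs))
  out <- list()
  for (i in seq_len(nrow(lows))) {
    dppm <- abs(highs$precursor_mz - lows$precursor_mz[i]) /
      lows$precursor_mz[i] * 1e6
    ok <- which(!taken & dppm <= ppm_tol &
                  highs$precursor_charge == lows$precursor_charge[i])
    if (length(ok) == 0) next
    j <- ok[order(abs(highs$rt[ok] - lows$rt[i]), highs$scan_id[ok])][1]
    taken[j] <- TRUE
    z <- lows$precursor_charge[i]
    out[[length(out) + 1L]] <- tibble::tibble(
      pair_id = length(out) + 1L,
      precursor_mz = lows$precursor_mz[i],
      precursor_charge = z,
      precursor_neutral_mass = lows$precursor_mz[i] * z - z * PROTON_MASS,
      rt = lows$rt[i],
      low_scan = lows$scan_id[i], high_scan = highs$scan_id[j],
      low_peaks = list(lows$peaks[[i]]), high_peaks = list(highs$peaks[[j]])
    )
  }
  n_drop <- (nrow(lows) - length(out)) + sum(!taken)
  if (n_drop > 0) message(n_drop, " unpaired scan(s) dropped")
  dplyr::bind_rows(out)
}

#' Oxonium-ion spectrum screen
#'
#' Takes the `top_n` most intense peaks and counts how many reference
#' oxonium ions they match at `tol_ppm`; the spectrum passes when at least
#' `min_matches` are found. This is the classic two-of-top-ten glycopeptide
#' spectrum filter.
#'
#' @param peaks Peak tibble (`mz`, `intensity`).
#' @param min_matches Minimum distinct oxonium ions matched (default 2).
#' @param top_n Number of top-intensity peaks examined (default 10).
#' @param oxonium Reference oxonium m/z vector (default [DEFAULT_OXONIUM_MZ]).
#' @param tol_ppm Match tolerance in ppm (default 20).
#' @return List with `pass` (logical) and `matched` (named m/z vector).
#' @export
oxonium_screen <- function(peaks, min_matches = 2L, top_n = 10L,
                           oxonium = DEFAULT_OXONIUM_MZ, tol_ppm = 20) {
  stopifnot(nrow(peaks) > 0)
  top <- peaks[order(-peaks$intensity), ][seq_len(min(top_n, nrow(peaks))), ]
  hit <- vapply(oxonium, function(m) {
    any(abs(top$mz - m) / m * 1e6 <= tol_ppm)
  }, logical(1))
  list(pass = sum(hit) >= min_matches, matched = oxonium[hit])
}

#' Extract TMT reporter intensities
#'
#' For each configured channel, picks the most intense peak within
#' `tolerance` of the channel's reporter m/z; a channel with no peak in the
#' window is recorded as `NA` (absent), never zero.
#'
#' @param peaks Peak tibble of the high-energy scan.
#' @param channels Character vector of channel names (default the four study
#'   channels 129C, 130C, 130N, 131).
#' @param tolerance Absolute m/z window half-width (default 0.003, suited to
#'   50K-resolution MS2).
#' @return Named numeric vector of intensities (NA for absent channels).
#' @export
extract_reporters <- function(peaks, channels = names(STUDY_CHANNELS),
                              tolerance = 0.003) {
  vapply(channels, function(ch) {
    m <- TMT10_REPORTER_MZ[[ch]]
    in_win <- which(abs(peaks$mz - m) <= tolerance)
    if (length(in_win) == 0) return(NA_real_)
    max(peaks$intensity[in_win])
  }, numeric(1))
}

# Vectorized peak matching: for each theoretical m/z, the index of the
# closest observed peak within tol_ppm (NA when none). obs_mz must be sorted.
match_peaks <- function(obs_mz, theo_mz, tol_ppm = 20) {
  if (length(obs_mz) == 0 || length(theo_mz) == 0) {
    return(rep(NA_integer_, length(theo_mz)))
  }
  lo <- findInterval(theo_mz, obs_mz)
  hi <- pmin(lo + 1L, length(obs_mz))
  lo <- pmax(lo, 1L)
  d_lo <- abs(obs_mz[lo] - theo_mz)
  d_hi <- abs(obs_mz[hi] - theo_mz)
  best <- ifelse(d_lo <= d_hi, lo, hi)
  d <- pmin(d_lo, d_hi)
  ifelse(d / theo_mz * 1e6 <= tol_ppm, best, NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a result table as TSV
#'
#' Plain tab-separated export (no quoting, no row names; m/z and ratio
#' columns at full precision) for PSM, quantification, manifest and category
#' tables.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
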