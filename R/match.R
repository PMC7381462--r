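#' Match one spectrum against a lipid target library
#'
#' For every target, finds the centroid with smallest absolute ppm
#' deviation within `+/- window_ppm` and records its intensity and signed
#' deviation `(observed - expected)/expected * 1e6`. Targets with no peak
#' in the window get intensity 0 and an absent (`NA`) deviation. When two
#' candidate peaks are equidistant in ppm the more intense one wins
#' (deterministic tie-break). A peak assigned to more than one target is
#' flagged via `shared_peak`.
#'
#' @param peaks Data frame of centroids with columns `mz` (strictly
#'   increasing) and `intensity` (>= 0).
#' @param library Lipid targets (`name`, `lipid_class`, `expected_mz`).
#' @param window_ppm Half-width of the search window in ppm. The default
#'   (10 ppm) is twice the downstream 5 ppm mean-deviation filter, so
#'   drifting lipids are observed and then filtered rather than lost.
#' @return A tibble with one row per target: `lipid`, `lipid_class`,
#'   `expected_mz`, `intensity`, `deviation_ppm`, `shared_peak`.
#' @examples
#' pk <- tibble::tibble(mz = c(400.1, 760.5889), intensity = c(5, 9))
#' lib <- tibble::tibble(name = "PC(34:1)", lipid_class = "PC",
#'                       expected_mz = 760.5851)
#' match_spectrum(pk, lib)
#' @export
match_spectrum <- function(peaks, library, window_ppm = 10) {
  if (window_ppm <= 0) abort("`window_ppm` must be positive.")
  if (nrow(library) == 0) abort("`library` must be nonempty.")
  out <- tibble(
    lipid = library$name,
    lipid_class = library$lipid_class,
    expected_mz = library$expected_mz,
    intensity = 0,
    deviation_ppm = NA_real_,
    shared_peak = FALSE
  )
  if (nrow(peaks) == 0) {
    warn("Empty spectrum: all targets unmatched.")
    return(out)
  }
  if (is.unsorted(peaks$mz, strictly = TRUE)) {
    abort("Spectrum peaks must be strictly increasing in m/z.")
  }
  if (any(peaks$intensity < 0)) abort("Peak intensities must be >= 0.")

  w <- window_ppm * 1e-6
  lo <- findInterval(library$expected_mz * (1 - w), peaks$mz,
                     left.open = TRUE) + 1L
  hi <- findInterval(library$expected_mz * (1 + w), peaks$mz)
  chosen <- rep(NA_integer_, nrow(library))
  for (j in which(hi >= lo)) {
    cand <- lo[j]:hi[j]
    dev <- (peaks$mz[cand] - library$expected_mz[j]) /
      library$expected_mz[j] * 1e6
    best <- cand[order(abs(dev), -peaks$intensity[cand])][1L]
    chosen[j] <- best
    out$intensity[j] <- peaks$intensity[best]
    out$deviation_ppm[j] <- (peaks$mz[best] - library$expected_mz[j]) /
      library$expected_mz[j] * 1e6
  }
  dup <- chosen[!is.na(chosen)][duplicated(chosen[!is.na(chosen)])]
  out$shared_peak <- !is.na(chosen) & chosen %in% dup
  out
}

#' Match every spectrum in a cohort
#'
#' Applies [match_spectrum()] to each sample in a long peak table and binds
#' the per-lipid signals with sample metadata.
#'
#' @param spectra Long peak tibble (`sample_id`, `role`, `batch`, `mz`,
#'   `intensity`), e.g. from [simulate_spectra()] or [read_peaklists()].
#' @inheritParams match_spectrum
#' @return A tibble of lipid signals: `sample_id`, `role`, `batch`,
#'   `lipid`, `intensity`, `deviation_ppm`, `shared_peak`.
#' @export
match_cohort <- function(spectra, library, window_ppm = 10) {
  stopifnot(all(c("sample_id", "role", "mz", "intensity") %in%
                  names(spectra)))
  bad <- setdiff(unique(spectra$role), SAMPLE_ROLES)
  if (length(bad) > 0) {
    abort(paste0("Unknown sample role(s): ", paste(bad, collapse = ", ")))
  }
  pieces <- spectra |>
    dplyr::group_split(.data$sample_id)
  purrr::map_dfr(pieces, function(pk) {
    sig <- match_spectrum(pk[, c("mz", "intensity")], library, window_ppm)
    tibble(
      sample_id = pk$sample_id[1],
      role = pk$role[1],
      batch = if ("batch" %in% names(pk)) pk$batch[1] else "B1",
      lipid = sig$lipid,
      intensity = sig$intensity,
      deviation_ppm = sig$deviation_ppm,
      shared_peak = sig$shared_peak
    )
  })
}
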