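#' Quality-control filters, normalisation and centering
#'
#' The four QC filters are applied in a fixed order — mass deviation, blank
#' ratio, missingness, QC dilution-series linearity — followed by
#' total-signal (TIC) normalisation and per-cohort mean centering. All four
#' thresholds are strict inequalities: a lipid is removed when its mean
#' |mass deviation| is *greater than* 5 ppm, its sample/blank intensity
#' ratio is *less than* 5, its zero fraction is *greater than* 10%, or its
#' dilution-series Pearson r is *less than* 0.9.
#'
#' @name qc_filters
NULL

#' @describeIn qc_filters Remove lipids whose mean absolute ppm deviation
#'   over matched samples exceeds `max_ppm`. Lipids never matched in any
#'   sample have no deviation and are removed (reported distinctly). With
#'   `use_signed = TRUE` the signed mean is thresholded on its absolute
#'   value instead (a signed mean can hide large symmetric errors, so the
#'   absolute mean is the default).
#' @param m A `feature_matrix` of subject samples.
#' @param max_ppm Mass-deviation threshold (ppm).
#' @param use_signed Use the signed mean deviation instead of the mean
#'   absolute deviation.
#' @export
filter_mass_deviation <- function(m, max_ppm = 5, use_signed = FALSE) {
  dev <- if (use_signed) {
    abs(colMeans(m$deviation, na.rm = TRUE))
  } else {
    colMeans(abs(m$deviation), na.rm = TRUE)
  }
  never <- colSums(!is.na(m$deviation)) == 0
  removed <- colnames(m$intensity)[never | (!is.na(dev) & dev > max_ppm)]
  note <- if (any(never)) {
    paste0("never matched: ",
           paste(colnames(m$intensity)[never], collapse = ", "))
  } else {
    NA_character_
  }
  m <- append_report(m, "mass_deviation", ncol(m$intensity), removed,
                     max_ppm, note)
  drop_lipids(m, removed)
}

#' @describeIn qc_filters Remove lipids whose mean sample intensity is less
#'   than `min_ratio` times the mean blank intensity. Lipids absent from
#'   the blanks (blank mean 0) have an infinite ratio and are retained.
#' @param blanks A `feature_matrix` built from blank spectra over the same
#'   library.
#' @param min_ratio Required sample/blank mean intensity ratio.
#' @export
filter_blank_ratio <- function(m, blanks, min_ratio = 5) {
  if (nrow(blanks$intensity) == 0) abort("`blanks` must be nonempty.")
  common <- colnames(m$intensity)
  if (!all(common %in% colnames(blanks$intensity))) {
    abort("Blank matrix lacks some lipid columns of `m`.")
  }
  sample_mean <- colMeans(m$intensity)
  blank_mean <- colMeans(blanks$intensity[, common, drop = FALSE])
  removed <- common[sample_mean < min_ratio * blank_mean]
  clean_blank <- blank_mean == 0 & sample_mean > 0
  note <- if (any(clean_blank)) {
    sprintf("%d lipids with zero blank signal retained", sum(clean_blank))
  } else {
    NA_character_
  }
  m <- append_report(m, "blank_ratio", ncol(m$intensity), removed,
                     min_ratio, note)
  drop_lipids(m, removed)
}

#' @describeIn qc_filters Remove lipids with zero intensity in more than
#'   `max_zero_frac` of samples.
#' @param max_zero_frac Maximum tolerated fraction of zero (undetected)
#'   values per lipid.
#' @export
filter_missingness <- function(m, max_zero_frac = 0.10) {
  zero_frac <- colMeans(m$intensity == 0)
  removed <- colnames(m$intensity)[zero_frac > max_zero_frac]
  m <- append_report(m, "missingness", ncol(m$intensity), removed,
                     max_zero_frac)
  drop_lipids(m, removed)
}

#' @describeIn qc_filters Remove lipids whose intensity does not increase
#'   linearly with serum concentration in the QC dilution series: Pearson r
#'   between per-replicate intensity and serum fraction (1.0/0.5/0.25),
#'   computed over all replicates, must reach `min_r`. Zero-variance
#'   (flat) lipids have undefined r and are removed — a flat signal cannot
#'   show the required linear increase.
#' @param qc A `feature_matrix` built from the QC roles
#'   (`qc100`/`qc50`/`qc25`); its rows carry serum fractions.
#' @param min_r Minimum Pearson correlation with serum fraction.
#' @export
filter_qc_linearity <- function(m, qc, min_r = 0.9) {
  frac <- qc$serum_fraction
  if (is.null(frac)) {
    abort("`qc` must be built from QC roles (qc100/qc50/qc25).")
  }
  if (length(unique(frac)) < 2) {
    abort("Need QC spectra at >= 2 dilution levels.")
  }
  common <- colnames(m$intensity)
  if (!all(common %in% colnames(qc$intensity))) {
    abort("QC matrix lacks some lipid columns of `m`.")
  }
  r <- vapply(common, function(l) {
    y <- qc$intensity[, l]
    if (sd(y) == 0) NA_real_ else cor(y, frac)
  }, numeric(1))
  removed <- common[is.na(r) | r < min_r]
  note <- if (anyNA(r)) {
    sprintf("%d lipids with zero QC variance (undefined r) removed",
            sum(is.na(r)))
  } else {
    NA_character_
  }
  m <- append_report(m, "qc_linearity", ncol(m$intensity), removed,
                     min_r, note)
  drop_lipids(m, removed)
}

#' @describeIn qc_filters Total-signal normalisation: each sample's
#'   intensities are divided by the sample's total over the retained
#'   lipids, so every row sums to 1. Idempotent. Errors on an all-zero
#'   sample.
#' @export
normalize_tic <- function(m) {
  totals <- rowSums(m$intensity)
  if (any(totals == 0)) {
    abort(paste0("All-zero sample(s): ",
                 paste(rownames(m$intensity)[totals == 0], collapse = ", ")))
  }
  m$intensity <- m$intensity / totals
  m$transform_log <- c(m$transform_log, "tic_normalized")
  m
}

#' @describeIn qc_filters Per-cohort mean centering: subtracts each lipid
#'   column's mean, so column means are 0. Cohorts are centered
#'   independently of one another.
#' @export
mean_center <- function(m) {
  m$intensity <- sweep(m$intensity, 2, colMeans(m$intensity))
  m$transform_log <- c(m$transform_log, "mean_centered")
  m
}

#' Run the full spectral-processing and QC chain for one cohort
#'
#' Matches all spectra against the library, assembles the subject, blank
#' and QC matrices, applies the four QC filters in order, then TIC
#' normalisation and mean centering.
#'
#' @param spectra Long peak tibble covering subject, blank and QC roles.
#' @param library Lipid target library.
#' @param window_ppm Matching window (ppm).
#' @param max_ppm,min_ratio,max_zero_frac,min_r Filter thresholds; see
#'   [qc_filters].
#' @param normalize,center Toggle the final transforms.
#' @param cohort_id Cohort label for the matrices.
#' @return A list with the processed subject `matrix` (a
#'   `feature_matrix`), the `blanks` and `qc` matrices, and the filter
#'   `report`.
#' @export
process_cohort <- function(spectra, library, window_ppm = 10,
                           max_ppm = 5, min_ratio = 5,
                           max_zero_frac = 0.10, min_r = 0.9,
                           normalize = TRUE, center = TRUE,
                           cohort_id = "cohort") {
  signals <- match_cohort(spectra, library, window_ppm)
  samples <- build_matrix(signals, "sample", cohort_id)
  blanks <- build_matrix(signals, "blank", cohort_id)
  qc <- build_matrix(signals, c("qc100", "qc50", "qc25"), cohort_id)
  m <- samples |>
    filter_mass_deviation(max_ppm) |>
    filter_blank_ratio(blanks, min_ratio) |>
    filter_missingness(max_zero_frac) |>
    filter_qc_linearity(qc, min_r)
  if (normalize) m <- normalize_tic(m)
  if (center) m <- mean_center(m)
  list(matrix = m, blanks = blanks, qc = qc, report = filter_report(m))
}
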