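#' Assemble a feature matrix from lipid signals
#'
#' Pivots matched signals into a samples x lipids intensity matrix with a
#' parallel matrix of signed ppm deviations (`NA` where a lipid was not
#' matched in that sample). The object also carries an append-only
#' transform log and the accumulating QC filter report.
#'
#' @param signals Signal tibble from [match_cohort()].
#' @param roles Role(s) to keep (e.g. `"sample"`, `"blank"`, or the three
#'   QC roles together).
#' @param cohort_id Identifier stored with the matrix.
#' @return A `feature_matrix` object.
#' @export
build_matrix <- function(signals, roles = "sample", cohort_id = "cohort") {
  stopifnot(all(roles %in% SAMPLE_ROLES))
  sub <- signals[signals$role %in% roles, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(paste0("No signals with role(s): ", paste(roles, collapse = ", ")))
  }
  if (anyDuplicated(sub[, c("sample_id", "lipid")])) {
    abort("Duplicate (sample, lipid) signals; one signal per pair expected.")
  }
  ids <- unique(sub$sample_id)
  lipids <- unique(sub$lipid)
  intensity <- matrix(0, length(ids), length(lipids),
                      dimnames = list(ids, lipids))
  deviation <- matrix(NA_real_, length(ids), length(lipids),
                      dimnames = list(ids, lipids))
  ridx <- match(sub$sample_id, ids)
  cidx <- match(sub$lipid, lipids)
  intensity[cbind(ridx, cidx)] <- sub$intensity
  deviation[cbind(ridx, cidx)] <- sub$deviation_ppm

  role_by_sample <- sub$role[!duplicated(sub$sample_id)]
  names(role_by_sample) <- ids
  serum_fraction <- NULL
  if (all(roles %in% names(QC_FRACTIONS))) {
    serum_fraction <- QC_FRACTIONS[role_by_sample]
    names(serum_fraction) <- ids
  }
  new_feature_matrix(intensity, deviation, cohort_id = cohort_id,
                     roles = roles, sample_roles = role_by_sample,
                     serum_fraction = serum_fraction)
}

new_feature_matrix <- function(intensity, deviation = NULL,
                               cohort_id = "cohort", roles = "sample",
                               sample_roles = NULL, serum_fraction = NULL,
                               transform_log = character(),
                               filter_report = NULL) {
  stopifnot(is.matrix(intensity))
  if (is.null(deviation)) {
    deviation <- matrix(NA_real_, nrow(intensity), ncol(intensity),
                        dimnames = dimnames(intensity))
  }
  stopifnot(identical(dim(intensity), dim(deviation)))
  if (anyDuplicated(rownames(intensity)) ||
      anyDuplicated(colnames(intensity))) {
    abort("Sample and lipid labels must be unique.")
  }
  structure(
    list(
      intensity = intensity, deviation = deviation,
      cohort_id = cohort_id, roles = roles,
      sample_roles = sample_roles, serum_fraction = serum_fraction,
      transform_log = transform_log,
      filter_report = filter_report %||% empty_filter_report()
    ),
    class = "feature_matrix"
  )
}

empty_filter_report <- function() {
  tibble(
    filter = character(), lipids_in = integer(), lipids_removed = integer(),
    threshold = numeric(), removed = list(), note = character()
  )
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensity)

#' @export
dimnames.feature_matrix <- function(x) dimnames(x$intensity)

#' Lipids retained in a feature matrix
#' @param m A `feature_matrix`.
#' @return Character vector of lipid (column) names.
#' @export
lipids <- function(m) colnames(m$intensity)

#' @export
as.matrix.feature_matrix <- function(x, ...) x$intensity

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d samples x %d lipids (%s)\n",
              x$cohort_id, nrow(x$intensity), ncol(x$intensity),
              paste(x$roles, collapse = "/")))
  if (length(x$transform_log) > 0) {
    cat("  transforms:", paste(x$transform_log, collapse = " -> "), "\n")
  }
  if (nrow(x$filter_report) > 0) {
    cat("  filters applied:", nrow(x$filter_report),
        "| lipids removed:", sum(x$filter_report$lipids_removed), "\n")
  }
  invisible(x)
}

#' @describeIn build_matrix Long tibble view of a `feature_matrix`
#'   (`sample_id`, `lipid`, `intensity`, `deviation_ppm`).
#' @param x A `feature_matrix`.
#' @param ... Unused.
#' @export
tidy.feature_matrix <- function(x, ...) {
  tibble(
    sample_id = rep(rownames(x$intensity), times = ncol(x$intensity)),
    lipid = rep(colnames(x$intensity), each = nrow(x$intensity)),
    intensity = as.vector(x$intensity),
    deviation_ppm = as.vector(x$deviation)
  )
}

# drop lipid columns, preserving metadata
drop_lipids <- function(m, remove) {
  keep <- setdiff(colnames(m$intensity), remove)
  m$intensity <- m$intensity[, keep, drop = FALSE]
  m$deviation <- m$deviation[, keep, drop = FALSE]
  m
}

append_report <- function(m, filter, lipids_in, removed, threshold,
                          note = NA_character_) {
  m$filter_report <- bind_rows(
    m$filter_report,
    tibble(filter = filter, lipids_in = lipids_in,
           lipids_removed = length(removed), threshold = threshold,
           removed = list(removed), note = note)
  )
  m
}

#' Filter report of a feature matrix
#' @param m A `feature_matrix`.
#' @return A tibble with one row per applied filter: `filter`,
#'   `lipids_in`, `lipids_removed`, `threshold`, `removed` (list column of
#'   names), `note`.
#' @export
filter_report <- function(m) m$filter_report
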