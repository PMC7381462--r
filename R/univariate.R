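#' Per-lipid generalised linear models against a clinical lipoprotein
#'
#' Fits one Gaussian-family GLM (intercept + single lipid predictor) per
#' lipid on the whole cohort (no train/test split), recording the slope,
#' the Pearson correlation and the two-sided p-value, and flagging lipids
#' passing the Bonferroni threshold `alpha / n_tests`.
#'
#' @param m Processed `feature_matrix` (or numeric matrix) of abundances.
#' @param y Clinical concentrations (mmol/L) aligned with rows, or a
#'   clinical table plus `target`.
#' @param target Column of `y` to use when `y` is a data frame.
#' @param n_tests Number of tests for the Bonferroni threshold; defaults
#'   to the number of lipids in `m`. Override (e.g. 125) to reproduce a
#'   fixed printed threshold.
#' @param alpha Family-wise error rate.
#' @param cohort_id Label stored in the results.
#' @return A tibble with one row per lipid: `lipid`, `target`,
#'   `coefficient`, `correlation`, `p_value`, `passes_bonferroni`,
#'   `cohort_id`; the threshold is attached as attribute
#'   `bonferroni_threshold`. Constant lipid columns are skipped with a
#'   warning.
#' @export
glm_per_lipid <- function(m, y, target = "TriG", n_tests = NULL,
                          alpha = 0.05, cohort_id = NULL) {
  x <- as.matrix(m)
  if (is.data.frame(y)) {
    y <- y[[target]][match(rownames(x), y$subject_id)]
  }
  if (length(y) != nrow(x)) abort("`y` must align with rows of `m`.")
  if (anyNA(x) || anyNA(y)) abort("No missing cells allowed.")
  cohort_id <- cohort_id %||%
    (if (inherits(m, "feature_matrix")) m$cohort_id else "cohort")
  thr <- bonferroni_threshold(n_tests %||% ncol(x), alpha)

  const <- apply(x, 2, sd) == 0
  if (any(const)) {
    warn(sprintf("%d constant lipid column(s) skipped.", sum(const)))
  }
  rows <- purrr::map(colnames(x)[!const], function(l) {
    fit <- glm(y ~ x[, l], family = gaussian())
    sm <- summary(fit)$coefficients
    tibble(
      lipid = l, target = target,
      coefficient = sm[2, 1],
      correlation = cor(x[, l], y),
      p_value = sm[2, 4]
    )
  })
  out <- bind_rows(rows) |>
    mutate(passes_bonferroni = .data$p_value < thr,
           cohort_id = cohort_id)
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' @param n_tests Number of tests (>= 1); e.g. 125 gives the threshold
#'   0.05/125 = 0.0004.
#' @param alpha Family-wise error rate.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(125) # 0.0004
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || n_tests < 1) {
    abort("`n_tests` must be a count >= 1.")
  }
  alpha / n_tests
}

#' Cross-cohort concordance of univariate association strengths
#'
#' Correlates per-lipid Pearson coefficients between two cohorts over the
#' lipids measured in both, and lists the lipids present in only one.
#' Concordance measures the *pattern* of associations: uniform attenuation
#' of one cohort's correlations leaves it near 1.
#'
#' @param results_a,results_b Tibbles from [glm_per_lipid()] (any tibbles
#'   keyed by `lipid` with a `correlation` column).
#' @return A list of class `concordance_result`: `r` (`NA` when fewer
#'   than 3 shared lipids), `n_shared`, `shared` (tibble with both
#'   correlation columns), `only_in_a`, `only_in_b`.
#' @export
concordance <- function(results_a, results_b) {
  shared <- inner_join(
    select(results_a, "lipid", correlation_a = "correlation"),
    select(results_b, "lipid", correlation_b = "correlation"),
    by = "lipid"
  )
  r <- if (nrow(shared) >= 3) {
    cor(shared$correlation_a, shared$correlation_b)
  } else {
    NA_real_
  }
  structure(
    list(
      r = r, n_shared = nrow(shared), shared = shared,
      only_in_a = setdiff(results_a$lipid, results_b$lipid),
      only_in_b = setdiff(results_b$lipid, results_a$lipid)
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result>\n")
  cat(sprintf("  r = %s over %d shared lipids\n",
              ifelse(is.na(x$r), "NA", sprintf("%.3f", x$r)), x$n_shared))
  cat(sprintf("  only in A: %d | only in B: %d\n",
              length(x$only_in_a), length(x$only_in_b)))
  invisible(x)
}
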