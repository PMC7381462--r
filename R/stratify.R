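#' Clinical cut-off scheme for the four lipoproteins
#'
#' Standard three-band clinical cut-offs (mmol/L): triglyceride Desirable
#' < 1.7, Borderline 1.7-2.2, Poor > 2.2; HDL runs the other way
#' (Desirable > 1.5, Borderline 1.1-1.5, Poor < 1.1); LDL 2.6/5.0; total
#' cholesterol 5.2/6.2. Values falling exactly on a boundary belong to the
#' Borderline band (the outer bounds are strict).
#'
#' @param hdl_poor_upper Upper bound of the HDL Poor band. Published
#'   tables sometimes garble this cut-off; 1.1 mmol/L is consistent with
#'   the Borderline band and is the default.
#' @return A tibble with columns `lipoprotein`, `lower`, `upper`,
#'   `direction`.
#' @export
clinical_cutoffs <- function(hdl_poor_upper = 1.1) {
  tibble(
    lipoprotein = CLINICAL_TARGETS,
    lower = c(1.7, hdl_poor_upper, 2.6, 5.2),
    upper = c(2.2, 1.5, 5.0, 6.2),
    direction = c("higher_worse", "lower_worse", "higher_worse",
                  "higher_worse")
  )
}

#' Assign clinical risk categories
#'
#' @param values Concentrations (mmol/L, > 0), vectorised.
#' @param lipoprotein One of `"TriG"`, `"HDL"`, `"LDL"`, `"TC"`.
#' @param scheme A cut-off scheme from [clinical_cutoffs()].
#' @return Factor with levels `Desirable`, `Borderline`, `Poor`.
#' @examples
#' assign_clinical(c(1.5, 1.7, 2.3), "TriG")
#' @export
assign_clinical <- function(values, lipoprotein = CLINICAL_TARGETS,
                            scheme = clinical_cutoffs()) {
  lipoprotein <- match.arg(lipoprotein)
  row <- scheme[scheme$lipoprotein == lipoprotein, ]
  if (nrow(row) != 1) abort("Scheme lacks this lipoprotein.")
  if (any(values <= 0)) abort("Concentrations must be positive.")
  lab <- if (row$direction == "higher_worse") {
    ifelse(values < row$lower, "Desirable",
           ifelse(values > row$upper, "Poor", "Borderline"))
  } else {
    ifelse(values > row$upper, "Desirable",
           ifelse(values < row$lower, "Poor", "Borderline"))
  }
  factor(lab, levels = c("Desirable", "Borderline", "Poor"))
}

#' Assign quartile (or n-tile) labels
#'
#' Ranks values (average rank for ties, then stable original-order
#' tie-break) and cuts the ranking into `n_groups` groups whose sizes
#' differ by at most one. Warns when more than 10% of values are tied.
#'
#' @param values Numeric vector (length >= 2 * `n_groups`).
#' @param n_groups Number of groups (4 = quartiles).
#' @return Factor with levels `Q1` (lowest) ... `Qn`.
#' @examples
#' assign_quartiles(1:8) # Q1 Q1 Q2 Q2 Q3 Q3 Q4 Q4
#' @export
assign_quartiles <- function(values, n_groups = 4L) {
  n <- length(values)
  if (n < 2L * n_groups) {
    abort(sprintf("Need at least %d values for %d groups.",
                  2L * n_groups, n_groups))
  }
  if (mean(duplicated(values)) > 0.10) {
    warn("More than 10% of values are tied; quartile bounds are rank-based.")
  }
  avg <- rank(values, ties.method = "average")
  pos <- rank(avg, ties.method = "first") # stable within ties
  grp <- ceiling(n_groups * pos / n)
  factor(paste0("Q", grp), levels = paste0("Q", seq_len(n_groups)))
}

#' Measured-vs-predicted category overlap table
#'
#' Cross-tabulates measured and predicted category assignments: for each
#' category, the overlap count is the number of subjects whose measured
#' *and* predicted values fall in that category; the denominator is the
#' measured-side category size; total accuracy is the pooled proportion of
#' subjects classified into their measured category.
#'
#' @param measured,predicted Equal-length factors over the same category
#'   set.
#' @param scheme Label recorded in the result (`"quartile"` or
#'   `"clinical"`).
#' @return An `overlap_table`: a tibble (`category`, `count`,
#'   `denominator`, `percentage`) with attributes `total_accuracy`
#'   (percent) and `scheme`.
#' @examples
#' m <- factor(c("A", "A", "B", "B")); p <- factor(c("A", "B", "B", "B"))
#' overlap_table(m, p)
#' @export
overlap_table <- function(measured, predicted,
                          scheme = c("quartile", "clinical")) {
  scheme <- match.arg(scheme)
  measured <- as.factor(measured)
  predicted <- as.factor(predicted)
  if (length(measured) != length(predicted)) {
    abort("Label vectors must have equal length.")
  }
  if (!setequal(levels(measured), levels(predicted))) {
    abort("Measured and predicted labels must share one category set.")
  }
  predicted <- factor(predicted, levels = levels(measured))
  cats <- levels(measured)
  agree <- measured == predicted
  count <- vapply(cats, function(c) sum(agree & measured == c), integer(1))
  denom <- vapply(cats, function(c) sum(measured == c), integer(1))
  out <- tibble(
    category = cats, count = unname(count), denominator = unname(denom),
    percentage = 100 * unname(count) / unname(denom)
  )
  attr(out, "total_accuracy") <- 100 * sum(count) / sum(denom)
  attr(out, "scheme") <- scheme
  class(out) <- c("overlap_table", class(out))
  out
}

#' Permutation chance baseline for category overlap
#'
#' Holds a balanced measured labelling of `n` subjects fixed and permutes
#' the predicted labels uniformly at random `n_reps` times, returning the
#' mean per-category overlap percentage with a 95% Monte-Carlo interval.
#' For balanced quartiles this converges to 25%.
#'
#' @param n Number of subjects.
#' @param n_categories Number of categories (4 = quartiles).
#' @param n_reps Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return One-row tibble: `mean_overlap_pct`, `ci_lower`, `ci_upper`,
#'   `n`, `n_categories`, `n_reps`.
#' @export
chance_baseline <- function(n, n_categories = 4L, n_reps = 1000L,
                            seed = 1L) {
  if (n_reps < 100L) abort("Need n_reps >= 100 for a stable baseline.")
  measured <- sort(rep_len(seq_len(n_categories), n))
  denom <- tabulate(measured, n_categories)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      perm <- sample(measured)
      hits <- tabulate(measured[measured == perm], n_categories)
      mean(100 * hits / denom)
    }, numeric(1))
  })
  ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
  tibble(
    mean_overlap_pct = mean(reps), ci_lower = ci[1], ci_upper = ci[2],
    n = n, n_categories = n_categories, n_reps = n_reps
  )
}

#' Stratify a panel model's test-set predictions
#'
#' Applies either the clinical cut-off scheme or independent quartiling to
#' the measured and predicted concentrations held in a `panel_model` and
#' returns the overlap table.
#'
#' @param model A `panel_model` (from [discover_panel()] or
#'   [validate_in_cohort()]).
#' @param scheme `"clinical"` or `"quartile"`.
#' @param cutoffs Cut-off scheme for the clinical route.
#' @return An [overlap_table()].
#' @export
stratify_predictions <- function(model, scheme = c("quartile", "clinical"),
                                 cutoffs = clinical_cutoffs()) {
  scheme <- match.arg(scheme)
  pr <- model$predictions
  if (scheme == "clinical") {
    meas <- assign_clinical(pr$measured, model$target, cutoffs)
    pred <- assign_clinical(pmax(pr$predicted, 1e-6), model$target, cutoffs)
  } else {
    meas <- assign_quartiles(pr$measured)
    pred <- assign_quartiles(pr$predicted)
  }
  overlap_table(meas, pred, scheme)
}
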