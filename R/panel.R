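#' Train/test split specification
#'
#' @param train_fraction Fraction of subjects assigned to training
#'   (default 70:30).
#' @param seed Integer seed for the split.
#' @param stratified If `TRUE`, sample within quartiles of the response so
#'   both sets cover the concentration range.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.70, seed = 1L,
                       stratified = FALSE) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 stratified = stratified),
            class = "split_spec")
}

#' Split a cohort into training and test indices
#'
#' @param n Number of subjects (>= 10).
#' @param spec A [split_spec()].
#' @param y Response vector, required for a stratified split.
#' @return List with sorted integer vectors `train` and `test` (disjoint,
#'   exhaustive; `length(train) == round(train_fraction * n)`).
#' @examples
#' split_cohort(777, split_spec(seed = 1))$train |> length() # 544
#' @export
split_cohort <- function(n, spec = split_spec(), y = NULL) {
  n <- as.integer(n)
  if (n < 10L) abort("Need at least 10 subjects to split.")
  n_train <- as.integer(round(spec$train_fraction * n))
  if (n_train < 1L || n_train >= n) {
    abort("Split leaves an empty training or test set.")
  }
  train <- withr::with_seed(spec$seed, {
    if (spec$stratified) {
      if (is.null(y) || length(y) != n) {
        abort("Stratified split needs a response `y` of length n.")
      }
      grp <- assign_quartiles(y)
      idx <- unlist(lapply(split(seq_len(n), grp), function(ix) {
        sample(ix, round(spec$train_fraction * length(ix)))
      }), use.names = FALSE)
      # adjust to the exact global training size
      if (length(idx) > n_train) {
        idx <- sample(idx, n_train)
      } else if (length(idx) < n_train) {
        idx <- c(idx, sample(setdiff(seq_len(n), idx),
                             n_train - length(idx)))
      }
      idx
    } else {
      sample.int(n, n_train)
    }
  })
  list(train = sort(train), test = setdiff(seq_len(n), train))
}

#' Random-forest configuration
#'
#' Defaults follow the classic random-forest regression settings: 500
#' trees, `mtry = p/3`, permutation importance (%IncMSE).
#'
#' @param ntree Number of trees.
#' @param mtry Variables tried per split; `NULL` uses `max(floor(p/3), 1)`.
#' @param seed Seed applied to every forest fit.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(ntree = 500L, mtry = NULL, seed = 1L) {
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 seed = as.integer(seed)),
            class = "rf_config")
}

fit_rf <- function(x, y, config) {
  mtry <- config$mtry %||% max(floor(ncol(x) / 3), 1)
  withr::with_seed(config$seed, {
    randomForest::randomForest(
      x = as.data.frame(x), y = y,
      ntree = config$ntree, mtry = min(mtry, ncol(x)),
      importance = TRUE
    )
  })
}

#' Rank lipids by random-forest importance
#'
#' Fits a random-forest regression of the clinical response on all lipids
#' in the training set and orders lipids by decreasing permutation
#' importance (%IncMSE).
#'
#' @param train Training feature matrix (numeric matrix or data frame,
#'   subjects x lipids; no missing cells, >= 30 rows).
#' @param y Clinical response (mmol/L), aligned with `train` rows.
#' @param config An [rf_config()].
#' @return A list of class `lipid_ranking`: `ranking` (lipid names, best
#'   first), `importance` tibble, and the fitted all-lipid `model`.
#' @export
rank_all_lipids <- function(train, y, config = rf_config()) {
  train <- as.matrix(train)
  if (anyNA(train)) abort("Training matrix must have no missing cells.")
  if (nrow(train) < 30L) abort("Need >= 30 training samples to rank lipids.")
  if (length(y) != nrow(train)) abort("`y` must align with `train` rows.")
  if (sd(y) == 0) abort("Constant response: ranking undefined.")
  fit <- fit_rf(train, y, config)
  imp <- randomForest::importance(fit, type = 1)[, 1]
  ord <- order(imp, decreasing = TRUE)
  structure(
    list(
      ranking = colnames(train)[ord],
      importance = tibble(lipid = colnames(train)[ord],
                          importance = unname(imp[ord]),
                          rank = seq_along(ord)),
      model = fit,
      config = config
    ),
    class = "lipid_ranking"
  )
}

#' Pearson evaluation of predicted vs measured concentrations
#'
#' @param predicted,measured Numeric vectors (length >= 3).
#' @return One-row tibble with `r` (Pearson), `p` (two-sided, from
#'   \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n-2 df), `msr` (mean squared
#'   residual, predicted minus measured) and `n`. `r`/`p` are `NA` with a
#'   warning when the predictions have zero variance.
#' @examples
#' evaluate_predictions(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' @export
evaluate_predictions <- function(predicted, measured) {
  n <- length(measured)
  if (n < 3L || length(predicted) != n) {
    abort("Need aligned vectors of length >= 3.")
  }
  msr <- mean((predicted - measured)^2)
  if (sd(predicted) == 0 || sd(measured) == 0) {
    warn("Zero variance: correlation undefined.")
    return(tibble(r = NA_real_, p = NA_real_, msr = msr, n = n))
  }
  r <- cor(predicted, measured)
  p <- pearson_p(r, n)
  tibble(r = r, p = p, msr = msr, n = n)
}

# two-sided p for a Pearson correlation via the t transform
pearson_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(t), df = n - 2)
}

#' Grow a minimal predictive lipid panel
#'
#' Starting from the top-ranked lipid, refits a random forest on the top-k
#' lipids (k = 1, 2, ...) until the k-lipid model's test-set correlation
#' reaches the all-lipid model's test-set correlation minus `tolerance`.
#' Ranking and growth use training data only; the held-out test set is
#' used for evaluation (an inner validation split can be emulated by
#' passing a sub-split as the "test" arguments).
#'
#' @param ranking A `lipid_ranking` from [rank_all_lipids()] (its all-lipid
#'   model supplies the reference test correlation) or a character vector
#'   of lipid names, in which case `all_lipid_r` must be given.
#' @param train_x,train_y Training features/response.
#' @param test_x,test_y Held-out features/response for evaluation.
#' @param tolerance Allowed shortfall in test r relative to the all-lipid
#'   model ("performs as well as", quantified; default 0.01).
#' @param config An [rf_config()].
#' @param all_lipid_r Reference test correlation when `ranking` is a bare
#'   character vector.
#' @param target Clinical lipoprotein name recorded in the result.
#' @return A `panel_model`: ordered `panel`, `training_msr` (out-of-bag
#'   mean squared residual of the panel forest), `test_r`, `test_p`,
#'   `test_msr`, `all_lipid_test_r`, the fitted forest, and the test-set
#'   predictions. `flagged` is `TRUE` if no proper subset matched the
#'   all-lipid model and the panel is all lipids.
#' @export
grow_panel <- function(ranking, train_x, train_y, test_x, test_y,
                       tolerance = 0.01, config = rf_config(),
                       all_lipid_r = NULL, target = "TriG") {
  if (tolerance < 0) abort("`tolerance` must be >= 0.")
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (inherits(ranking, "lipid_ranking")) {
    all_fit <- ranking$model
    all_pred <- predict(all_fit, as.data.frame(test_x))
    all_lipid_r <- cor(all_pred, test_y)
    ranked <- ranking$ranking
  } else {
    ranked <- ranking
    if (is.null(all_lipid_r)) {
      abort("Provide `all_lipid_r` when `ranking` is a character vector.")
    }
  }
  if (length(ranked) == 0) abort("Empty ranking.")

  best <- NULL
  flagged <- FALSE
  for (k in seq_along(ranked)) {
    panel <- ranked[seq_len(k)]
    fit <- fit_rf(train_x[, panel, drop = FALSE], train_y, config)
    pred <- predict(fit, as.data.frame(test_x[, panel, drop = FALSE]))
    ev <- evaluate_predictions(pred, test_y)
    best <- list(panel = panel, fit = fit, ev = ev, pred = pred)
    if (!is.na(ev$r) && ev$r >= all_lipid_r - tolerance) break
    if (k == length(ranked)) flagged <- TRUE
  }

  new_panel_model(
    target = target, panel = best$panel,
    training_msr = utils::tail(best$fit$mse, 1),
    test_r = best$ev$r, test_p = best$ev$p, test_msr = best$ev$msr,
    all_lipid_test_r = all_lipid_r,
    n_train = nrow(train_x), n_test = nrow(test_x),
    rf_config = config, fit = best$fit,
    predictions = tibble(measured = test_y, predicted = best$pred),
    flagged = flagged
  )
}

new_panel_model <- function(target, panel, training_msr, test_r, test_p,
                            test_msr, all_lipid_test_r, n_train, n_test,
                            rf_config, fit, predictions, flagged = FALSE) {
  structure(
    list(target = target, panel = panel, training_msr = training_msr,
         test_r = test_r, test_p = test_p, test_msr = test_msr,
         all_lipid_test_r = all_lipid_test_r, n_train = n_train,
         n_test = n_test, rf_config = rf_config, fit = fit,
         predictions = predictions, flagged = flagged),
    class = "panel_model"
  )
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("<panel_model> %s: %d lipids\n", x$target, length(x$panel)))
  cat(sprintf("  training MSR %.3f | test r %.3f (p = %.2e, n = %d)\n",
              x$training_msr, x$test_r, x$test_p, x$n_test))
  cat(sprintf("  all-lipid test r %.3f%s\n", x$all_lipid_test_r,
              if (x$flagged) " [no proper subset matched]" else ""))
  cat("  panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

#' Discover a minimal lipid panel for one clinical lipoprotein
#'
#' End-to-end stage-1 discovery: 70:30 split, all-lipid random-forest
#' ranking on the training set, iterative forward panel growth, test-set
#' evaluation.
#'
#' @param m Processed `feature_matrix` (post-QC, normalised, centered).
#' @param clinical Clinical table with `subject_id` and the target column.
#' @param target One of `"TriG"`, `"HDL"`, `"LDL"`, `"TC"`.
#' @param split A [split_spec()].
#' @param config An [rf_config()].
#' @param tolerance Panel-growth stopping tolerance on test r.
#' @return A `panel_model`.
#' @export
discover_panel <- function(m, clinical, target = CLINICAL_TARGETS,
                           split = split_spec(), config = rf_config(),
                           tolerance = 0.01) {
  target <- match.arg(target)
  x <- as.matrix(m)
  y <- clinical[[target]][match(rownames(x), clinical$subject_id)]
  if (anyNA(y)) abort("Clinical table does not cover all samples.")
  idx <- split_cohort(nrow(x), split, y = y)
  ranking <- rank_all_lipids(x[idx$train, , drop = FALSE], y[idx$train],
                             config)
  grow_panel(ranking,
             x[idx$train, , drop = FALSE], y[idx$train],
             x[idx$test, , drop = FALSE], y[idx$test],
             tolerance = tolerance, config = config, target = target)
}
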