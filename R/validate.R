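#' Translate a discovered panel into another cohort's lipid space
#'
#' Intersects a panel with the lipids measured in a target cohort,
#' recording which panel members are missing there. No model is refit at
#' this step.
#'
#' @param panel A `panel_model` or a character vector of lipid names.
#' @param target_lipids Lipids measured in the target cohort (character
#'   vector or a `feature_matrix`).
#' @return A `translation_record` with `source_panel`, `lipids_missing`,
#'   `lipids_used` (panel order preserved) and, once completed by
#'   [validate_in_cohort()], the target-cohort `model`.
#' @export
translate_panel <- function(panel, target_lipids) {
  source_target <- NULL
  source_r <- NA_real_
  if (inherits(panel, "panel_model")) {
    source_target <- panel$target
    source_r <- panel$test_r
    panel <- panel$panel
  }
  if (inherits(target_lipids, "feature_matrix")) {
    target_lipids <- lipids(target_lipids)
  }
  used <- panel[panel %in% target_lipids]
  missing <- setdiff(panel, target_lipids)
  if (length(used) == 0) {
    abort("No panel lipid is measured in the target cohort; validation impossible.")
  }
  structure(
    list(source_target = source_target, source_panel = panel,
         source_test_r = source_r, lipids_missing = missing,
         lipids_used = used, model = NULL),
    class = "translation_record"
  )
}

#' Retrain and evaluate a translated panel in the target cohort
#'
#' Implements stage-2 validation: the target cohort is split 70:30, a
#' random forest is trained from scratch on the training split restricted
#' to the translated lipids, and evaluated on the test split. Only lipid
#' identities cross cohorts — never trees or coefficients. A
#' `transport = TRUE` mode instead applies a supplied source-cohort model
#' directly to the target test split (not the published procedure; for
#' comparison only).
#'
#' @param rec A `translation_record` from [translate_panel()].
#' @param m Target cohort processed `feature_matrix`.
#' @param clinical Target cohort clinical table.
#' @param split A [split_spec()] (use a seed independent of the discovery
#'   split).
#' @param config An [rf_config()].
#' @param transport Apply `transport_model` without retraining.
#' @param transport_model A fitted source-cohort `panel_model` (required
#'   when `transport = TRUE`).
#' @param target Clinical lipoprotein; defaults to the record's source
#'   target.
#' @return The completed `translation_record`, with `model` a
#'   `panel_model` fitted in the target cohort.
#' @export
validate_in_cohort <- function(rec, m, clinical, split = split_spec(),
                               config = rf_config(), transport = FALSE,
                               transport_model = NULL, target = NULL) {
  stopifnot(inherits(rec, "translation_record"))
  target <- target %||% rec$source_target %||% "TriG"
  x <- as.matrix(m)
  if (!all(rec$lipids_used %in% colnames(x))) {
    abort("`lipids_used` must all be columns of the target matrix.")
  }
  y <- clinical[[target]][match(rownames(x), clinical$subject_id)]
  idx <- split_cohort(nrow(x), split, y = y)
  xs <- x[, rec$lipids_used, drop = FALSE]

  if (transport) {
    if (is.null(transport_model)) {
      abort("`transport = TRUE` needs `transport_model`.")
    }
    if (length(rec$lipids_missing) > 0) {
      abort("Transport requires every source-panel lipid in the target cohort; retrain instead.")
    }
    pred <- predict(transport_model$fit,
                    as.data.frame(xs[idx$test, , drop = FALSE]))
    ev <- evaluate_predictions(pred, y[idx$test])
    rec$model <- new_panel_model(
      target = target, panel = rec$lipids_used,
      training_msr = NA_real_, test_r = ev$r, test_p = ev$p,
      test_msr = ev$msr, all_lipid_test_r = NA_real_,
      n_train = 0L, n_test = length(idx$test), rf_config = config,
      fit = transport_model$fit,
      predictions = tibble(measured = y[idx$test], predicted = pred)
    )
    rec$mode <- "transport"
    return(rec)
  }

  fit <- fit_rf(xs[idx$train, , drop = FALSE], y[idx$train], config)
  pred <- predict(fit, as.data.frame(xs[idx$test, , drop = FALSE]))
  ev <- evaluate_predictions(pred, y[idx$test])
  rec$model <- new_panel_model(
    target = target, panel = rec$lipids_used,
    training_msr = utils::tail(fit$mse, 1),
    test_r = ev$r, test_p = ev$p, test_msr = ev$msr,
    all_lipid_test_r = NA_real_,
    n_train = length(idx$train), n_test = length(idx$test),
    rf_config = config, fit = fit,
    predictions = tibble(measured = y[idx$test], predicted = pred)
  )
  rec$mode <- "retrain"
  rec
}

#' @export
print.translation_record <- function(x, ...) {
  cat("<translation_record>", x$source_target %||% "", "\n")
  cat(sprintf("  source panel %d lipids; %d missing in target; %d used\n",
              length(x$source_panel), length(x$lipids_missing),
              length(x$lipids_used)))
  if (length(x$lipids_missing) > 0) {
    cat("  missing:", paste(x$lipids_missing, collapse = ", "), "\n")
  }
  if (!is.null(x$model)) {
    cat(sprintf("  target test r %.3f (p = %.2e)\n",
                x$model$test_r, x$model$test_p))
  }
  invisible(x)
}
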