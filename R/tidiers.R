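#' Broom-style tidiers for fitted objects
#'
#' `tidy()` returns per-component rows (panel lipids with importance
#' ranks, shared-lipid correlations, overlap categories); `glance()`
#' returns one-row model summaries.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.panel_model <- function(x, ...) {
  tibble(lipid = x$panel, rank = seq_along(x$panel), target = x$target)
}

#' @rdname tidiers
#' @export
glance.panel_model <- function(x, ...) {
  tibble(
    target = x$target, panel_size = length(x$panel),
    training_msr = x$training_msr, test_r = x$test_r, test_p = x$test_p,
    test_msr = x$test_msr, all_lipid_test_r = x$all_lipid_test_r,
    n_train = x$n_train, n_test = x$n_test, flagged = x$flagged
  )
}

#' @rdname tidiers
#' @export
tidy.translation_record <- function(x, ...) {
  tibble(
    lipid = x$source_panel,
    target = x$source_target %||% NA_character_,
    used = x$source_panel %in% x$lipids_used
  )
}

#' @rdname tidiers
#' @export
glance.translation_record <- function(x, ...) {
  tibble(
    target = x$source_target %||% NA_character_,
    source_panel_size = length(x$source_panel),
    n_missing = length(x$lipids_missing),
    n_used = length(x$lipids_used),
    source_test_r = x$source_test_r,
    validation_test_r = if (is.null(x$model)) NA_real_ else x$model$test_r,
    validation_test_p = if (is.null(x$model)) NA_real_ else x$model$test_p,
    validation_training_msr = if (is.null(x$model)) NA_real_ else
      x$model$training_msr
  )
}

#' @rdname tidiers
#' @export
tidy.concordance_result <- function(x, ...) x$shared

#' @rdname tidiers
#' @export
glance.concordance_result <- function(x, ...) {
  tibble(r = x$r, n_shared = x$n_shared,
         n_only_in_a = length(x$only_in_a),
         n_only_in_b = length(x$only_in_b))
}

#' @rdname tidiers
#' @export
glance.overlap_table <- function(x, ...) {
  tibble(
    total_accuracy = attr(x, "total_accuracy"),
    scheme = attr(x, "scheme"),
    n = sum(x$denominator),
    n_categories = nrow(x)
  )
}

#' @rdname tidiers
#' @export
tidy.lipid_ranking <- function(x, ...) x$importance
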