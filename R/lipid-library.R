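#' Generate a synthetic lipid target library
#'
#' Builds a library of named lipid species with expected m/z values spread
#' over the direct-infusion acquisition range (150-2000 m/z by default).
#' Adjacent targets are kept more than `3 * window_ppm` apart (relative to
#' the heavier target) so that ppm-window peak assignment is unambiguous by
#' construction.
#'
#' @param n_lipids Number of targets to generate.
#' @param n_classes Number of distinct lipid classes (each used at least
#'   once). Class names are drawn from common lipidomics nomenclature (PC,
#'   TG, CE, SM, ...), with numbered extras beyond eleven.
#' @param seed Integer seed.
#' @param mz_range Acquisition m/z range.
#' @param window_ppm Reference matching window used to derive the minimum
#'   target spacing.
#' @return A tibble with columns `name`, `lipid_class`, `expected_mz`,
#'   sorted by `expected_mz` (strictly increasing).
#' @examples
#' make_lipid_library(20, 4, seed = 1)
#' @export
make_lipid_library <- function(n_lipids, n_classes, seed = 1L,
                               mz_range = c(150, 2000), window_ppm = 10) {
  n_lipids <- as.integer(n_lipids)
  n_classes <- as.integer(n_classes)
  if (n_lipids < 1L || n_classes < 1L || n_lipids < n_classes) {
    abort("Require n_lipids >= n_classes >= 1.")
  }
  # Jittered grid: step s, jitter within +/- 0.35 s, so the minimum gap is
  # 0.3 s. That gap must exceed 3x the ppm window at the top of the range.
  s <- diff(mz_range) / (n_lipids + 1)
  min_gap_needed <- 3 * window_ppm * 1e-6 * mz_range[2]
  if (n_lipids > 1L && 0.3 * s <= min_gap_needed) {
    abort(sprintf(
      "Cannot place %d targets in [%g, %g] with spacing > %.3g m/z.",
      n_lipids, mz_range[1], mz_range[2], min_gap_needed
    ))
  }
  class_pool <- c("PC", "PE", "TG", "DG", "CE", "SM", "LPC", "PC-O",
                  "PG", "PI", "PS")
  if (n_classes > length(class_pool)) {
    class_pool <- c(class_pool,
                    paste0("CL", seq_len(n_classes - length(class_pool))))
  }
  classes <- class_pool[seq_len(n_classes)]

  withr::with_seed(seed, {
    base <- mz_range[1] + s * seq_len(n_lipids)
    mz <- base + runif(n_lipids, -0.35 * s, 0.35 * s)
    # every class at least once, remainder at random, order shuffled
    cls <- sample(c(classes,
                    sample(classes, n_lipids - n_classes, replace = TRUE)))
  })
  # unique names per class: walk a (carbons:double bonds) grid
  idx_in_class <- stats::ave(seq_len(n_lipids), cls, FUN = seq_along)
  name <- sprintf("%s(%d:%d)", cls,
                  24L + 2L * ((idx_in_class - 1L) %/% 8L),
                  (idx_in_class - 1L) %% 8L)
  tibble(name = name, lipid_class = cls, expected_mz = mz) |>
    arrange(.data$expected_mz)
}
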