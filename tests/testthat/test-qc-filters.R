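test_that("mass-deviation filter reads its 5 ppm boundary strictly", {
  int <- matrix(1, 2, 4)
  dev <- cbind(c(5, 5), c(5.1, 5.1), c(4, -4), c(NA, NA))
  m <- make_fm(int, dev)
  out <- filter_mass_deviation(m, max_ppm = 5)
  # exactly 5.0 retained; 5.1 removed; symmetric +/-4 retained; never
  # matched removed and reported distinctly
  expect_equal(lipids(out), c("L1", "L3"))
  rep <- filter_report(out)
  expect_equal(sort(rep$removed[[1]]), c("L2", "L4"))
  expect_match(rep$note, "never matched")
  # signed-mean convention also keeps the +/-4 column (mean 0)
  out_signed <- filter_mass_deviation(m, max_ppm = 5, use_signed = TRUE)
  expect_true("L3" %in% lipids(out_signed))
})

test_that("blank-ratio filter removes under-5x signals, keeps clean blanks", {
  int <- matrix(c(100, 100, 100, 100, 50, 50), 2)
  m <- make_fm(int, matrix(0, 2, 3))
  blanks <- make_fm(matrix(c(25, 25, 20, 20, 0, 0), 2))
  out <- filter_blank_ratio(m, blanks, min_ratio = 5)
  # ratio 4 -> removed; ratio exactly 5 -> retained; blank 0 -> retained
  expect_equal(lipids(out), c("L2", "L3"))
  expect_equal(filter_report(out)$removed[[1]], "L1")
})

test_that("missingness filter reads its 10% boundary strictly", {
  n <- 100
  mk_col <- function(k) c(rep(0, k), rep(1, n - k))
  int <- cbind(mk_col(11), mk_col(10), mk_col(0))
  m <- make_fm(int, matrix(0, n, 3))
  out <- filter_missingness(m, max_zero_frac = 0.10)
  expect_equal(lipids(out), c("L2", "L3"))
})

test_that("QC linearity filter demands r >= 0.9 and fails flat signals", {
  int <- matrix(1, 3, 3, dimnames = list(NULL, c("L1", "L2", "L3")))
  qc_int <- cbind(c(1, 2, 4), c(4, 2, 1), c(3, 3, 3))
  qc <- make_fm(qc_int, serum_fraction = c(0.25, 0.5, 1.0))
  m <- make_fm(int, matrix(0, 3, 3))
  out <- filter_qc_linearity(m, qc, min_r = 0.9)
  expect_equal(lipids(out), "L1") # y = 4x exactly: r = 1
  rep <- filter_report(out)
  expect_true(all(c("L2", "L3") %in% rep$removed[[1]]))
  expect_match(rep$note, "zero QC variance")
})

test_that("each filter matches its brute-force per-column predicate", {
  for (trial in 1:100) {
    withr::with_seed(trial, {
      ns <- sample(4:10, 1)
      p <- sample(3:8, 1)
      int <- matrix(rpois(ns * p, 20) *
                      rbinom(ns * p, 1, 0.85), ns, p,
                    dimnames = list(paste0("S", seq_len(ns)),
                                    paste0("L", seq_len(p))))
      dev <- matrix(rnorm(ns * p, 0, 4), ns, p)
      dev[sample(ns * p, ns)] <- NA
      dev[, 1] <- NA # guarantee a never-matched column sometimes
      m <- make_fm(int, dev)
      blanks <- make_fm(matrix(rpois(2 * p, 5), 2, p))
      qc_int <- matrix(rpois(6 * p, 30), 6, p)
      frac <- rep(c(0.25, 0.5, 1.0), each = 2)
      qc <- make_fm(qc_int, serum_fraction = frac)

      got1 <- lipids(filter_mass_deviation(m))
      want1 <- colnames(int)[apply(dev, 2, oracle_keep_mass)]
      expect_equal(got1 %||% character(0), want1)

      got2 <- lipids(filter_blank_ratio(m, blanks))
      want2 <- colnames(int)[vapply(seq_len(p), function(j) {
        oracle_keep_blank(int[, j], blanks$intensity[, j])
      }, logical(1))]
      expect_equal(got2 %||% character(0), want2)

      got3 <- lipids(filter_missingness(m))
      want3 <- colnames(int)[apply(int, 2, oracle_keep_missing)]
      expect_equal(got3 %||% character(0), want3)

      got4 <- lipids(filter_qc_linearity(m, qc))
      want4 <- colnames(int)[vapply(seq_len(p), function(j) {
        oracle_keep_qc(qc_int[, j], frac)
      }, logical(1))]
      expect_equal(got4 %||% character(0), want4)
    })
  }
})

test_that("TIC normalisation and centering behave as stated", {
  m <- make_fm(matrix(c(2, 3, 5), 1, 3), matrix(0, 1, 3))
  out <- normalize_tic(m)
  expect_equal(as.vector(as.matrix(out)), c(0.2, 0.3, 0.5))
  expect_equal(as.matrix(normalize_tic(out)), as.matrix(out)) # idempotent
  expect_equal(out$transform_log, "tic_normalized")

  single <- normalize_tic(make_fm(matrix(c(7, 3), 2, 1)))
  expect_equal(as.vector(as.matrix(single)), c(1, 1))

  zero_row <- make_fm(matrix(c(1, 0, 2, 0), 2, 2))
  expect_error(normalize_tic(zero_row), "S2")

  cen <- mean_center(make_fm(matrix(c(0.2, 0.4), 2, 1)))
  expect_equal(as.vector(as.matrix(cen)), c(-0.1, 0.1))
  expect_equal(as.matrix(mean_center(cen)), as.matrix(cen)) # fixed point

  # normalisation preserves within-sample intensity ratios
  withr::with_seed(5, {
    raw <- matrix(runif(20, 1, 50), 4, 5)
    nm <- normalize_tic(make_fm(raw))
    expect_equal(unname(as.matrix(nm)[, 1] / as.matrix(nm)[, 2]),
                 raw[, 1] / raw[, 2])
  })
})

test_that("cohorts are centered independently", {
  a <- mean_center(normalize_tic(make_fm(matrix(runif(12, 1, 5), 3, 4),
                                         cohort_id = "A")))
  b <- mean_center(normalize_tic(make_fm(matrix(runif(12, 5, 9), 3, 4),
                                         cohort_id = "B")))
  expect_equal(unname(colMeans(as.matrix(a))), rep(0, 4))
  expect_equal(unname(colMeans(as.matrix(b))), rep(0, 4))
})

test_that("planted failing lipids are removed by their designated filter", {
  co <- small_cohorts()
  proc <- process_cohort(co$discovery$spectra, co$discovery$library,
                         cohort_id = "discovery")
  rep <- proc$report
  spec <- co$discovery$spec
  expect_setequal(rep$removed[[match("mass_deviation", rep$filter)]],
                  spec$high_ppm_lipids)
  expect_setequal(rep$removed[[match("blank_ratio", rep$filter)]],
                  spec$blank_fail_lipids)
  expect_setequal(rep$removed[[match("missingness", rep$filter)]],
                  spec$high_missing_lipids)
  expect_setequal(rep$removed[[match("qc_linearity", rep$filter)]],
                  spec$nonlinear_qc_lipids)
  # no clean lipid lost; retained set is the clean detectable set
  planted <- unlist(spec[c("blank_fail_lipids", "high_ppm_lipids",
                           "nonlinear_qc_lipids", "high_missing_lipids")])
  expect_setequal(lipids(proc$matrix),
                  setdiff(co$discovery$library$name, planted))
  # removal sets disjoint and counts chain across the report
  expect_equal(rep$lipids_in[-1],
               (rep$lipids_in - rep$lipids_removed)[-nrow(rep)])
  expect_equal(anyDuplicated(unlist(rep$removed)), 0L)
  # pipeline finishes normalised and centered
  expect_equal(proc$matrix$transform_log,
               c("tic_normalized", "mean_centered"))
  expect_equal(unname(colMeans(as.matrix(proc$matrix))),
               rep(0, length(lipids(proc$matrix))))
})
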