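test_that("70:30 splits are exact, disjoint, exhaustive, reproducible", {
  s <- split_cohort(10, split_spec(seed = 1))
  expect_equal(length(s$train), 7)
  expect_equal(length(s$test), 3)

  s777 <- split_cohort(777, split_spec(seed = 2))
  expect_equal(length(s777$train), 544) # round(0.7 * 777)
  expect_equal(length(s777$test), 233)
  expect_equal(sort(c(s777$train, s777$test)), 1:777)

  expect_identical(split_cohort(100, split_spec(seed = 5)),
                   split_cohort(100, split_spec(seed = 5)))
  expect_error(split_cohort(9), "at least 10")

  # stratified split still hits the exact training size
  y <- rlnorm(100)
  st <- split_cohort(100, split_spec(seed = 3, stratified = TRUE), y = y)
  expect_equal(length(st$train), 70)
})

test_that("evaluation reports Pearson r, t-based p and MSR", {
  id <- evaluate_predictions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(id$r, 1)
  expect_equal(id$msr, 0)

  flip <- evaluate_predictions(-c(1, 2, 3, 4) + 10, c(1, 2, 3, 4))
  expect_equal(flip$r, -1)

  # r = 0.5, n = 100: t = 0.5 sqrt(98)/sqrt(0.75), two-sided on 98 df
  p <- lipidpanelr:::pearson_p(0.5, 100)
  expect_equal(p, 2 * pt(-0.5 * sqrt(98) / sqrt(0.75), 98))
  expect_equal(signif(p, 2), 1.2e-07)

  # the in-package t transform agrees with cor.test
  withr::with_seed(11, {
    a <- rnorm(40); b <- a + rnorm(40, 0, 2)
    ev <- evaluate_predictions(a, b)
    ct <- cor.test(a, b)
    expect_equal(ev$r, unname(ct$estimate))
    expect_equal(ev$p, ct$p.value, tolerance = 1e-12)
  })

  expect_warning(ev0 <- evaluate_predictions(rep(1, 5), 1:5),
                 "Zero variance")
  expect_true(is.na(ev0$r))
})

test_that("random-forest ranking recovers a dominant planted lipid", {
  hits <- 0
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- 300
      z <- rnorm(n)
      x <- cbind(z + rnorm(n, 0, 0.3),
                 matrix(rnorm(n * 9), n, 9))
      colnames(x) <- paste0("L", 1:10)
      rk <- rank_all_lipids(x, z, rf_config(ntree = 100, seed = s))
      if (rk$ranking[1] == "L1") hits <- hits + 1
    })
  }
  expect_gte(hits, 19)
})

test_that("ranking is uniform over lipids when the response is noise", {
  top <- character(200)
  for (s in 1:200) {
    withr::with_seed(1000 + s, {
      x <- matrix(rnorm(60 * 5), 60, 5,
                  dimnames = list(NULL, paste0("L", 1:5)))
      y <- rnorm(60)
      top[s] <- rank_all_lipids(x, y,
                                rf_config(ntree = 50, seed = s))$ranking[1]
    })
  }
  counts <- table(factor(top, levels = paste0("L", 1:5)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("a duplicated top lipid shares the leading ranks", {
  withr::with_seed(4, {
    n <- 400
    z <- rnorm(n)
    x <- cbind(z + rnorm(n, 0, 0.2), z + rnorm(n, 0, 0.2),
               matrix(rnorm(n * 8), n, 8))
    colnames(x) <- c("dupA", "dupB", paste0("N", 1:8))
    rk <- rank_all_lipids(x, z, rf_config(ntree = 200, seed = 4))
    expect_true(all(c("dupA", "dupB") %in% rk$ranking[1:3]))
  })
})

test_that("panel growth stops at the smallest sufficient panel", {
  withr::with_seed(6, {
    n <- 200
    z <- rnorm(n)
    x <- cbind(z, matrix(rnorm(n * 5), n, 5))
    colnames(x) <- paste0("L", 1:6)
    idx <- split_cohort(n, split_spec(seed = 6))
    rk <- rank_all_lipids(x[idx$train, ], z[idx$train],
                          rf_config(ntree = 100, seed = 6))
    pm <- grow_panel(rk, x[idx$train, ], z[idx$train],
                     x[idx$test, ], z[idx$test],
                     tolerance = 0.01, rf_config(ntree = 100, seed = 6))
    expect_equal(pm$panel, "L1") # the perfect lipid suffices alone
    expect_false(pm$flagged)

    # degenerate tolerance: the first model always "performs as well"
    pm1 <- grow_panel(rk, x[idx$train, ], z[idx$train],
                      x[idx$test, ], z[idx$test],
                      tolerance = 1.0, rf_config(ntree = 100, seed = 6))
    expect_equal(length(pm1$panel), 1)
  })
})

test_that("discovery is deterministic and leak-free by construction", {
  co <- small_cohorts()
  proc <- process_cohort(co$discovery$spectra, co$discovery$library)
  cfg <- rf_config(ntree = 150, seed = 9)
  pm1 <- discover_panel(proc$matrix, co$discovery$clinical, "TriG",
                        split_spec(seed = 9), cfg)
  pm2 <- discover_panel(proc$matrix, co$discovery$clinical, "TriG",
                        split_spec(seed = 9), cfg)
  expect_identical(pm1$panel, pm2$panel)
  expect_identical(pm1$test_r, pm2$test_r)
  # the split is fixed before ranking: train/test partition the cohort
  idx <- split_cohort(nrow(as.matrix(proc$matrix)), split_spec(seed = 9),
                      y = co$discovery$clinical$TriG)
  expect_equal(pm1$n_train, length(idx$train))
  expect_equal(pm1$n_test, length(idx$test))
  expect_equal(nrow(pm1$predictions), length(idx$test))
  # broom surface
  expect_equal(nrow(tidy(pm1)), length(pm1$panel))
  expect_equal(glance(pm1)$panel_size, length(pm1$panel))
})
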