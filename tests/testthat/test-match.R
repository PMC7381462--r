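lib1 <- tibble::tibble(name = "PC(34:1)", lipid_class = "PC",
                       expected_mz = 760.5851)

test_that("ppm deviations are signed and windowed correctly", {
  pk <- tibble::tibble(mz = 760.5889, intensity = 100)
  sig <- match_spectrum(pk, lib1, window_ppm = 10)
  expect_equal(round(sig$deviation_ppm, 1), 5.0)
  expect_equal(sig$deviation_ppm, (760.5889 - 760.5851) / 760.5851 * 1e6)
  expect_equal(sig$intensity, 100)

  exact <- match_spectrum(tibble::tibble(mz = 760.5851, intensity = 7),
                          lib1, 10)
  expect_equal(exact$deviation_ppm, 0)

  far <- match_spectrum(
    tibble::tibble(mz = 760.5851 * (1 + 12e-6), intensity = 7), lib1, 10
  )
  expect_equal(far$intensity, 0)
  expect_true(is.na(far$deviation_ppm))
})

test_that("equidistant candidates break ties toward the intense peak", {
  pk <- tibble::tibble(mz = c(760.5851 * (1 - 5e-6), 760.5851 * (1 + 5e-6)),
                       intensity = c(1, 9))
  sig <- match_spectrum(pk, lib1, window_ppm = 10)
  expect_equal(sig$intensity, 9)
  expect_gt(sig$deviation_ppm, 0)
})

test_that("matching equals the brute-force all-pairs oracle", {
  for (trial in 1:50) {
    withr::with_seed(trial, {
      n_t <- sample(2:20, 1)
      targets <- sort(runif(n_t, 400, 900))
      # cluster some peaks near targets, scatter the rest
      near <- targets[sample(n_t, ceiling(n_t / 2))] *
        (1 + rnorm(ceiling(n_t / 2), 0, 8e-6))
      stray <- runif(sample(1:30, 1), 400, 900)
      mz <- sort(unique(c(near, stray)))
      pk <- tibble::tibble(mz = mz, intensity = runif(length(mz), 1, 100))
      lib <- tibble::tibble(name = paste0("T", seq_len(n_t)),
                            lipid_class = "X", expected_mz = targets)
      w <- sample(c(5, 10, 20), 1)
      got <- match_spectrum(pk, lib, w)
      want <- brute_match(pk, lib, w)
      expect_equal(got$intensity, want$intensity)
      expect_equal(got$deviation_ppm, want$deviation_ppm)
    })
  }
})

test_that("enlarging the window never loses matches", {
  withr::with_seed(99, {
    targets <- sort(runif(15, 300, 1200))
    mz <- sort(targets * (1 + rnorm(15, 0, 1e-5)))
    pk <- tibble::tibble(mz = mz, intensity = runif(15, 1, 10))
    lib <- tibble::tibble(name = paste0("T", 1:15), lipid_class = "X",
                          expected_mz = targets)
    n_matched <- vapply(c(1, 2, 5, 10, 20, 50), function(w) {
      sum(match_spectrum(pk, lib, w)$intensity > 0)
    }, numeric(1))
    expect_true(all(diff(n_matched) >= 0))
  })
})

test_that("matching contracts: empty inputs and unsorted peaks", {
  expect_warning(sig <- match_spectrum(tibble::tibble(mz = numeric(),
                                                      intensity = numeric()),
                                       lib1, 10), "Empty spectrum")
  expect_equal(sig$intensity, 0)
  expect_error(match_spectrum(tibble::tibble(mz = 1, intensity = 1),
                              lib1[0, ], 10), "nonempty")
  expect_error(match_spectrum(tibble::tibble(mz = c(2, 1),
                                             intensity = c(1, 1)),
                              lib1, 10), "increasing")
})

test_that("build_matrix assembles intensities and deviations faithfully", {
  sig <- tidyr::expand_grid(sample_id = c("A", "B", "C"),
                            lipid = c("L1", "L2")) |>
    dplyr::mutate(role = "sample", batch = "B1",
                  intensity = c(1, 2, 3, 4, 5, 6),
                  deviation_ppm = c(4, -4, 1, 1, 0, 2),
                  shared_peak = FALSE)
  m <- build_matrix(sig, "sample")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(as.vector(as.matrix(m)), c(1, 3, 5, 2, 4, 6))
  expect_equal(colMeans(m$deviation)[["L1"]], (4 + 1 + 0) / 3)

  # signed deviations (+4, -4) average to 0 while |deviations| average to 4
  two <- sig[sig$sample_id %in% c("A", "B") & sig$lipid == "L1", ]
  two$deviation_ppm <- c(4, -4)
  m_two <- build_matrix(two, "sample")
  expect_equal(mean(m_two$deviation[, "L1"]), 0)
  expect_equal(mean(abs(m_two$deviation[, "L1"])), 4)

  # all-miss column: zeros with absent deviation
  sig2 <- sig
  sig2$intensity[sig2$lipid == "L2"] <- 0
  sig2$deviation_ppm[sig2$lipid == "L2"] <- NA
  m2 <- build_matrix(sig2, "sample")
  expect_equal(unname(as.matrix(m2)[, "L2"]), c(0, 0, 0))
  expect_true(all(is.na(m2$deviation[, "L2"])))

  expect_error(build_matrix(dplyr::bind_rows(sig, sig[1, ]), "sample"),
               "Duplicate")
})
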