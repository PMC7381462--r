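noise_free_spec <- function(n, p, seed = 1, ...) {
  cohort_spec(n_subjects = n, n_lipids_detectable = p,
              noise_cv = 0, missing_rate = 0, mass_error_ppm_sd = 0,
              seed = seed, ...)
}

test_that("zero-noise spectra place one exact centroid per detectable lipid", {
  lib <- make_lipid_library(15, 3, seed = 4)
  spec <- noise_free_spec(6, 15, seed = 4)
  cl <- simulate_clinical(spec)
  sp <- simulate_spectra(cl, lib, spec)
  subj <- sp[sp$role == "sample", ]
  counts <- table(subj$sample_id)
  expect_true(all(counts == 15))
  for (id in unique(subj$sample_id)) {
    expect_equal(sort(subj$mz[subj$sample_id == id]), sort(lib$expected_mz))
  }
  # peaks strictly increasing within every sample (all roles)
  by_sample <- split(sp$mz, sp$sample_id)
  expect_true(all(vapply(by_sample,
                         function(m) !is.unsorted(m, strictly = TRUE),
                         logical(1))))
})

test_that("QC dilution series is exactly proportional at zero noise", {
  lib <- make_lipid_library(10, 2, seed = 5)
  spec <- noise_free_spec(4, 10, seed = 5)
  cl <- simulate_clinical(spec)
  sp <- simulate_spectra(cl, lib, spec)
  q100 <- sp[sp$sample_id == "QC100_1", ]
  q50 <- sp[sp$sample_id == "QC50_1", ]
  q25 <- sp[sp$sample_id == "QC25_1", ]
  expect_equal(q50$intensity, 0.5 * q100$intensity)
  expect_equal(q25$intensity, 0.25 * q100$intensity)
})

test_that("blanks carry only contaminants plus planted blank-fail lipids", {
  lib <- make_lipid_library(10, 2, seed = 6)
  fail <- lib$name[3]
  spec <- noise_free_spec(4, 10, seed = 6, blank_fail_lipids = fail,
                          n_contaminants = 10)
  cl <- simulate_clinical(spec)
  sp <- simulate_spectra(cl, lib, spec)
  blank <- sp[sp$role == "blank" & sp$sample_id == "BLANK_1", ]
  expect_equal(nrow(blank), 11) # 10 contaminants + 1 failing lipid
  # contaminant peaks stay far from all targets; one peak hits the target
  near <- vapply(blank$mz, function(m) {
    min(abs(m - lib$expected_mz) / lib$expected_mz) * 1e6 < 10
  }, logical(1))
  expect_equal(sum(near), 1)
  expect_equal(blank$mz[near], lib$expected_mz[lib$name == fail])
})

test_that("planted effects are recovered at the designed correlation", {
  lib <- make_lipid_library(20, 2, seed = 8)
  f <- 0.36
  am <- tibble::tibble(lipid = lib$name[5], target = "TriG",
                       effect_size = f)
  spec <- cohort_spec(n_subjects = 800, n_lipids_detectable = 20,
                      association_map = am, noise_cv = 0,
                      missing_rate = 0, seed = 8)
  cl <- simulate_clinical(spec)
  sp <- simulate_spectra(cl, lib, spec)
  sig <- match_cohort(sp, lib)
  m <- build_matrix(sig, "sample")
  x <- as.matrix(m)[cl$subject_id, lib$name[5]]
  expect_lt(abs(stats::cor(x, cl$TriG) - sqrt(f)), 0.08)
})

test_that("spectra generation is seeded-deterministic and validates the map", {
  lib <- make_lipid_library(8, 2, seed = 9)
  spec <- cohort_spec(n_subjects = 5, n_lipids_detectable = 8, seed = 9)
  cl <- simulate_clinical(spec)
  expect_identical(simulate_spectra(cl, lib, spec),
                   simulate_spectra(cl, lib, spec))
  bad <- spec
  bad$association_map <- tibble::tibble(lipid = "NOPE(1:1)",
                                        target = "TriG",
                                        effect_size = 0.5)
  expect_error(simulate_spectra(cl, lib, bad), "absent from library")
})

test_that("paired cohorts share the configured lipid overlap and dropout", {
  co <- make_paired_cohorts(
    cohort_spec(n_subjects = 40, n_lipids_detectable = 163, seed = 21),
    validation_cohort_spec(n_subjects = 40, n_lipids_detectable = 118,
                           seed = 22),
    library_size = 600
  )
  # clean (non-failing) detectable sets
  disc_fail <- unlist(co$discovery$spec[c("blank_fail_lipids",
                                          "high_ppm_lipids",
                                          "nonlinear_qc_lipids",
                                          "high_missing_lipids")])
  val_fail <- unlist(co$validation$spec[c("blank_fail_lipids",
                                          "high_ppm_lipids",
                                          "nonlinear_qc_lipids",
                                          "high_missing_lipids")])
  disc_clean <- setdiff(co$discovery$library$name, disc_fail)
  val_clean <- setdiff(co$validation$library$name, val_fail)
  expect_equal(length(disc_clean), 163)
  expect_equal(length(val_clean), 118)
  expect_equal(length(intersect(disc_clean, val_clean)),
               round(0.71 * 118)) # = 84
  expect_identical(co$shared_lipids, intersect(co$shared_lipids, val_clean))
  # dropout lipids measured in discovery but absent from validation
  expect_true(all(co$panel_dropout %in% co$discovery$library$name))
  expect_false(any(co$panel_dropout %in% co$validation$library$name))
  # empty dropout leaves the detectable set untouched
  co2 <- make_paired_cohorts(
    cohort_spec(n_subjects = 30, n_lipids_detectable = 60, seed = 31),
    validation_cohort_spec(n_subjects = 30, n_lipids_detectable = 50,
                           seed = 32),
    panel_dropout = character(),
    panel_sizes = c(TriG = 6L, HDL = 5L, LDL = 4L, TC = 5L),
    library_size = 300
  )
  expect_equal(nrow(co2$validation$library), 50 + 12)
  am_d <- co2$discovery$spec$association_map
  am_v <- co2$validation$spec$association_map
  expect_true(all(am_d$lipid %in% am_v$lipid))
  # validation effects attenuated by attenuation^2
  j <- match(am_d$lipid, am_v$lipid)
  expect_equal(am_v$effect_size[j], 0.8^2 * am_d$effect_size)
})
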