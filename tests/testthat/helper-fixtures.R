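# Shared fixtures and independent oracles used across test files.

# feature_matrix straight from matrices (bypasses matching)
make_fm <- function(intensity, deviation = NULL, serum_fraction = NULL,
                    cohort_id = "test") {
  if (is.null(rownames(intensity))) {
    rownames(intensity) <- paste0("S", seq_len(nrow(intensity)))
  }
  if (is.null(colnames(intensity))) {
    colnames(intensity) <- paste0("L", seq_len(ncol(intensity)))
  }
  if (!is.null(deviation)) dimnames(deviation) <- dimnames(intensity)
  lipidpanelr:::new_feature_matrix(
    intensity, deviation, cohort_id = cohort_id,
    roles = if (is.null(serum_fraction)) "sample" else
      c("qc100", "qc50", "qc25"),
    serum_fraction = serum_fraction
  )
}

# brute-force all-pairs nearest-in-window matcher (oracle for match_spectrum)
brute_match <- function(peaks, library, window_ppm) {
  out <- tibble::tibble(
    lipid = library$name, intensity = 0, deviation_ppm = NA_real_
  )
  for (j in seq_len(nrow(library))) {
    dev <- (peaks$mz - library$expected_mz[j]) / library$expected_mz[j] * 1e6
    in_win <- which(abs(dev) <= window_ppm)
    if (length(in_win) == 0) next
    best <- in_win[order(abs(dev[in_win]), -peaks$intensity[in_win])][1]
    out$intensity[j] <- peaks$intensity[best]
    out$deviation_ppm[j] <- dev[best]
  }
  out
}

# one-line per-column predicates (oracles for the four QC filters)
oracle_keep_mass <- function(dev_col, max_ppm = 5) {
  any(!is.na(dev_col)) && mean(abs(dev_col), na.rm = TRUE) <= max_ppm
}
oracle_keep_blank <- function(sample_col, blank_col, min_ratio = 5) {
  !(mean(sample_col) < min_ratio * mean(blank_col))
}
oracle_keep_missing <- function(sample_col, max_zero_frac = 0.10) {
  !(mean(sample_col == 0) > max_zero_frac)
}
oracle_keep_qc <- function(qc_col, frac, min_r = 0.9) {
  if (stats::sd(qc_col) == 0) return(FALSE)
  stats::cor(qc_col, frac) >= min_r
}

# small paired-cohort fixture, built once per test run
small_cohorts <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_paired_cohorts(
        cohort_spec(n_subjects = 120, n_lipids_detectable = 60, seed = 11),
        validation_cohort_spec(n_subjects = 120, n_lipids_detectable = 50,
                               seed = 12),
        panel_sizes = c(TriG = 6L, HDL = 5L, LDL = 4L, TC = 5L),
        library_size = 400, effect_scale = 4
      )
    }
    cache
  }
})

# simulate a single cohort with planted TriG lipids and return the
# processed matrix + clinical table (used by recovery/degradation tests)
simulate_trig_cohort <- function(n_subjects, n_lipids = 60,
                                 n_planted = 12, effect_scale = 1,
                                 seed = 1, library_size = 200,
                                 n_detectable = NULL) {
  n_detectable <- n_detectable %||% n_lipids
  lib <- make_lipid_library(library_size, 6, seed = seed)
  clean <- withr::with_seed(seed + 7, sample(lib$name, n_detectable))
  am <- default_association_map(clean[seq_len(n_planted)],
                                panel_sizes = c(TriG = as.integer(n_planted)))
  am$effect_size <- pmin(1, effect_scale * am$effect_size)
  spec <- cohort_spec(
    n_subjects = n_subjects, n_lipids_detectable = n_detectable,
    association_map = am, seed = seed
  )
  clinical <- simulate_clinical(spec)
  sub_lib <- lib[lib$name %in% clean, ]
  spectra <- simulate_spectra(clinical, sub_lib, spec)
  proc <- process_cohort(spectra, sub_lib, cohort_id = "trig")
  list(matrix = proc$matrix, clinical = clinical, planted = am$lipid,
       spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
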