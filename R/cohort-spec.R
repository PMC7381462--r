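#' Describe a synthetic cohort
#'
#' A `cohort_spec` collects every parameter the synthetic-data generator
#' needs for one cohort: sample size, the clinical lipoprotein distribution
#' (mmol/L), how many lipids are detectable, the planted lipid-lipoprotein
#' associations, and the noise/missingness/mass-error structure of the
#' spectra. Defaults describe a plasma-like adult cohort (n = 777; TriG
#' 1.53 +/- 1.00, HDL 1.51 +/- 0.42, TC 5.83 +/- 1.08 mmol/L; 163
#' detectable lipids); [validation_cohort_spec()] gives the paediatric
#' dried-blood-spot-like counterpart.
#'
#' `clinical_means`/`clinical_sds` parameterise triglyceride (lognormal),
#' HDL (truncated normal) and a latent pre-mix total cholesterol (truncated
#' normal). LDL is then derived by the Friedewald formula
#' \eqn{LDL = TC - HDL - TriG/2.2} and the reported TC is `HDL + LDL` when
#' `tc_mode = "hdl_plus_ldl"` (the default) or the latent draw itself when
#' `tc_mode = "premix"`.
#'
#' @param n_subjects Number of subjects.
#' @param clinical_means,clinical_sds Named numeric vectors with entries
#'   `TriG`, `HDL`, `TC` (mmol/L). `TC` is the latent pre-mix total
#'   cholesterol fed to the Friedewald derivation.
#' @param n_lipids_detectable Number of clean (QC-passing) lipids whose
#'   peaks appear in subject spectra.
#' @param shared_lipid_fraction Fraction of this cohort's detectable lipids
#'   that are shared with a paired discovery cohort (used by
#'   [make_paired_cohorts()]).
#' @param association_map Tibble with columns `lipid`, `target`,
#'   `effect_size`: each row plants an association between one lipid's
#'   abundance and one clinical lipoprotein; `effect_size` is the fraction
#'   of (noise-free) intensity variance explained, so the planted
#'   correlation is `sqrt(effect_size)`. `NULL` means no planted effects.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise on intensities.
#' @param missing_rate Per-lipid probability that a subject's peak is
#'   dropped (not detected).
#' @param mass_error_ppm_sd SD of the per-peak ppm mass error.
#' @param biological_cv Scale of between-subject biological intensity
#'   variation (the planted associations live inside this term).
#' @param tc_mode How the reported TC column is produced; see Details.
#' @param n_blanks,n_qc_replicates Number of blank spectra and of replicate
#'   spectra per QC dilution level.
#' @param blank_ratio Sample-to-blank mean intensity ratio for designated
#'   blank-failing lipids (must be < 5 for the blank filter to catch them).
#' @param n_contaminants Number of off-target contaminant peaks per blank.
#' @param blank_fail_lipids,high_ppm_lipids,nonlinear_qc_lipids,high_missing_lipids
#'   Character vectors of lipid names planted to fail, respectively, the
#'   blank-ratio, mass-deviation, QC-linearity and missingness filters.
#' @param high_missing_rate Zero probability used for `high_missing_lipids`.
#' @param high_ppm_mean Mean ppm mass error for `high_ppm_lipids`.
#' @param seed Integer seed; all draws for this cohort flow from it.
#'
#' @return A list of class `cohort_spec`.
#' @seealso [simulate_clinical()], [simulate_spectra()],
#'   [make_paired_cohorts()]
#' @export
cohort_spec <- function(n_subjects = 777,
                        clinical_means = c(TriG = 1.53, HDL = 1.51, TC = 5.83),
                        clinical_sds = c(TriG = 1.00, HDL = 0.42, TC = 1.08),
                        n_lipids_detectable = 163,
                        shared_lipid_fraction = 0.71,
                        association_map = NULL,
                        noise_cv = 0.10,
                        missing_rate = 0.02,
                        mass_error_ppm_sd = 2,
                        biological_cv = 0.30,
                        tc_mode = c("hdl_plus_ldl", "premix"),
                        n_blanks = 3,
                        n_qc_replicates = 3,
                        blank_ratio = 3,
                        n_contaminants = 25,
                        blank_fail_lipids = character(),
                        high_ppm_lipids = character(),
                        nonlinear_qc_lipids = character(),
                        high_missing_lipids = character(),
                        high_missing_rate = 0.30,
                        high_ppm_mean = 8,
                        seed = 1L) {
  tc_mode <- match.arg(tc_mode)
  spec <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      clinical_means = clinical_means,
      clinical_sds = clinical_sds,
      n_lipids_detectable = as.integer(n_lipids_detectable),
      shared_lipid_fraction = shared_lipid_fraction,
      association_map = association_map,
      noise_cv = noise_cv,
      missing_rate = missing_rate,
      mass_error_ppm_sd = mass_error_ppm_sd,
      biological_cv = biological_cv,
      tc_mode = tc_mode,
      n_blanks = as.integer(n_blanks),
      n_qc_replicates = as.integer(n_qc_replicates),
      blank_ratio = blank_ratio,
      n_contaminants = as.integer(n_contaminants),
      blank_fail_lipids = blank_fail_lipids,
      high_ppm_lipids = high_ppm_lipids,
      nonlinear_qc_lipids = nonlinear_qc_lipids,
      high_missing_lipids = high_missing_lipids,
      high_missing_rate = high_missing_rate,
      high_ppm_mean = high_ppm_mean,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_subjects < 1L) abort("`n_subjects` must be a positive count.")
  if (spec$n_lipids_detectable < 1L) {
    abort("`n_lipids_detectable` must be a positive count.")
  }
  need <- c("TriG", "HDL", "TC")
  if (!all(need %in% names(spec$clinical_means)) ||
      !all(need %in% names(spec$clinical_sds))) {
    abort("`clinical_means` and `clinical_sds` need entries TriG, HDL, TC.")
  }
  if (any(spec$clinical_means[c("HDL", "TC")] <= 0) ||
      spec$clinical_means[["TriG"]] < 0) {
    abort("Clinical means must be positive (TriG may be 0).")
  }
  if (any(spec$clinical_sds[need] < 0)) abort("Clinical SDs must be >= 0.")
  props <- c(spec$shared_lipid_fraction, spec$missing_rate,
             spec$high_missing_rate)
  if (any(props < 0 | props > 1)) {
    abort("Proportions (shared fraction, missing rates) must lie in [0, 1].")
  }
  if (spec$noise_cv < 0 || spec$biological_cv < 0 ||
      spec$mass_error_ppm_sd < 0) {
    abort("Noise parameters must be >= 0.")
  }
  if (!is.null(spec$association_map)) {
    am <- spec$association_map
    if (!all(c("lipid", "target", "effect_size") %in% names(am))) {
      abort("`association_map` needs columns lipid, target, effect_size.")
    }
    if (!all(am$target %in% CLINICAL_TARGETS)) {
      abort("`association_map$target` must be one of TriG, HDL, LDL, TC.")
    }
    if (any(am$effect_size < 0 | am$effect_size > 1)) {
      abort("`effect_size` is a variance fraction and must lie in [0, 1].")
    }
    if (anyDuplicated(am$lipid)) {
      abort("Each lipid may carry at most one planted association.")
    }
  }
  spec
}

#' @rdname cohort_spec
#' @param ... Overrides passed on to [cohort_spec()].
#' @export
validation_cohort_spec <- function(...) {
  defaults <- list(
    n_subjects = 835,
    clinical_means = c(TriG = 0.97, HDL = 1.48, TC = 4.09),
    clinical_sds = c(TriG = 0.54, HDL = 0.32, TC = 0.65),
    n_lipids_detectable = 118,
    shared_lipid_fraction = 0.71,
    seed = 2L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_spec, args)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  subjects:", x$n_subjects,
      " detectable lipids:", x$n_lipids_detectable, "\n")
  cm <- x$clinical_means
  cs <- x$clinical_sds
  cat(sprintf("  TriG %.2f+/-%.2f  HDL %.2f+/-%.2f  TC(premix) %.2f+/-%.2f mmol/L\n",
              cm["TriG"], cs["TriG"], cm["HDL"], cs["HDL"],
              cm["TC"], cs["TC"]))
  n_assoc <- if (is.null(x$association_map)) 0L else nrow(x$association_map)
  cat("  planted associations:", n_assoc,
      " noise_cv:", x$noise_cv,
      " missing_rate:", x$missing_rate, "\n")
  cat("  tc_mode:", x$tc_mode, " seed:", x$seed, "\n")
  invisible(x)
}

#' Default planted association map for paired cohorts
#'
#' Assigns lipid names to the four clinical lipoproteins with effect sizes
#' (variance fractions) calibrated so that each planted panel, taken
#' together, predicts its lipoprotein at the accuracy typical of adult
#' plasma cohorts (panel r of about 0.91 for TriG, 0.75 HDL, 0.56 LDL,
#' 0.42 TC). For a panel of k lipids sharing the lipoprotein factor with
#' variance fraction f, the optimally combined panel correlates at
#' \eqn{r = \sqrt{f / (f + (1-f)/k)}}, so the calibrated effect (equal
#' across the panel, as the closed form assumes) is
#' \eqn{f = r^2 / (k (1 - r^2) + r^2)}.
#'
#' The closed form describes noise-free abundances; the default
#' simulation chain (multiplicative measurement noise, missingness,
#' total-signal normalisation) attenuates realised per-lipid correlations
#' by a further factor of about 0.76, so effects are inflated by
#' `1 / chain_attenuation^2` to land the *processed-matrix* correlations
#' on the calibrated targets.
#'
#' @param lipids Character vector of candidate lipid names; the first
#'   `sum(panel_sizes)` are used in order.
#' @param panel_sizes Named integer vector: planted panel size per target.
#' @param panel_r Named numeric vector: target panel-level correlation per
#'   lipoprotein.
#' @param chain_attenuation Realised-over-designed per-lipid correlation
#'   ratio of the default processing chain; set to 1 for the bare
#'   closed-form effects.
#' @return A tibble with columns `lipid`, `target`, `effect_size`.
#' @export
default_association_map <- function(lipids,
                                    panel_sizes = c(TriG = 12L, HDL = 11L,
                                                    LDL = 10L, TC = 11L),
                                    panel_r = c(TriG = 0.914, HDL = 0.748,
                                                LDL = 0.556, TC = 0.424),
                                    chain_attenuation = 0.76) {
  stopifnot(all(names(panel_sizes) %in% CLINICAL_TARGETS),
            all(names(panel_sizes) %in% names(panel_r)))
  total <- sum(panel_sizes)
  if (length(lipids) < total) {
    abort(sprintf("Need at least %d lipid names, got %d.",
                  total, length(lipids)))
  }
  pieces <- vector("list", length(panel_sizes))
  offset <- 0L
  for (i in seq_along(panel_sizes)) {
    tgt <- names(panel_sizes)[i]
    k <- panel_sizes[[i]]
    r2 <- panel_r[[tgt]]^2
    f <- r2 / (k * (1 - r2) + r2) / chain_attenuation^2
    pieces[[i]] <- tibble(
      lipid = lipids[offset + seq_len(k)],
      target = tgt,
      effect_size = rep(min(f, 0.9), k)
    )
    offset <- offset + k
  }
  bind_rows(pieces)
}
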