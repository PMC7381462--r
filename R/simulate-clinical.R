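#' Simulate a clinical lipoprotein table
#'
#' Draws per-subject triglyceride (right-skewed lognormal, moment-matched
#' to the requested mean/SD), HDL and a latent pre-mix total cholesterol
#' (normals truncated at zero), then derives LDL with the Friedewald
#' formula \eqn{LDL = TC_{premix} - HDL - TriG/2.2} (all mmol/L). The
#' reported `TC` column is `HDL + LDL` under the default
#' `tc_mode = "hdl_plus_ldl"`, or the latent draw under `"premix"`.
#'
#' Draws producing non-positive LDL are rejected and redrawn; if more than
#' 5% of the initial draws are non-positive a warning is raised, and
#' generation fails after 50 resampling rounds.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `TriG`, `HDL`, `LDL`, `TC`
#'   (mmol/L), `spec$n_subjects` rows.
#' @examples
#' simulate_clinical(cohort_spec(n_subjects = 50, seed = 1))
#' @export
simulate_clinical <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_subjects
  mu <- spec$clinical_means
  sig <- spec$clinical_sds

  draw <- function(k) {
    trig <- rlnorm_moments(k, mu[["TriG"]], sig[["TriG"]])
    hdl <- rnorm_trunc_pos(k, mu[["HDL"]], sig[["HDL"]])
    tc_premix <- rnorm_trunc_pos(k, mu[["TC"]], sig[["TC"]])
    ldl <- tc_premix - hdl - trig / 2.2
    tibble(TriG = trig, HDL = hdl, LDL = ldl, tc_premix = tc_premix)
  }

  out <- withr::with_seed(spec$seed, {
    d <- draw(n)
    bad <- d$LDL <= 0
    if (mean(bad) > 0.05) {
      warn(sprintf(
        "%.1f%% of draws gave non-positive Friedewald LDL; resampling.",
        100 * mean(bad)
      ))
    }
    tries <- 0L
    while (any(bad)) {
      tries <- tries + 1L
      if (tries > 50L) {
        abort("Could not generate positive LDL within 50 resampling rounds; check clinical means/SDs.")
      }
      d[bad, ] <- draw(sum(bad))
      bad <- d$LDL <= 0
    }
    d
  })

  tc <- if (spec$tc_mode == "premix") out$tc_premix else out$HDL + out$LDL
  tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    TriG = out$TriG, HDL = out$HDL, LDL = out$LDL, TC = tc
  )
}

# lognormal with given arithmetic mean and SD; sd = 0 degenerates to mean
rlnorm_moments <- function(n, mean, sd) {
  if (mean == 0 || sd == 0) return(rep(mean, n))
  sdlog2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# normal truncated at (just above) zero by rejection
rnorm_trunc_pos <- function(n, mean, sd, floor = 1e-3) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- x <= floor
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x <= floor
  }
  x
}
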