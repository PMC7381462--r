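#' Simulate centroided direct-infusion spectra for a cohort
#'
#' Generates one centroided peak list per subject plus blank spectra and a
#' three-level QC dilution series (100/50/25% serum), emulating
#' direct-infusion lipidomics after centroiding: one centroid per
#' detectable lipid per sample, no isotopes or adducts.
#'
#' The intensity model per subject i and lipid j is
#' \deqn{x_{ij} = b_j \, (1 + c_{bio}(\sqrt{f_j}\, z_{i} +
#'   \sqrt{1-f_j}\,\epsilon_{ij}))\, \eta_{ij}}
#' where \eqn{b_j} is a lipid baseline, \eqn{z_i} the subject's
#' standardised concentration of the lipid's associated lipoprotein,
#' \eqn{f_j} the planted variance fraction from the spec's
#' `association_map` (0 when unplanted), \eqn{\epsilon} unit Gaussian
#' biological noise and \eqn{\eta} lognormal measurement noise with CV
#' `noise_cv`. The noise-free correlation between \eqn{x_{ij}} and the
#' lipoprotein is therefore \eqn{\sqrt{f_j}}. Peaks are placed at the
#' expected m/z perturbed by Normal(0, `mass_error_ppm_sd`) ppm and dropped
#' with probability `missing_rate`.
#'
#' Planted QC failures: `high_ppm_lipids` get mean ppm error
#' `high_ppm_mean`; `blank_fail_lipids` appear in blanks at
#' `1/blank_ratio` of their sample baseline; `nonlinear_qc_lipids` respond
#' inversely to serum fraction in the QC series; `high_missing_lipids` are
#' zeroed at `high_missing_rate`. Blanks otherwise contain only off-target
#' contaminant peaks.
#'
#' @param clinical A clinical table from [simulate_clinical()] (or any
#'   tibble with `subject_id` and the lipoprotein columns).
#' @param library Lipid targets (tibble `name`, `lipid_class`,
#'   `expected_mz`): the detectable set for this cohort.
#' @param spec The [cohort_spec()] controlling noise, missingness, QC
#'   design and planted associations.
#' @return A tibble of peaks with columns `sample_id`, `role`, `batch`,
#'   `mz`, `intensity`; m/z strictly increasing within each sample.
#' @export
simulate_spectra <- function(clinical, library, spec) {
  validate_cohort_spec(spec)
  if (nrow(library) == 0) abort("`library` must be nonempty.")
  if (nrow(clinical) == 0) abort("`clinical` must be nonempty.")
  am <- spec$association_map
  if (!is.null(am) && !all(am$lipid %in% library$name)) {
    missing <- setdiff(am$lipid, library$name)
    abort(paste0("association_map references lipids absent from library: ",
                 paste(missing, collapse = ", ")))
  }

  n <- nrow(clinical)
  p <- nrow(library)
  lip <- library$name
  mz0 <- library$expected_mz

  f <- stats::setNames(rep(0, p), lip)
  tgt <- stats::setNames(rep(NA_character_, p), lip)
  if (!is.null(am)) {
    f[am$lipid] <- am$effect_size
    tgt[am$lipid] <- am$target
  }
  ppm_mu <- ifelse(lip %in% spec$high_ppm_lipids, spec$high_ppm_mean, 0)
  miss_rate <- ifelse(lip %in% spec$high_missing_lipids,
                      spec$high_missing_rate, spec$missing_rate)

  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  meas_noise <- function(k) {
    if (sdlog == 0) rep(1, k) else exp(rnorm(k, -sdlog^2 / 2, sdlog))
  }
  ppm_draw <- function(k, mu) rnorm(k, mu, spec$mass_error_ppm_sd)

  withr::with_seed(spec$seed + 101L, {
    baseline <- rlnorm(p, log(1e5), 1)

    # subject z-scores of each lipoprotein actually used by the map
    zmat <- matrix(0, n, p)
    for (t in unique(stats::na.omit(tgt))) {
      v <- clinical[[t]]
      z <- if (sd(v) > 0) (v - mean(v)) / sd(v) else rep(0, n)
      zmat[, tgt == t & !is.na(tgt)] <- z
    }
    eps <- matrix(rnorm(n * p), n, p)
    latent <- sweep(zmat, 2, sqrt(f), `*`) +
      sweep(eps, 2, sqrt(1 - f), `*`)
    mult <- pmax(1 + spec$biological_cv * latent, 0.01)
    x <- sweep(mult, 2, baseline, `*`) * matrix(meas_noise(n * p), n, p)
    drop_mask <- matrix(runif(n * p), n, p) <
      matrix(miss_rate, n, p, byrow = TRUE)
    x[drop_mask] <- 0
    ppm <- matrix(ppm_draw(n * p, rep(ppm_mu, each = n)), n, p)
    mz_obs <- sweep(1 + ppm * 1e-6, 2, mz0, `*`)

    subj_peaks <- peaks_from_matrices(clinical$subject_id, "sample",
                                      x, mz_obs)

    # QC dilution series: pooled serum, so no biological term
    qc_pieces <- list()
    nonlin <- lip %in% spec$nonlinear_qc_lipids
    for (role in names(QC_FRACTIONS)) {
      frac <- QC_FRACTIONS[[role]]
      scale_j <- ifelse(nonlin, 1.25 - frac, frac)
      for (r in seq_len(spec$n_qc_replicates)) {
        xi <- baseline * scale_j * meas_noise(p)
        mzi <- mz0 * (1 + ppm_draw(p, ppm_mu) * 1e-6)
        qc_pieces[[paste(role, r)]] <- peaks_from_matrices(
          sprintf("%s_%d", toupper(role), r), role,
          matrix(xi, 1), matrix(mzi, 1)
        )
      }
    }

    # blanks: contaminants + planted blank-failing lipids
    blank_pieces <- list()
    bf <- lip %in% spec$blank_fail_lipids
    contam_mz <- draw_contaminant_mz(spec$n_contaminants, mz0)
    for (r in seq_len(spec$n_blanks)) {
      xi <- ifelse(bf, baseline / spec$blank_ratio * meas_noise(p), 0)
      mzi <- mz0 * (1 + ppm_draw(p, ppm_mu) * 1e-6)
      lip_part <- tibble(mz = mzi[bf & xi > 0], intensity = xi[bf & xi > 0])
      con_part <- tibble(
        mz = contam_mz,
        intensity = rlnorm(length(contam_mz), log(1e3), 0.5)
      )
      pk <- bind_rows(lip_part, con_part) |> arrange(.data$mz)
      blank_pieces[[r]] <- tibble(
        sample_id = sprintf("BLANK_%d", r), role = "blank",
        batch = "B1", mz = pk$mz, intensity = pk$intensity
      )
    }

    bind_rows(subj_peaks, bind_rows(qc_pieces), bind_rows(blank_pieces))
  })
}

# melt intensity/mz matrices (rows = samples) into sorted peak tibbles,
# dropping zero-intensity (undetected) entries
peaks_from_matrices <- function(ids, role, x, mz) {
  keep <- x > 0
  idx <- which(keep, arr.ind = TRUE)
  out <- tibble(
    sample_id = ids[idx[, 1]], role = role, batch = "B1",
    mz = mz[keep], intensity = x[keep]
  )
  arrange(out, .data$sample_id, .data$mz)
}

# contaminant m/z at least 100 ppm away from every library target
draw_contaminant_mz <- function(k, targets, range = c(150, 2000)) {
  if (k == 0) return(numeric())
  out <- numeric(0)
  while (length(out) < k) {
    cand <- runif(2 * k, range[1], range[2])
    ok <- vapply(cand, function(m) {
      min(abs(m - targets) / targets) * 1e6 > 100
    }, logical(1))
    out <- c(out, cand[ok])
  }
  sort(out[seq_len(k)])
}

#' Generate linked discovery and validation cohorts
#'
#' Builds a shared lipid library, carves out the detectable lipid sets of a
#' plasma-like discovery cohort and a DBS-like validation cohort (with a
#' configurable shared fraction), plants lipid-lipoprotein association
#' panels that are recoverable in both cohorts, adds per-filter failing
#' lipids so every QC filter has positive cases, and simulates clinical
#' tables and spectra for both cohorts.
#'
#' The validation cohort's planted effect sizes are multiplied by
#' `attenuation^2`, so planted correlations scale linearly with
#' `attenuation`; `attenuation = 0` removes all transferable signal.
#' `panel_dropout` lipids are removed from the validation cohort's
#' detectable set, emulating panel members not measurable in dried blood
#' spots.
#'
#' @param discovery_spec,validation_spec [cohort_spec()]s for the two
#'   cohorts. Their `association_map`s are filled in from
#'   [default_association_map()] when `NULL`.
#' @param panel_dropout Lipid names to exclude from the validation
#'   detectable set; `NULL` picks the two weakest planted TriG lipids,
#'   `character()` drops none.
#' @param attenuation Multiplier on planted correlations in the validation
#'   cohort, in `[0, 1]`.
#' @param panel_sizes Planted panel sizes per lipoprotein.
#' @param library_size,n_classes Size and class count of the full target
#'   library.
#' @param n_failing_per_filter Planted failing lipids (per filter, per
#'   cohort) added on top of the clean detectable sets.
#' @param effect_scale Multiplier applied to the default planted effect
#'   sizes (capped at 1); useful for stronger-signal demonstration
#'   cohorts. Ignored when the discovery spec supplies its own map.
#' @return A list of class `paired_cohorts` with elements `discovery` and
#'   `validation` (each `spectra`, `clinical`, `library`, `spec`),
#'   `shared_lipids`, `panel_dropout`, `attenuation` and the full `library`.
#' @export
make_paired_cohorts <- function(discovery_spec = cohort_spec(),
                                validation_spec = validation_cohort_spec(),
                                panel_dropout = NULL,
                                attenuation = 0.8,
                                panel_sizes = c(TriG = 12L, HDL = 11L,
                                                LDL = 10L, TC = 11L),
                                library_size = 1649,
                                n_classes = 11,
                                n_failing_per_filter = 3L,
                                effect_scale = 1) {
  stopifnot(attenuation >= 0, attenuation <= 1)
  n_assoc <- sum(panel_sizes)
  full_lib <- make_lipid_library(library_size, n_classes,
                                 seed = discovery_spec$seed)
  n_disc <- discovery_spec$n_lipids_detectable
  n_val <- validation_spec$n_lipids_detectable
  n_shared <- round(validation_spec$shared_lipid_fraction * n_val)
  n_fail <- 4L * n_failing_per_filter
  if (n_disc < n_assoc + 10L) {
    abort(sprintf(
      "Discovery detectable set (%d) too small for %d planted lipids.",
      n_disc, n_assoc
    ))
  }
  if (library_size < n_disc + n_val + 2L * n_fail) {
    abort("Library too small for the requested detectable + failing sets.")
  }

  sets <- withr::with_seed(discovery_spec$seed + 211L, {
    disc_clean <- sample(full_lib$name, n_disc)
    assoc_lipids <- sample(disc_clean, n_assoc)
    am_disc <- discovery_spec$association_map %||% {
      am <- default_association_map(assoc_lipids, panel_sizes)
      am$effect_size <- pmin(1, effect_scale * am$effect_size)
      am
    }

    dropout <- panel_dropout %||% {
      trig <- am_disc$lipid[am_disc$target == "TriG"]
      utils::tail(trig, 2L)
    }
    if (!all(dropout %in% disc_clean)) {
      abort("`panel_dropout` must be a subset of the discovery lipids.")
    }
    transferable <- setdiff(am_disc$lipid, dropout)
    if (length(intersect(am_disc$lipid, dropout)) > 0 &&
        length(transferable) == 0) {
      warn("panel_dropout removes every planted panel lipid; panels unlearnable in validation.")
    }
    if (n_shared < length(transferable)) {
      abort("shared_lipid_fraction too small to carry the planted panels.")
    }
    shared <- c(transferable,
                sample(setdiff(disc_clean, c(am_disc$lipid, dropout)),
                       n_shared - length(transferable)))
    val_only <- sample(setdiff(full_lib$name, union(disc_clean, dropout)),
                       n_val - n_shared)
    val_clean <- c(shared, val_only)

    pool <- setdiff(full_lib$name, union(disc_clean, val_clean))
    fail_names <- sample(pool, 2L * n_fail)
    split_fail <- function(v) {
      k <- n_failing_per_filter
      list(blank = v[seq_len(k)], ppm = v[k + seq_len(k)],
           missing = v[2L * k + seq_len(k)], nonlinear = v[3L * k + seq_len(k)])
    }
    list(disc_clean = disc_clean, val_clean = val_clean, shared = shared,
         am_disc = am_disc, dropout = dropout,
         disc_fail = split_fail(fail_names[seq_len(n_fail)]),
         val_fail = split_fail(fail_names[n_fail + seq_len(n_fail)]))
  })

  am_val <- sets$am_disc |>
    filter(.data$lipid %in% sets$val_clean) |>
    mutate(effect_size = pmin(1, attenuation^2 * .data$effect_size))
  if (nrow(am_val) == 0) am_val <- NULL

  fill_spec <- function(spec, am, fail) {
    spec$association_map <- am
    spec$blank_fail_lipids <- fail$blank
    spec$high_ppm_lipids <- fail$ppm
    spec$high_missing_lipids <- fail$missing
    spec$nonlinear_qc_lipids <- fail$nonlinear
    validate_cohort_spec(spec)
  }
  discovery_spec <- fill_spec(discovery_spec, sets$am_disc, sets$disc_fail)
  validation_spec <- fill_spec(validation_spec, am_val, sets$val_fail)

  lib_of <- function(clean, fail) {
    full_lib |>
      filter(.data$name %in% c(clean, unlist(fail))) |>
      arrange(.data$expected_mz)
  }
  disc_lib <- lib_of(sets$disc_clean, sets$disc_fail)
  val_lib <- lib_of(sets$val_clean, sets$val_fail)

  clin_d <- simulate_clinical(discovery_spec)
  clin_v <- simulate_clinical(validation_spec)
  structure(
    list(
      discovery = list(
        spectra = simulate_spectra(clin_d, disc_lib, discovery_spec),
        clinical = clin_d, library = disc_lib, spec = discovery_spec
      ),
      validation = list(
        spectra = simulate_spectra(clin_v, val_lib, validation_spec),
        clinical = clin_v, library = val_lib, spec = validation_spec
      ),
      shared_lipids = sets$shared,
      panel_dropout = sets$dropout,
      attenuation = attenuation,
      library = full_lib
    ),
    class = "paired_cohorts"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.paired_cohorts <- function(x, ...) {
  cat("<paired_cohorts>\n")
  cat("  discovery :", x$discovery$spec$n_subjects, "subjects,",
      nrow(x$discovery$library), "library targets\n")
  cat("  validation:", x$validation$spec$n_subjects, "subjects,",
      nrow(x$validation$library), "library targets\n")
  cat("  shared lipids:", length(x$shared_lipids),
      " dropout:", paste(x$panel_dropout, collapse = ", "), "\n")
  cat("  attenuation:", x$attenuation, "\n")
  invisible(x)
}
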