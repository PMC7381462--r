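#' Run the full discovery-to-validation pipeline
#'
#' Sequences every stage on a pair of (by default synthetic) cohorts:
#' simulate paired cohorts, match spectra, apply the four QC filters plus
#' TIC normalisation and per-cohort mean centering, discover a minimal
#' lipid panel per clinical lipoprotein in the discovery cohort, translate
#' and retrain each panel in the validation cohort, fit per-lipid GLMs in
#' both cohorts with Bonferroni control and their cross-cohort
#' concordance, and stratify test-set predictions (clinical cut-offs in
#' the discovery cohort, quartiles in the validation cohort).
#'
#' All randomness flows from `seed` and the cohort specs' own seeds; two
#' runs with identical inputs produce identical manifests.
#'
#' @param discovery_spec,validation_spec [cohort_spec()]s; defaults are
#'   the plasma-like (n = 777) and DBS-like (n = 835) study conditions.
#' @param cohorts Optionally, a precomputed [make_paired_cohorts()] result
#'   (then the specs are ignored).
#' @param targets Clinical lipoproteins to model.
#' @param window_ppm Matching window.
#' @param tolerance Panel-growth stopping tolerance.
#' @param rf Random-forest configuration.
#' @param seed Master seed for splits.
#' @param attenuation Validation-cohort effect attenuation (passed to
#'   [make_paired_cohorts()]).
#' @param outdir Optional directory; when given, matrices, reports and the
#'   manifest are written there as TSV/JSON.
#' @return A `run_manifest` list: per-cohort lipid counts and filter
#'   reports, `panels` and `translations` (named by target), association
#'   tables, `concordance`, `overlap` tables (8 = 4 lipoproteins x
#'   clinical/quartile), seeds and checksums.
#' @export
run_pipeline <- function(discovery_spec = cohort_spec(),
                         validation_spec = validation_cohort_spec(),
                         cohorts = NULL,
                         targets = CLINICAL_TARGETS,
                         window_ppm = 10, tolerance = 0.01,
                         rf = rf_config(), seed = 1L,
                         attenuation = 0.8,
                         outdir = NULL) {
  cohorts <- cohorts %||% make_paired_cohorts(discovery_spec,
                                              validation_spec,
                                              attenuation = attenuation)
  proc_d <- process_cohort(cohorts$discovery$spectra,
                           cohorts$discovery$library,
                           window_ppm = window_ppm, cohort_id = "discovery")
  proc_v <- process_cohort(cohorts$validation$spectra,
                           cohorts$validation$library,
                           window_ppm = window_ppm, cohort_id = "validation")
  clin_d <- cohorts$discovery$clinical
  clin_v <- cohorts$validation$clinical

  panels <- list()
  translations <- list()
  overlaps <- list()
  assoc_d <- list()
  assoc_v <- list()
  conc <- list()
  for (tg in targets) {
    cfg <- rf_config(ntree = rf$ntree, mtry = rf$mtry,
                     seed = rf$seed + match(tg, CLINICAL_TARGETS))
    pm <- discover_panel(proc_d$matrix, clin_d, tg,
                         split = split_spec(seed = seed),
                         config = cfg, tolerance = tolerance)
    rec <- translate_panel(pm, proc_v$matrix)
    rec <- validate_in_cohort(rec, proc_v$matrix, clin_v,
                              split = split_spec(seed = seed + 100L),
                              config = cfg)
    panels[[tg]] <- pm
    translations[[tg]] <- rec
    overlaps[[paste0(tg, "_clinical")]] <-
      stratify_predictions(pm, "clinical")
    overlaps[[paste0(tg, "_quartile")]] <-
      stratify_predictions(rec$model, "quartile")
    assoc_d[[tg]] <- glm_per_lipid(proc_d$matrix, clin_d, tg)
    assoc_v[[tg]] <- glm_per_lipid(proc_v$matrix, clin_v, tg)
    conc[[tg]] <- concordance(assoc_d[[tg]], assoc_v[[tg]])
  }

  manifest <- structure(
    list(
      version = as.character(packageVersion("lipidpanelr")),
      seed = seed,
      cohort_seeds = c(discovery = cohorts$discovery$spec$seed,
                       validation = cohorts$validation$spec$seed),
      params = list(window_ppm = window_ppm, tolerance = tolerance,
                    rf = unclass(rf), attenuation = cohorts$attenuation),
      counts = tibble(
        cohort = c("discovery", "validation"),
        n_subjects = c(nrow(clin_d), nrow(clin_v)),
        lipids_matched = c(nrow(cohorts$discovery$library),
                           nrow(cohorts$validation$library)),
        lipids_retained = c(length(lipids(proc_d$matrix)),
                            length(lipids(proc_v$matrix)))
      ),
      filter_reports = list(discovery = proc_d$report,
                            validation = proc_v$report),
      panels = panels,
      translations = translations,
      associations = list(discovery = assoc_d, validation = assoc_v),
      concordance = conc,
      overlap = overlaps,
      panel_dropout = cohorts$panel_dropout,
      shared_lipids = cohorts$shared_lipids
    ),
    class = "run_manifest"
  )
  manifest$checksums <- c(
    panels = object_checksum(lapply(panels, glance)),
    translations = object_checksum(lapply(translations, glance)),
    overlap = object_checksum(lapply(overlaps, as_tibble)),
    counts = object_checksum(manifest$counts)
  )

  if (!is.null(outdir)) write_manifest(manifest, proc_d, proc_v, outdir)
  manifest
}

write_manifest <- function(manifest, proc_d, proc_v, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_feature_matrix(proc_d$matrix, file.path(outdir, "discovery"))
  write_feature_matrix(proc_v$matrix, file.path(outdir, "validation"))
  tsv <- function(df, name) {
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(manifest$counts, "counts.tsv")
  tsv(bind_rows(lapply(manifest$panels, glance)), "panels.tsv")
  tsv(bind_rows(lapply(manifest$translations, glance)), "translations.tsv")
  tsv(bind_rows(lapply(names(manifest$overlap), function(nm) {
    mutate(as_tibble(manifest$overlap[[nm]]), table = nm)
  })), "overlap.tsv")
  summary <- list(
    version = manifest$version, seed = manifest$seed,
    cohort_seeds = as.list(manifest$cohort_seeds),
    params = manifest$params,
    checksums = as.list(manifest$checksums)
  )
  jsonlite::write_json(summary, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> lipidpanelr", x$version, "\n")
  print(x$counts)
  cat("\nPanels (discovery -> validation test r):\n")
  for (tg in names(x$panels)) {
    pm <- x$panels[[tg]]
    vr <- x$translations[[tg]]$model$test_r
    cat(sprintf("  %-4s panel %2d lipids  r = %.3f -> %.3f (%d dropped)\n",
                tg, length(pm$panel), pm$test_r, vr,
                length(x$translations[[tg]]$lipids_missing)))
  }
  invisible(x)
}
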