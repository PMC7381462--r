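#' Write spectra as per-sample tabular peak lists
#'
#' Writes one TSV per sample (columns `mz`, `intensity`; commented header
#' lines carry the sample id, role and batch) plus a `manifest.tsv`
#' mapping `sample_id` to file and role.
#'
#' @param spectra Long peak tibble (`sample_id`, `role`, `batch`, `mz`,
#'   `intensity`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble (`sample_id`, `file`, `role`,
#'   `batch`).
#' @export
write_peaklists <- function(spectra, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- spectra |>
    dplyr::distinct(.data$sample_id, .data$role, .data$batch) |>
    mutate(file = paste0(gsub("[^A-Za-z0-9_.-]", "_", .data$sample_id),
                         ".tsv"))
  for (i in seq_len(nrow(meta))) {
    pk <- spectra[spectra$sample_id == meta$sample_id[i],
                  c("mz", "intensity")]
    path <- file.path(dir, meta$file[i])
    con <- file(path, "w")
    writeLines(c(
      paste0("# sample_id=", meta$sample_id[i]),
      paste0("# role=", meta$role[i]),
      paste0("# batch=", meta$batch[i])
    ), con)
    out <- data.frame(mz = sprintf("%.17g", pk$mz),
                      intensity = sprintf("%.17g", pk$intensity))
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  manifest <- select(meta, "sample_id", "file", "role", "batch")
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read peak lists listed in a manifest
#'
#' Validates roles and peak ordering: m/z must be strictly increasing and
#' intensities non-negative within each file.
#'
#' @param manifest Path to a `manifest.tsv` written by
#'   [write_peaklists()] (or a directory containing one).
#' @return A long peak tibble (`sample_id`, `role`, `batch`, `mz`,
#'   `intensity`).
#' @export
read_peaklists <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.tsv")
  if (!file.exists(manifest)) abort(paste0("No manifest at ", manifest))
  dir <- dirname(manifest)
  man <- as_tibble(read.delim(manifest, sep = "\t",
                              colClasses = "character"))
  bad_roles <- setdiff(unique(man$role), SAMPLE_ROLES)
  if (length(bad_roles) > 0) {
    abort(paste0("Unknown role(s) in manifest: ",
                 paste(bad_roles, collapse = ", ")))
  }
  pieces <- purrr::pmap(man, function(sample_id, file, role, batch, ...) {
    path <- file.path(dir, file)
    if (!file.exists(path)) abort(paste0("Missing peak list: ", path))
    pk <- read.delim(path, sep = "\t", comment.char = "#")
    if (any(pk$intensity < 0)) {
      abort(paste0("Negative intensity in ", file))
    }
    if (nrow(pk) > 1 && is.unsorted(pk$mz, strictly = TRUE)) {
      first_bad <- which(diff(pk$mz) <= 0)[1] + 1L
      abort(sprintf("%s: m/z not strictly increasing at row %d",
                    file, first_bad))
    }
    tibble(sample_id = sample_id, role = role, batch = batch,
           mz = pk$mz, intensity = pk$intensity)
  })
  bind_rows(pieces)
}

#' Write and read feature matrices
#'
#' A `feature_matrix` round-trips through three plain-text files sharing a
#' prefix: `<prefix>_intensity.tsv`, `<prefix>_deviation.tsv` and
#' `<prefix>_meta.json` (cohort id, roles, transform log, serum
#' fractions).
#'
#' @param m A `feature_matrix`.
#' @param prefix Path prefix for the output files.
#' @return `write_feature_matrix()` returns the file paths invisibly;
#'   `read_feature_matrix()` returns the restored `feature_matrix`.
#' @export
write_feature_matrix <- function(m, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- paste0(prefix, c("_intensity.tsv", "_deviation.tsv",
                            "_meta.json"))
  write_mat <- function(mat, path) {
    chr <- apply(mat, 2, function(v) sprintf("%.17g", v))
    chr[is.na(mat)] <- "NA"
    df <- data.frame(sample_id = rownames(mat), chr, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(m$intensity, paths[1])
  write_mat(m$deviation, paths[2])
  jsonlite::write_json(
    list(cohort_id = m$cohort_id, roles = m$roles,
         sample_roles = as.list(m$sample_roles %||% list()),
         serum_fraction = as.list(m$serum_fraction %||% list()),
         transform_log = m$transform_log),
    paths[3], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(prefix) {
  read_mat <- function(path) {
    df <- read.delim(path, sep = "\t", check.names = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    mode(mat) <- "numeric"
    rownames(mat) <- df$sample_id
    mat
  }
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  sr <- if (length(meta$sample_roles) > 0) unlist(meta$sample_roles) else NULL
  sf <- if (length(meta$serum_fraction) > 0) {
    unlist(meta$serum_fraction)
  } else {
    NULL
  }
  new_feature_matrix(
    read_mat(paste0(prefix, "_intensity.tsv")),
    read_mat(paste0(prefix, "_deviation.tsv")),
    cohort_id = meta$cohort_id, roles = meta$roles,
    sample_roles = sr, serum_fraction = sf,
    transform_log = as.character(meta$transform_log %||% character())
  )
}

#' Write or read a cohort specification as YAML
#'
#' @param spec A [cohort_spec()].
#' @param path File path.
#' @return `read_cohort_config()` returns a `cohort_spec`.
#' @export
write_cohort_config <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- unclass(spec)
  # yaml drops names on atomic vectors; maps survive as lists
  for (nm in c("clinical_means", "clinical_sds")) x[[nm]] <- as.list(x[[nm]])
  if (!is.null(x$association_map)) {
    x$association_map <- as.list(as.data.frame(x$association_map))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$association_map)) {
    x$association_map <- as_tibble(x$association_map)
  }
  for (nm in c("clinical_means", "clinical_sds")) x[[nm]] <- unlist(x[[nm]])
  do.call(cohort_spec, x)
}

# md5 of an arbitrary R object via serialisation (for manifest checksums)
object_checksum <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # version 2 serialisation is stable across R sessions
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
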