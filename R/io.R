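# Plain-text persistence: tab-delimited numeric tables for matrices and
# metrics, YAML for configuration, JSON for run manifests. Everything
# written here reads back bit-exactly via full-precision formatting.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read a connectivity matrix as a delimited file
#'
#' Square tab-delimited numeric layout with a `#`-comment header carrying
#' band, subject and trial-count provenance; full `%.17g` precision so the
#' round trip is bit-exact.
#'
#' @param w a `plv_matrix` (or plain matrix).
#' @param path file path.
#' @param band,subject optional provenance overriding the matrix
#'   attributes.
#' @return `read_plv_matrix` returns the `plv_matrix`.
#' @export
write_plv_matrix <- function(w, path, band = attr(w, "band"),
                             subject = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# band=%s subject=%s n_trials=%s",
                     band %||% "NA", subject %||% "NA",
                     attr(w, "n_trials") %||% "NA"), con)
  writeLines(apply(unclass(w), 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_plv_matrix
#' @export
read_plv_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  w <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(w) <- NULL
  meta <- regmatches(header,
                     gregexpr("[a-z_]+=[^ ]+", header))[[1L]]
  kv <- strsplit(meta, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  structure(w, class = c("plv_matrix", "matrix"),
            band = if (identical(vals[["band"]], "NA")) NA_character_ else
              vals[["band"]],
            n_trials = suppressWarnings(as.integer(vals[["n_trials"]])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a delimited recording with an event table
#'
#' The sensor-space input format: a channels-in-columns numeric matrix
#' (tab/whitespace delimited, one row per sample, optional header) plus an
#' event table with columns `sample`, `condition`, `correct`.
#'
#' @param data_path path to the numeric signal matrix (samples x channels).
#' @param events_path path to the delimited event table.
#' @param sample_rate sampling rate in Hz.
#' @param header does the signal file have a header row of channel labels?
#' @return An [eeg_recording()].
#' @export
read_recording <- function(data_path, events_path, sample_rate,
                           header = FALSE) {
  mat <- as.matrix(utils::read.table(data_path, header = header))
  labels <- if (header) colnames(mat) else NULL
  dimnames(mat) <- NULL
  events <- utils::read.table(events_path, header = TRUE)
  events$correct <- as.logical(events$correct)
  eeg_recording(t(mat), sample_rate, events, labels)
}

#' Write cohort records and metric tables of a pipeline run
#'
#' Persists subject records, global (and nodal) metric tables, the
#' statistical results and a JSON manifest of the parameters actually used
#' into `config$output_dir`.
#'
#' @param result a [run_pipeline()] result whose config names an
#'   `output_dir`.
#' @return The output directory, invisibly.
#' @export
write_pipeline_result <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  dir <- result$config$output_dir
  if (is.null(dir)) stop("config has no output_dir", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(result$records, file.path(dir, "cohort_records.tsv"))
  .write_tsv(result$global, file.path(dir, "global_metrics.tsv"))
  if (!is.null(result$nodal))
    .write_tsv(result$nodal, file.path(dir, "nodal_metrics.tsv"))
  .write_tsv(result$stats$table, file.path(dir, "group_stats.tsv"))
  if (!is.null(result$nodal_stats))
    .write_tsv(result$nodal_stats, file.path(dir, "nodal_stats.tsv"))
  if (!is.null(result$correlations))
    .write_tsv(result$correlations, file.path(dir, "correlations.tsv"))
  sim <- result$config$sim
  manifest <- list(
    seed = sim$seed,
    n_subjects_per_group = sim$n_subjects_per_group,
    n_nodes = sim$n_nodes, n_trials = sim$n_trials,
    sample_rate = sim$sample_rate,
    phase_jitter_sigma = sim$phase_jitter_sigma,
    bands = result$config$bands,
    plv_window_ms = result$config$plv_window_ms,
    artifact_threshold_uv = result$config$artifact_threshold_uv,
    alpha = result$config$alpha,
    global_family_size = result$config$global_family_size,
    bonferroni_threshold = result$stats$threshold,
    covariates = result$config$covariate_cols,
    group_sizes = as.list(result$log$group_sizes))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a simulation / pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; the `sim` key holds
#' [sim_config()] arguments. Unknown keys error.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  bad <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(bad))
    stop("unknown sim config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  sim <- do.call(sim_config, sim_args)
  y$sim <- NULL
  if (!is.null(y$bands)) y$bands <- as.data.frame(y$bands)
  bad <- setdiff(names(y), names(formals(pipeline_config)))
  if (length(bad))
    stop("unknown pipeline config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, c(list(sim = sim), y))
}
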