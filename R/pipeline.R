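#' Pipeline configuration
#'
#' Validates and bundles every stage parameter of the simulate -> preprocess
#' -> localize -> connect -> metrics -> stats chain. Validation happens here,
#' before any compute: in particular the PLV window must lie inside the
#' epoch span and test-family sizes must be positive.
#'
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param bands band table, see [band_definitions()].
#' @param plv_window_ms analysis window for phase locking (ms).
#' @param artifact_threshold_uv amplitude rejection threshold (microvolts).
#' @param condition condition analysed (default `"NoGo"`, correct trials).
#' @param use_sensor_space if `TRUE`, node signals are projected to
#'   sensors through a [synthetic_gain()] forward model and mapped back with
#'   [minimum_norm_inverse()] before connectivity; if `FALSE` the generator's
#'   node signals are used directly.
#' @param n_sensors sensor count of the synthetic forward model.
#' @param sensor_noise_sd sensor noise SD (microvolts).
#' @param lambda minimum-norm regularization; `NULL` for the SNR heuristic.
#' @param snr assumed SNR for the default `lambda`.
#' @param nodal if `TRUE`, run the nodal-level statistics stage.
#' @param alpha family-wise error rate.
#' @param global_family_size Bonferroni family for the global tests
#'   (default 16 = 4 indices x 4 bands).
#' @param correlation_family_size Bonferroni family for the trauma
#'   correlations (default 60).
#' @param covariate_cols covariate columns of the cohort records.
#' @param output_dir optional directory; when set, every stage persists its
#'   artifact there.
#'
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            bands = band_definitions(),
                            plv_window_ms = c(200, 700),
                            artifact_threshold_uv = 75,
                            condition = "NoGo",
                            use_sensor_space = FALSE,
                            n_sensors = 32L,
                            sensor_noise_sd = 0.5,
                            lambda = NULL,
                            snr = 3,
                            nodal = FALSE,
                            alpha = 0.05,
                            global_family_size = 16L,
                            correlation_family_size = 60L,
                            covariate_cols = c("sai", "tai", "bdi",
                                               "caars_total"),
                            output_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  if (plv_window_ms[1L] < sim$epoch_window_ms[1L] ||
      plv_window_ms[2L] > sim$epoch_window_ms[2L] ||
      plv_window_ms[1L] >= plv_window_ms[2L])
    stop("PLV window must lie inside the epoch span", call. = FALSE)
  if (global_family_size < 1L || correlation_family_size < 1L)
    stop("test-family sizes must be >= 1", call. = FALSE)
  if (artifact_threshold_uv <= 0)
    stop("artifact threshold must be positive", call. = FALSE)
  if (any(bands$f_hi >= sim$sample_rate / 2))
    stop("band edges must stay below the Nyquist frequency", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis chain on a synthetic cohort
#'
#' Stages: cohort simulation; optional sensor projection and minimum-norm
#' localization; amplitude artifact rejection and condition selection;
#' per-band PLV connectivity in the analysis window; weighted network
#' indices; quartile grouping and covariate-adjusted group statistics with
#' Bonferroni control (plus optional nodal statistics and trauma
#' correlations). Deterministic under a fixed `sim$seed`; when
#' `output_dir` is set every stage writes its artifact and a manifest of the
#' parameters actually used.
#'
#' @param config a [pipeline_config()].
#'
#' @return Object of class `pipeline_result`: `records` (with quartile
#'   `group_label`), `global` and optionally `nodal` metric tables, `stats`
#'   ([network_group_analysis()] result), optional `nodal_stats` and
#'   `correlations`, and a `log` of per-stage bookkeeping.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()

  cohort <- generate_cohort(config$sim)
  records <- cohort$records
  log$n_subjects <- nrow(records)

  epochs <- cohort$epochs
  if (config$use_sensor_space) {
    gain <- synthetic_gain(config$n_sensors, config$sim$n_nodes,
                           seed = config$sim$seed)
    inv <- minimum_norm_inverse(gain, lambda = config$lambda, snr = config$snr)
    epochs <- lapply(seq_along(epochs), function(s) {
      sens <- project_to_sensors(epochs[[s]], gain, config$sensor_noise_sd,
                                 seed = cohort$subject_seeds[s] %% 1000000L + s)
      apply_inverse(sens, inv)
    })
    names(epochs) <- records$subject_id
    log$lambda <- inv$lambda
  }

  kept <- integer(length(epochs))
  for (s in seq_along(epochs)) {
    rej <- reject_artifacts(epochs[[s]], config$artifact_threshold_uv)
    epochs[[s]] <- rej$epochs
    kept[s] <- rej$log$n_kept
  }
  log$epochs_kept <- stats::setNames(kept, records$subject_id)

  conn <- cohort_connectivity(epochs, config$bands, config$plv_window_ms,
                              condition = config$condition)
  log$subjects_connected <- length(conn$matrices)
  log$trials_used <- conn$info

  metrics <- cohort_metrics(conn, nodal = config$nodal)

  records$group_truth <- records$group_label
  records$group_label <- assign_groups(records$ctq_total)
  log$group_sizes <- table(records$group_label)

  stats_res <- network_group_analysis(
    metrics$global, records, covariate_cols = config$covariate_cols,
    alpha = config$alpha, family_size = config$global_family_size)

  nodal_stats <- NULL
  correlations <- NULL
  if (config$nodal && !is.null(metrics$nodal)) {
    nodal_stats <- nodal_group_analysis(
      metrics$nodal, records, covariate_cols = config$covariate_cols,
      alpha = config$alpha)
    correlations <- nodal_trauma_correlations(
      metrics$nodal, records, nodal_stats,
      covariate_cols = config$covariate_cols,
      alpha = config$alpha, family_size = config$correlation_family_size)
  }

  result <- structure(
    list(records = records, global = metrics$global, nodal = metrics$nodal,
         stats = stats_res, nodal_stats = nodal_stats,
         correlations = correlations, config = config, log = log),
    class = "pipeline_result")

  if (!is.null(config$output_dir)) write_pipeline_result(result)
  result
}

#' Nodal-level covariate-adjusted group comparison
#'
#' Tests the nodal clustering coefficient of every node x band cell with
#' the same covariate-adjusted model as the global analysis, at the
#' Bonferroni threshold `alpha / n_nodes`.
#'
#' @param nodal nodal metric table from [cohort_metrics()].
#' @param records cohort data frame with `subject_id`, group and covariates.
#' @inheritParams network_group_analysis
#'
#' @return Data frame: band, node, F, p, partial eta squared, significance.
#' @export
nodal_group_analysis <- function(nodal, records, group_col = "group_label",
                                 covariate_cols = c("sai", "tai", "bdi",
                                                    "caars_total"),
                                 alpha = 0.05) {
  n_nodes <- length(unique(nodal$node))
  thr <- bonferroni_threshold(alpha, n_nodes)
  rows <- list()
  for (b in unique(nodal$band)) {
    for (nd in sort(unique(nodal$node))) {
      sel <- nodal$band == b & nodal$node == nd
      m <- match(nodal$subject[sel], records$subject_id)
      at <- ancova_group_test(nodal$clustering[sel],
                              records[[group_col]][m],
                              records[m, covariate_cols, drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        band = b, node = nd, F = at$F, p = at$p,
        partial_eta_sq = at$partial_eta_sq, significant = at$p < thr)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}

#' Partial correlations of nodal clustering with trauma measures
#'
#' For each node flagged in the nodal group analysis (or all nodes when no
#' flags exist), correlates its clustering coefficient with the trauma total
#' and subscale scores, controlling for the covariates, at the Bonferroni
#' threshold `alpha / family_size`.
#'
#' @param nodal nodal metric table.
#' @param records cohort data frame.
#' @param nodal_stats result of [nodal_group_analysis()] (optional filter).
#' @param trauma_cols trauma measure columns.
#' @inheritParams network_group_analysis
#' @param family_size Bonferroni family for the correlations (default 60).
#'
#' @return Data frame of partial correlations with significance flags.
#' @export
nodal_trauma_correlations <- function(nodal, records, nodal_stats = NULL,
                                      trauma_cols = c("ctq_total",
                                                      "ctq_physical_abuse",
                                                      "ctq_emotional_abuse",
                                                      "ctq_sexual_abuse",
                                                      "ctq_physical_neglect",
                                                      "ctq_emotional_neglect"),
                                      covariate_cols = c("sai", "tai", "bdi",
                                                         "caars_total"),
                                      alpha = 0.05, family_size = 60L) {
  thr <- bonferroni_threshold(alpha, family_size)
  cells <- unique(nodal[, c("band", "node")])
  if (!is.null(nodal_stats) && any(nodal_stats$significant)) {
    sig <- nodal_stats[nodal_stats$significant, c("band", "node")]
    cells <- merge(cells, sig)
  }
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- nodal$band == cells$band[i] & nodal$node == cells$node[i]
    m <- match(nodal$subject[sel], records$subject_id)
    covs <- records[m, covariate_cols, drop = FALSE]
    for (tc in trauma_cols) {
      pc <- partial_correlation(records[[tc]][m], nodal$clustering[sel], covs)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(band = cells$band[i], node = cells$node[i], measure = tc),
        pc, significant = pc$p < thr)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(out)) attr(out, "threshold") <- thr
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  subjects: %d (groups: %s)\n", nrow(x$records),
              paste(sprintf("%s=%d", names(x$log$group_sizes),
                            x$log$group_sizes), collapse = ", ")))
  cat(sprintf("  bands: %s | PLV window %g-%g ms\n",
              paste(x$config$bands$name, collapse = ", "),
              x$config$plv_window_ms[1L], x$config$plv_window_ms[2L]))
  n_sig <- sum(x$stats$table$significant)
  cat(sprintf("  global tests: %d/%d significant at %.6g\n",
              n_sig, nrow(x$stats$table), x$stats$threshold))
  invisible(x)
}

#' @export
summary.pipeline_result <- function(object, ...) {
  cat(render_report(object), sep = "\n")
  invisible(object)
}

#' Render a human-readable report of a pipeline run
#'
#' Group mean (SD) tables per index and band with p values, effect sizes
#' and post-hoc pairwise p values, mirroring the layout of a group
#' comparison table; plus nodal and correlation sections when those stages
#' ran.
#'
#' @param result a [run_pipeline()] result.
#'
#' @return Character vector of report lines (also printed).
#' @export
render_report <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  if (is.null(result$global) || is.null(result$stats))
    stop("result bundle is incomplete", call. = FALSE)
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  rec <- result$records
  add("== Cohort ==")
  add("N = %d (low %d / middle %d / high %d by trauma-score quartiles)",
      nrow(rec), sum(rec$group_label == "low"),
      sum(rec$group_label == "middle"), sum(rec$group_label == "high"))
  for (v in c("ctq_total", result$config$covariate_cols)) {
    mu <- tapply(rec[[v]], rec$group_label, mean)
    sd_ <- tapply(rec[[v]], rec$group_label, stats::sd)
    add("  %-12s %s", v, paste(sprintf("%.2f (%.2f)", mu, sd_),
                               collapse = "  "))
  }
  add("")
  add("== Global network indices (group mean (SD), ANCOVA) ==")
  tab <- result$stats$table
  g <- result$global
  m <- match(g$subject, rec$subject_id)
  for (i in seq_len(nrow(tab))) {
    sel <- g$band == tab$band[i]
    vals <- g[[tab$index[i]]][sel]
    grp <- rec$group_label[m[sel]]
    mu <- tapply(vals, grp, mean); sd_ <- tapply(vals, grp, stats::sd)
    add("%-9s %-12s %s  F=%.2f p=%.4g eta2p=%.3f%s", tab$band[i],
        tab$index[i],
        paste(sprintf("%.3f (%.3f)", mu, sd_), collapse = "  "),
        tab$F[i], tab$p[i], tab$partial_eta_sq[i],
        if (tab$significant[i]) " *" else "")
    if (tab$significant[i] && "p_low_high" %in% names(tab))
      add("          pairwise p: low-middle %.4g, low-high %.4g, middle-high %.4g",
          tab$p_low_middle[i], tab$p_low_high[i], tab$p_middle_high[i])
  }
  if (!is.null(result$nodal_stats)) {
    add("")
    add("== Nodal clustering: significant nodes (threshold %.6g) ==",
        attr(result$nodal_stats, "threshold"))
    sig <- result$nodal_stats[result$nodal_stats$significant, , drop = FALSE]
    if (nrow(sig) == 0L) add("  none")
    for (i in seq_len(nrow(sig)))
      add("  %-9s node %3d  F=%.2f p=%.4g eta2p=%.3f", sig$band[i],
          sig$node[i], sig$F[i], sig$p[i], sig$partial_eta_sq[i])
  } else {
    add("")
    add("(nodal stage not run)")
  }
  if (!is.null(result$correlations)) {
    sig <- result$correlations[result$correlations$significant, , drop = FALSE]
    add("")
    add("== Partial correlations with trauma measures (threshold %.6g) ==",
        attr(result$correlations, "threshold"))
    if (nrow(sig) == 0L) add("  none significant")
    for (i in seq_len(nrow(sig)))
      add("  %-9s node %3d  %-22s r=%.3f p=%.4g", sig$band[i], sig$node[i],
          sig$measure[i], sig$r_partial[i], sig$p[i])
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
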