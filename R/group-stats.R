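#' Assign low/middle/high groups by trauma-score quartiles
#'
#' Cuts at the 25% and 75% quantiles computed with the inclusive
#' linear-interpolation convention (R quantile type 7). Values `<= Q1` go to
#' the low group and values `>= Q3` to the high group, so boundary ties fall
#' to the outer groups.
#'
#' @param ctq_totals numeric vector of trauma questionnaire totals.
#' @return Factor with levels `low`, `middle`, `high`.
#' @export
assign_groups <- function(ctq_totals) {
  if (length(ctq_totals) < 8L)
    stop("need at least 8 subjects for a quartile split", call. = FALSE)
  q <- stats::quantile(ctq_totals, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1L] == q[2L])
    stop("quartiles are degenerate (constant scores?)", call. = FALSE)
  factor(ifelse(ctq_totals <= q[1L], "low",
                ifelse(ctq_totals >= q[2L], "high", "middle")),
         levels = c("low", "middle", "high"))
}

# design matrix for covariate-adjusted models; covariates may be NULL,
# a vector, matrix, or data frame
.cov_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  z <- as.matrix(as.data.frame(covariates))
  if (nrow(z) != n) stop("covariate length mismatch", call. = FALSE)
  storage.mode(z) <- "double"
  z
}

#' Covariate-adjusted group comparison (ANCOVA) of a network index
#'
#' Fits the general linear model `value ~ covariates + group` and tests the
#' group factor adjusted for the covariates (sequential sums of squares with
#' group entered last). Effect size is partial eta squared,
#' `SS_group / (SS_group + SS_error)`. With `multivariate = TRUE`, `values`
#' may be a matrix of indices and a Wilks-lambda MANOVA test of the group
#' effect is returned alongside.
#'
#' @param values numeric vector (or matrix when `multivariate = TRUE`) of
#'   per-subject index values.
#' @param groups factor of group labels.
#' @param covariates optional vector/matrix/data frame of covariates.
#' @param multivariate if `TRUE`, also run the Wilks multivariate test
#'   across the columns of `values`.
#'
#' @return An object of class `network_ancova`: `F`, `df_effect`,
#'   `df_error`, `p`, `partial_eta_sq`, `group_means` (covariate-adjusted),
#'   and optionally `wilks` (data frame).
#' @export
ancova_group_test <- function(values, groups, covariates = NULL,
                              multivariate = FALSE) {
  groups <- droplevels(as.factor(groups))
  vmat <- as.matrix(values)
  n <- nrow(vmat)
  if (length(groups) != n) stop("groups length mismatch", call. = FALSE)
  z <- .cov_matrix(covariates, n)
  k_cov <- if (is.null(z)) 0L else ncol(z)
  if (any(table(groups) < 2L) || n < nlevels(groups) * 2L + k_cov)
    stop("need at least 2 subjects per group beyond the covariates",
         call. = FALSE)
  y <- vmat[, 1L]
  dat <- data.frame(.y = y, .g = groups)
  if (!is.null(z)) {
    colnames(z) <- paste0(".z", seq_len(ncol(z)))
    dat <- cbind(dat, z)
    form <- stats::as.formula(paste(".y ~", paste(colnames(z), collapse = " + "),
                                    "+ .g"))
  } else {
    form <- .y ~ .g
  }
  fit <- stats::lm(form, data = dat)
  if (fit$rank < length(stats::coef(fit)))
    stop("rank-deficient design (collinear covariates?)", call. = FALSE)
  a <- stats::anova(fit)
  i_g <- which(rownames(a) == ".g")
  ss_g <- a$`Sum Sq`[i_g]
  ss_e <- a$`Sum Sq`[nrow(a)]
  res <- list(
    F = a$`F value`[i_g],
    df_effect = a$Df[i_g],
    df_error = a$Df[nrow(a)],
    p = a$`Pr(>F)`[i_g],
    partial_eta_sq = ss_g / (ss_g + ss_e),
    group_means = .adjusted_means(y, groups, z),
    n = n, fit = fit
  )
  if (multivariate && ncol(vmat) > 1L) {
    mdat <- dat
    mfit <- if (is.null(z)) {
      stats::manova(vmat ~ groups)
    } else {
      stats::manova(stats::as.formula(
        paste("vmat ~", paste(colnames(z), collapse = " + "), "+ .g")),
        data = mdat)
    }
    ms <- summary(mfit, test = "Wilks")$stats
    i_m <- which(rownames(ms) == if (is.null(z)) "groups" else ".g")
    res$wilks <- data.frame(wilks = ms[i_m, "Wilks"],
                            F = ms[i_m, "approx F"],
                            p = ms[i_m, "Pr(>F)"])
  }
  structure(res, class = "network_ancova")
}

# covariate-adjusted group means: predictions at the covariate grand mean
.adjusted_means <- function(y, groups, z) {
  if (is.null(z)) return(tapply(y, groups, mean))
  x <- stats::model.matrix(~ groups)
  xz <- cbind(x, sweep(z, 2L, colMeans(z)))
  beta <- stats::lm.fit(xz, y)$coefficients
  beta[is.na(beta)] <- 0
  lev <- levels(groups)
  out <- stats::setNames(numeric(length(lev)), lev)
  out[1L] <- beta[1L]
  if (length(lev) > 1L)
    out[-1L] <- beta[1L] + beta[2L:length(lev)]
  out
}

#' @export
print.network_ancova <- function(x, ...) {
  cat(sprintf(
    "Covariate-adjusted group test: F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
    x$df_effect, x$df_error, x$F, x$p, x$partial_eta_sq))
  cat("Adjusted group means:\n")
  print(round(x$group_means, 4))
  if (!is.null(x$wilks))
    cat(sprintf("Wilks lambda = %.4f, F = %.3f, p = %.4g\n",
                x$wilks$wilks, x$wilks$F, x$wilks$p))
  invisible(x)
}

#' @export
summary.network_ancova <- function(object, ...) {
  print(object)
  cat("\nUnderlying linear model:\n")
  print(summary(object$fit))
  invisible(object)
}

#' @export
coef.network_ancova <- function(object, ...) stats::coef(object$fit)

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests in the family (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  alpha / m
}

#' Covariate-adjusted post-hoc pairwise comparisons
#'
#' Tests the covariate-adjusted mean contrast for every group pair using
#' the error term of the full model (all groups + covariates), as
#' conventional post-hoc machinery does, and Bonferroni-multiplies each p
#' value by the number of pairs (capped at 1).
#'
#' @inheritParams ancova_group_test
#'
#' @return Data frame with one row per pair: `pair`, `diff` (second minus
#'   first adjusted mean), `t`, `p_raw`, `p_adj`.
#' @export
posthoc_pairwise <- function(values, groups, covariates = NULL) {
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 subjects for pairwise tests",
         call. = FALSE)
  z <- .cov_matrix(covariates, length(values))
  x <- stats::model.matrix(~ groups)
  if (!is.null(z)) x <- cbind(x, z)
  fit <- stats::lm.fit(x, values)
  rss <- sum(fit$residuals^2)
  df <- length(values) - fit$rank
  xtx_inv <- chol2inv(chol(crossprod(x)))
  beta <- fit$coefficients
  pairs <- utils::combn(seq_along(lev), 2L)
  n_pairs <- ncol(pairs)
  out <- vector("list", n_pairs)
  for (j in seq_len(n_pairs)) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    # contrast of adjusted means: treatment coding, group columns 2..k
    cvec <- numeric(ncol(x))
    if (i1 > 1L) cvec[i1] <- -1
    if (i2 > 1L) cvec[i2] <- 1
    est <- sum(cvec * beta)
    se <- sqrt(rss / df * drop(t(cvec) %*% xtx_inv %*% cvec))
    tval <- est / se
    p_raw <- 2 * stats::pt(-abs(tval), df)
    out[[j]] <- data.frame(
      pair = paste(lev[i1], lev[i2], sep = "-"),
      diff = est, t = tval, p_raw = p_raw,
      p_adj = min(1, n_pairs * p_raw))
  }
  do.call(rbind, out)
}

#' Partial Pearson correlation
#'
#' Correlates the residuals of `x` and `y` after linear removal of the
#' covariates; the p value uses a t reference with `n - k - 2` degrees of
#' freedom. With no covariates this is the ordinary Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional vector/matrix/data frame of covariates.
#'
#' @return One-row data frame: `r_partial`, `t`, `df`, `p`, `n`,
#'   `n_covariates`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y length mismatch", call. = FALSE)
  z <- .cov_matrix(covariates, n)
  k <- if (is.null(z)) 0L else ncol(z)
  if (n <= k + 2L) stop("need n > n_covariates + 2", call. = FALSE)
  if (is.null(z)) {
    rx <- x - mean(x); ry <- y - mean(y)
  } else {
    xz <- cbind(1, z)
    rx <- stats::lm.fit(xz, x)$residuals
    ry <- stats::lm.fit(xz, y)$residuals
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; correlation undefined", call. = FALSE)
  # a variable fully explained by the covariates leaves only numerical
  # noise in its residuals: the partial correlation is 0 by convention
  tol_x <- 1e-10 * stats::sd(x)
  tol_y <- 1e-10 * stats::sd(y)
  r <- if (stats::sd(rx) < tol_x || stats::sd(ry) < tol_y) {
    0
  } else {
    sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  }
  df <- n - k - 2L
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  data.frame(r_partial = r, t = tval, df = df,
             p = 2 * stats::pt(-abs(tval), df), n = n, n_covariates = k)
}

#' Power of a one-way fixed-effects ANOVA
#'
#' Uses the noncentral F distribution with noncentrality
#' `lambda = f^2 * n_total` and degrees of freedom `(k - 1, n_total - k)`,
#' where `f` is Cohen's effect size.
#'
#' @param effect_size_f Cohen's f (>= 0).
#' @param n_total total sample size.
#' @param k_groups number of groups.
#' @param alpha significance level.
#' @return Power in `[0, 1]`.
#' @export
anova_power <- function(effect_size_f, n_total, k_groups, alpha = 0.05) {
  if (effect_size_f < 0) stop("effect size must be non-negative", call. = FALSE)
  df1 <- k_groups - 1L
  df2 <- n_total - k_groups
  if (df1 < 1L || df2 < 1L) stop("invalid degrees of freedom", call. = FALSE)
  crit <- stats::qf(1 - alpha, df1, df2)
  1 - stats::pf(crit, df1, df2, ncp = effect_size_f^2 * n_total)
}

#' Group comparison of all global indices across bands
#'
#' Runs the covariate-adjusted group test for every index x band cell,
#' flags cells significant at the Bonferroni threshold `alpha / m` (default
#' family: 4 indices x 4 bands = 16 tests), and adds post-hoc pairwise
#' comparisons for the significant cells.
#'
#' @param global long-format data frame from [cohort_metrics()] (`subject`,
#'   `band`, `strength`, `clustering`, `path_length`, `efficiency`).
#' @param records cohort data frame carrying grouping and covariates, with
#'   a `subject_id` column.
#' @param group_col column of `records` holding the group factor.
#' @param covariate_cols covariate columns of `records`.
#' @param alpha family-wise error rate.
#' @param family_size number of tests the Bonferroni family counts
#'   (default: indices x bands actually present).
#'
#' @return Object of class `network_group_stats`: data frame `table` with
#'   F, p, partial eta squared, significance flag and pairwise p values,
#'   plus the threshold used.
#' @export
network_group_analysis <- function(global, records,
                                   group_col = "group_label",
                                   covariate_cols = c("sai", "tai", "bdi",
                                                      "caars_total"),
                                   alpha = 0.05, family_size = NULL) {
  idx_cols <- intersect(c("strength", "clustering", "path_length",
                          "efficiency"), names(global))
  bands <- unique(global$band)
  if (is.null(family_size)) family_size <- length(idx_cols) * length(bands)
  thr <- bonferroni_threshold(alpha, family_size)
  m <- match(global$subject, records$subject_id)
  if (anyNA(m)) stop("metric subjects missing from records", call. = FALSE)
  rows <- list()
  for (b in bands) {
    sel <- global$band == b
    rec <- records[m[sel], , drop = FALSE]
    grp <- rec[[group_col]]
    cov <- rec[, covariate_cols, drop = FALSE]
    for (ix in idx_cols) {
      vals <- global[[ix]][sel]
      at <- ancova_group_test(vals, grp, cov)
      row <- data.frame(band = b, index = ix, F = at$F,
                        df_effect = at$df_effect, df_error = at$df_error,
                        p = at$p, partial_eta_sq = at$partial_eta_sq,
                        significant = at$p < thr)
      means <- at$group_means
      row$mean_low <- means["low"]; row$mean_middle <- means["middle"]
      row$mean_high <- means["high"]
      ph <- posthoc_pairwise(vals, grp, cov)
      for (j in seq_len(nrow(ph))) {
        row[[paste0("p_", gsub("-", "_", ph$pair[j]))]] <- ph$p_adj[j]
        row[[paste0("diff_", gsub("-", "_", ph$pair[j]))]] <- ph$diff[j]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  structure(list(table = do.call(rbind, rows), alpha = alpha,
                 family_size = family_size, threshold = thr,
                 covariates = covariate_cols),
            class = "network_group_stats")
}

#' @export
print.network_group_stats <- function(x, ...) {
  cat(sprintf(
    "Covariate-adjusted group comparison of %d index x band cells\n",
    nrow(x$table)))
  cat(sprintf("Bonferroni threshold: %.6g (alpha %.3g / %d tests)\n",
              x$threshold, x$alpha, x$family_size))
  tab <- x$table
  show <- tab[, c("band", "index", "F", "p", "partial_eta_sq", "significant")]
  show$F <- round(show$F, 3)
  show$partial_eta_sq <- round(show$partial_eta_sq, 3)
  show$p <- signif(show$p, 3)
  print(show, row.names = FALSE)
  invisible(x)
}
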