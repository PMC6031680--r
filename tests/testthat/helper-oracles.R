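# Independent oracles used across the suite. Each reimplements a quantity
# from first principles (enumeration, closed form, or brute-force
# simulation), deliberately avoiding the package's own code paths.

# all-pairs shortest path lengths by Floyd-Warshall on edge lengths 1/w
fw_distances <- function(w, length_map = c("inverse", "neglog")) {
  length_map <- match.arg(length_map)
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && w[i, j] > 0)
      d[i, j] <- if (length_map == "inverse") 1 / w[i, j] else -log(w[i, j])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

fw_path_length <- function(w) {
  d <- fw_distances(w)
  mean(d[row(d) != col(d)])
}

fw_efficiency <- function(w) {
  d <- fw_distances(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  mean(inv[row(d) != col(d)])
}

# Onnela weighted clustering by explicit triple enumeration
oracle_clustering <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k_i <- sum(w[i, ] > 0)
    if (k_i < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h)
        acc <- acc + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    }
    out[i] <- acc / (k_i * (k_i - 1))
  }
  out
}

# inclusive linear-interpolation percentile (quantile type 7) from scratch
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# partial correlation through the precision matrix of (x, y, covariates)
oracle_partial_r <- function(x, y, z) {
  s <- stats::cov(cbind(x, y, z))
  p <- solve(s)
  -p[1, 2] / sqrt(p[1, 1] * p[2, 2])
}

# ANCOVA F and partial eta^2 from raw normal equations: compare the
# residual sum of squares of the covariate-only model with the full model
oracle_ancova <- function(values, groups, covariates) {
  groups <- droplevels(as.factor(groups))
  z <- as.matrix(covariates)
  dummies <- stats::model.matrix(~ groups)[, -1, drop = FALSE]
  rss <- function(x) {
    beta <- solve(crossprod(x), crossprod(x, values))
    sum((values - x %*% beta)^2)
  }
  sse_full <- rss(cbind(1, z, dummies))
  sse_red <- rss(cbind(1, z))
  df_g <- ncol(dummies)
  df_e <- length(values) - 1 - ncol(z) - ncol(dummies)
  ss_g <- sse_red - sse_full
  list(F = (ss_g / df_g) / (sse_full / df_e),
       partial_eta_sq = ss_g / (ss_g + sse_full),
       df_effect = df_g, df_error = df_e,
       p = stats::pf((ss_g / df_g) / (sse_full / df_e), df_g, df_e,
                     lower.tail = FALSE))
}

# noncentral-F tail probability via the Poisson-weighted incomplete-beta
# series (independent of stats::pf's noncentral code path)
oracle_ncf_power <- function(f, n_total, k, alpha, terms = 2000) {
  df1 <- k - 1
  df2 <- n_total - k
  crit <- stats::qf(1 - alpha, df1, df2)
  lambda <- f^2 * n_total
  x <- df1 * crit / (df1 * crit + df2)
  j <- 0:terms
  cdf <- sum(exp(-lambda / 2 + j * log(lambda / 2) - lfactorial(j)) *
               stats::pbeta(x, df1 / 2 + j, df2 / 2))
  1 - cdf
}

# Monte-Carlo SD of the empirical resultant length of n_trials wrapped-normal
# phase differences with jitter SDs (si, sj)
mc_plv_se <- function(si, sj, n_trials, reps = 500, seed = 999) {
  set.seed(seed)
  r <- replicate(reps, {
    d <- stats::rnorm(n_trials, 0, si) - stats::rnorm(n_trials, 0, sj)
    Mod(mean(exp(1i * d)))
  })
  stats::sd(r)
}

# independent reimplementation of seed-dropping farthest-point sampling
oracle_fps <- function(xy, n_nodes) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n_nodes == n) return(seq_len(n))
  d2 <- as.matrix(stats::dist(xy))^2
  centroid_d <- rowSums(sweep(xy, 2, colMeans(xy))^2)
  anchor <- which.min(centroid_d)
  sel <- integer(0)
  mind <- d2[, anchor]
  for (k in seq_len(n_nodes)) {
    pick <- unname(which.max(mind))
    sel <- c(sel, pick)
    mind <- pmin(mind, d2[, pick])
  }
  sel
}

# small complete weighted graph with weights bounded away from 0
random_plv_graph <- function(n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2, 0.05, 1)
  w <- w + t(w)
  w
}

n_epochs <- function(x) dim(x$data)[1L]

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1L], d))
}

# bare epoch-set builder for tests that need full control over the tensor
new_epoch_set_for_test <- function(data, fs = 1000, condition = NULL,
                                   correct = NULL) {
  n <- dim(data)[1L]
  if (is.null(condition)) condition <- rep("NoGo", n)
  if (is.null(correct)) correct <- rep(TRUE, n)
  plvnet:::new_epoch_set(data, seq_len(dim(data)[3L]) - 1, fs,
                         condition, correct)
}

# fast desk-scale pipeline configuration used by simulation studies
desk_pipeline_config <- function(seed, sigma = NULL, ...) {
  sim_args <- list(
    n_subjects_per_group = c(15L, 25L, 15L), n_nodes = 20L, n_trials = 48L,
    sample_rate = 125, nogo_only = TRUE, seed = seed)
  if (!is.null(sigma)) sim_args$phase_jitter_sigma <- sigma
  pipeline_config(sim = do.call(sim_config, sim_args), ...)
}
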