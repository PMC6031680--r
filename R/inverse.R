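#' Gain (lead-field) matrix container
#'
#' @param matrix numeric sensors x sources matrix.
#' @param source_coordinates sources x 3 matrix of source positions.
#'
#' @return An object of class `gain_matrix`.
#' @export
gain_matrix <- function(matrix, source_coordinates) {
  matrix <- as.matrix(matrix)
  source_coordinates <- as.matrix(source_coordinates)
  if (!all(is.finite(matrix))) stop("gain must be finite", call. = FALSE)
  if (nrow(source_coordinates) != ncol(matrix))
    stop("one coordinate row per source is required", call. = FALSE)
  structure(list(matrix = matrix, source_coordinates = source_coordinates),
            class = "gain_matrix")
}

#' @export
print.gain_matrix <- function(x, ...) {
  cat(sprintf("<gain_matrix> %d sensors x %d sources\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Synthetic spherical-head forward model
#'
#' Places current dipoles with random fixed orientations on an inner sphere
#' and sensors on an outer sphere (both quasi-uniform Fibonacci lattices);
#' the gain entry is the dipole potential kernel
#' `dot(orientation, r_sensor - r_source) / |r_sensor - r_source|^3`.
#' A smooth, seedable stand-in for a boundary-element head model so the
#' inverse chain can be exercised and round-trip tested; it is synthetic and
#' carries no anatomical meaning.
#'
#' @param n_sensors,n_sources counts of sensors and sources.
#' @param source_radius,sensor_radius sphere radii (arbitrary units).
#' @param seed seed for the dipole orientations.
#'
#' @return A [gain_matrix()] whose gain columns have unit norm.
#' @export
synthetic_gain <- function(n_sensors = 32L, n_sources = 200L,
                           source_radius = 0.8, sensor_radius = 1,
                           seed = 1L) {
  stopifnot(n_sensors >= 1L, n_sources >= 1L)
  fib <- function(n, r) {
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    theta <- pi * (1 + sqrt(5)) * i
    r * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  }
  src <- fib(n_sources, source_radius)
  sens <- fib(n_sensors, sensor_radius)
  set.seed(seed)
  ori <- matrix(stats::rnorm(3L * n_sources), n_sources)
  ori <- ori / sqrt(rowSums(ori^2))
  g <- matrix(0, n_sensors, n_sources)
  for (j in seq_len(n_sources)) {
    d <- sweep(sens, 2L, src[j, ])
    g[, j] <- (d %*% ori[j, ]) / (rowSums(d^2))^1.5
  }
  g <- sweep(g, 2L, sqrt(colSums(g^2)), "/")
  gain_matrix(g, src)
}

#' Regularized minimum-norm inverse operator
#'
#' Builds `W = G' (G G' + lambda^2 I)^{-1}`, the L2 minimum-norm estimator
#' of source amplitudes from sensor data. With `lambda = 0` and a
#' full-row-rank gain this is the Moore-Penrose pseudo-inverse.
#'
#' @param gain a [gain_matrix()] or bare sensors x sources matrix.
#' @param lambda regularization parameter (>= 0). The default follows the
#'   common SNR heuristic `lambda^2 = trace(G G') / (n_sensors * snr^2)`.
#' @param snr assumed amplitude signal-to-noise ratio for the default
#'   `lambda` (default 3).
#'
#' @return An object of class `inverse_operator` with elements `matrix`
#'   (sources x sensors) and `lambda`.
#' @export
minimum_norm_inverse <- function(gain, lambda = NULL, snr = 3) {
  g <- if (inherits(gain, "gain_matrix")) gain$matrix else as.matrix(gain)
  gram <- tcrossprod(g)
  if (is.null(lambda))
    lambda <- sqrt(sum(diag(gram)) / (nrow(g) * snr^2))
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  sys <- gram + lambda^2 * diag(nrow(g))
  w <- tryCatch(t(solve(sys, g)),
                error = function(e)
                  stop("sensor covariance is singular; use lambda > 0 with a ",
                       "rank-deficient gain", call. = FALSE))
  structure(list(matrix = w, lambda = lambda), class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %d sources x %d sensors, lambda = %.4g\n",
              nrow(x$matrix), ncol(x$matrix), x$lambda))
  invisible(x)
}

#' Apply an inverse operator to sensor epochs
#'
#' @param epochs a sensor-space `epoch_set`.
#' @param inv an [minimum_norm_inverse()] operator.
#'
#' @return A source-space `epoch_set` (one "channel" per source), trial
#'   count and labels preserved.
#' @export
apply_inverse <- function(epochs, inv) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(inv, "inverse_operator"))
  d <- dim(epochs$data)
  w <- inv$matrix
  if (ncol(w) != d[2L])
    stop(sprintf("operator expects %d sensors but epochs have %d channels",
                 ncol(w), d[2L]), call. = FALSE)
  sens <- aperm(epochs$data, c(2L, 1L, 3L))
  dim(sens) <- c(d[2L], d[1L] * d[3L])
  src <- w %*% sens
  dim(src) <- c(nrow(w), d[1L], d[3L])
  new_epoch_set(aperm(src, c(2L, 1L, 3L)), epochs$times_ms,
                epochs$sample_rate, epochs$condition, epochs$correct,
                paste0("source", seq_len(nrow(w))))
}

#' Evenly spread node subset by farthest-point sampling
#'
#' Greedy farthest-point sampling: starting from an anchor (the source
#' nearest the centroid), repeatedly add the source maximizing its minimum
#' distance to the already selected set, breaking ties by lowest index. The
#' anchor only seeds the first selection and is not itself returned, so the
#' selected set is maximally spread (on collinear points with `n_nodes = 2`
#' this yields the two endpoints). Deterministic given the coordinates.
#'
#' @param source_coordinates sources x d coordinate matrix (or a
#'   [gain_matrix()]).
#' @param n_nodes number of nodes to select (default 314).
#'
#' @return Integer vector of selected source indices, in selection order.
#' @export
downsample_nodes <- function(source_coordinates, n_nodes = 314L) {
  if (inherits(source_coordinates, "gain_matrix"))
    source_coordinates <- source_coordinates$source_coordinates
  xy <- as.matrix(source_coordinates)
  n <- nrow(xy)
  if (n_nodes < 1L) stop("n_nodes must be at least 1", call. = FALSE)
  if (n_nodes > n) stop("n_nodes exceeds the number of sources", call. = FALSE)
  if (n_nodes == n) return(seq_len(n))
  centroid <- colMeans(xy)
  d2c <- rowSums(sweep(xy, 2L, centroid)^2)
  anchor <- which.min(d2c)  # which.min takes the lowest index on ties
  mind <- rowSums(sweep(xy, 2L, xy[anchor, ])^2)
  sel <- integer(n_nodes)
  for (k in seq_len(n_nodes)) {
    cand <- which.max(mind)
    sel[k] <- cand
    mind <- pmin(mind, rowSums(sweep(xy, 2L, xy[cand, ])^2))
  }
  sel
}
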