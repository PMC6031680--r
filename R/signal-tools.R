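# Frequency-domain zero-phase filtering and analytic-signal helpers.
#
# Zero-phase band-pass = squared magnitude response of an order-`order`
# Butterworth applied with zero phase (same transfer magnitude as
# forward-backward filtering). Signals are odd-reflection padded before the
# FFT so boundary transients stay out of the analysis window; FFT lengths
# are rounded up to 5-smooth sizes for speed.

# Squared (two-pass) Butterworth magnitude response at physical frequencies f.
# f_lo <= 0 degenerates to a low-pass.
.butter2_gain <- function(f, f_lo, f_hi, order) {
  if (f_lo <= 0) {
    r <- (f / f_hi)^(2L * order)
  } else {
    f0sq <- f_lo * f_hi
    bw <- f_hi - f_lo
    r <- ifelse(f == 0, Inf, ((f^2 - f0sq) / (f * bw))^2)^order
  }
  (1 / (1 + r))^2
}

# analytic-signal (one-sided spectrum) multiplier of length m
.hilbert_mask <- function(m) {
  h <- numeric(m)
  h[1L] <- 1
  if (m %% 2L == 0L) {
    h[m / 2L + 1L] <- 1
    h[2L:(m / 2L)] <- 2
  } else {
    h[2L:((m + 1L) / 2L)] <- 2
  }
  h
}

# smallest 5-smooth integer >= n (fast FFT length)
.next_fast_len <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

# Odd-reflection padding of a samples x channels matrix, with `extra`
# trailing zeros to reach a fast FFT length.
.reflect_pad <- function(x, pad, extra = 0L) {
  n <- nrow(x)
  if (pad < 1L && extra < 1L) return(x)
  pieces <- list()
  if (pad >= 1L)
    pieces$head <- 2 * x[rep(1L, pad), , drop = FALSE] -
      x[(pad + 1L):2L, , drop = FALSE]
  pieces$body <- x
  if (pad >= 1L)
    pieces$tail <- 2 * x[rep(n, pad), , drop = FALSE] -
      x[(n - 1L):(n - pad), , drop = FALSE]
  if (extra >= 1L)
    pieces$zeros <- matrix(0, extra, ncol(x))
  do.call(rbind, pieces)
}

.pad_length <- function(n, fs, f_lo) {
  f_eff <- max(f_lo, 0.5)
  min(n - 1L, as.integer(ceiling(fs / f_eff)))
}

# Multi-band engine: one forward FFT of the padded samples x channels
# matrix, then per band a gain (optionally one-sided analytic) multiply and
# inverse FFT, all in the compiled kernel. `bands` is a list of
# c(f_lo, f_hi) pairs.
.filter_bands <- function(x, fs, bands, order = 4L, analytic = FALSE) {
  stopifnot(is.matrix(x), fs > 0)
  for (b in bands)
    if (b[1L] < 0 || b[1L] >= b[2L] || b[2L] >= fs / 2)
      stop("invalid band edges: need 0 <= f_lo < f_hi < sample_rate/2",
           call. = FALSE)
  n <- nrow(x)
  pad <- max(vapply(bands, function(b) .pad_length(n, fs, b[1L]), integer(1)))
  m0 <- n + 2L * pad
  m <- .next_fast_len(m0)
  xp <- .reflect_pad(x, pad, extra = m - m0)
  edges <- do.call(rbind, bands)
  out <- .cpp_filter_bands(xp, fs, edges, as.integer(order), analytic)
  sel <- (pad + 1L):(pad + n)
  lapply(out, function(y) y[sel, , drop = FALSE])
}

# padded frame info for callers that window the padded output themselves
.band_pad_info <- function(n, fs, bands) {
  pad <- max(vapply(bands, function(b) .pad_length(n, fs, b[1L]), integer(1)))
  m0 <- n + 2L * pad
  list(pad = pad, m = .next_fast_len(m0))
}

# single-band convenience wrapper
.zero_phase_bandpass <- function(x, fs, f_lo, f_hi, order = 4L,
                                 analytic = FALSE) {
  .filter_bands(x, fs, list(c(f_lo, f_hi)), order, analytic)[[1L]]
}

# trials x channels x samples array -> samples x (trials*channels) matrix
.epochs_to_mat <- function(arr) {
  d <- dim(arr)
  m <- aperm(arr, c(3L, 1L, 2L))
  dim(m) <- c(d[3L], d[1L] * d[2L])
  m
}

# inverse of .epochs_to_mat
.mat_to_epochs <- function(mat, n_trials, n_channels) {
  arr <- mat
  dim(arr) <- c(nrow(mat), n_trials, n_channels)
  aperm(arr, c(2L, 3L, 1L))
}
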