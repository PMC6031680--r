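#' Default frequency-band definitions
#'
#' The four analysis bands: alpha 8-12 Hz, low beta 12-18 Hz, high beta
#' 18-30 Hz, gamma 30-55 Hz. Delta and theta are excluded by default
#' because the 500 ms analysis window holds only one or two full cycles of
#' those rhythms, which biases phase-locking estimates.
#'
#' @return Data frame with columns `name`, `f_lo`, `f_hi`.
#' @export
band_definitions <- function() {
  data.frame(name = c("alpha", "low_beta", "high_beta", "gamma"),
             f_lo = c(8, 12, 18, 30),
             f_hi = c(12, 18, 30, 55))
}

#' Instantaneous phase of band-limited epochs
#'
#' Band-pass filters whole epochs with the zero-phase filter of
#' [bandpass_filter()], takes the analytic-signal (Hilbert) phase, and crops
#' to the analysis window (default 200-700 ms, the late inhibitory
#' component). Filtering precedes cropping so filter transients stay outside
#' the window.
#'
#' @param epochs an `epoch_set` of node signals.
#' @param band list/row with `f_lo`, `f_hi` in Hz, or `NULL` if `epochs`
#'   are already band-limited.
#' @param window_ms analysis window (ms relative to stimulus).
#' @param order filter order, see [bandpass_filter()].
#'
#' @return A list of class `phase_epochs`: `phases` (trials x nodes x
#'   window samples, radians in `(-pi, pi]`), `times_ms`, `band`.
#' @export
instantaneous_phase <- function(epochs, band = NULL,
                                window_ms = c(200, 700), order = 4L) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1L] < 1L) stop("no epochs to compute phases from", call. = FALSE)
  bands <- if (is.null(band)) {
    data.frame(name = NA_character_, f_lo = 0.5,
               f_hi = epochs$sample_rate / 2 * 0.999)
  } else {
    as.data.frame(band)
  }
  .phases_multiband(epochs, bands, window_ms, order)[[1L]]
}

# shared engine: one forward FFT, one phase tensor per band
.phases_multiband <- function(epochs, bands, window_ms = c(200, 700),
                              order = 4L) {
  d <- dim(epochs$data)
  mat <- .epochs_to_mat(epochs$data)
  if (any(colSums(abs(mat)) == 0))
    stop("phase is undefined for an identically zero signal", call. = FALSE)
  keep <- which(epochs$times_ms >= window_ms[1L] &
                  epochs$times_ms < window_ms[2L])
  if (!length(keep))
    stop("analysis window contains no samples", call. = FALSE)
  band_list <- lapply(seq_len(nrow(bands)),
                      function(b) c(bands$f_lo[b], bands$f_hi[b]))
  ana <- .filter_bands(mat, epochs$sample_rate, band_list, order,
                       analytic = TRUE)
  out <- lapply(seq_along(ana), function(b) {
    ph <- Arg(ana[[b]][keep, , drop = FALSE])
    structure(list(phases = .mat_to_epochs(ph, d[1L], d[2L]),
                   times_ms = epochs$times_ms[keep],
                   band = bands$name[b]),
              class = "phase_epochs")
  })
  names(out) <- bands$name
  out
}

#' Phase-locking value adjacency matrix
#'
#' Across-trials convention: at each window sample t the PLV of a node pair
#' is the modulus of the trial-mean unit phasor of their phase difference,
#' `| (1/N) sum_k exp(i (phi_i - phi_j)) |`; these are then averaged over
#' the window. Values lie in `[0, 1]`; the diagonal is forced to 0 for
#' network use. A within-trial (over-time) mode is available via
#' `convention = "within_trial"`.
#'
#' @param phases a [instantaneous_phase()] result.
#' @param convention `"across_trials"` (default) or `"within_trial"`.
#'
#' @return Symmetric nodes x nodes matrix of class `plv_matrix` with
#'   attributes `band` and `n_trials`.
#' @export
plv_matrix <- function(phases, convention = c("across_trials",
                                              "within_trial")) {
  stopifnot(inherits(phases, "phase_epochs"))
  convention <- match.arg(convention)
  ph <- phases$phases
  d <- dim(ph)
  n_trials <- d[1L]; n_nodes <- d[2L]; n_t <- d[3L]
  if (convention == "across_trials" && n_trials < 2L)
    stop("across-trials PLV needs >= 2 trials (with a single trial it is ",
         "identically 1); use convention = 'within_trial' for single trials",
         call. = FALSE)
  if (convention == "across_trials") {
    w <- .plv_from_phase_list(list(ph))[[1L]]
  } else {
    acc <- matrix(0, n_nodes, n_nodes)
    z <- exp(1i * ph)
    for (k in seq_len(n_trials)) {
      zk <- matrix(z[k, , ], n_nodes, n_t)
      acc <- acc + Mod(tcrossprod(zk, Conj(zk)))
    }
    w <- acc / (n_trials * n_t)
  }
  w <- (w + t(w)) / 2
  w <- pmin(pmax(w, 0), 1)
  diag(w) <- 0
  structure(w, class = c("plv_matrix", "matrix"),
            band = phases$band, n_trials = n_trials)
}

#' @export
print.plv_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("<plv_matrix> %d nodes, band %s, %d trials, mean PLV %.3f\n",
              nrow(x), attr(x, "band"), attr(x, "n_trials"), mean(off)))
  invisible(x)
}

# Across-trials PLV from unit-phasor components (trials*nodes x time
# matrices of cos(phi) and sin(phi)), via real BLAS crossproducts per time
# sample: Re = C'C + S'S, Im = S'C - (S'C)'.
.plv_from_phasors <- function(ca, sa, n_trials, n_nodes) {
  n_t <- ncol(ca)
  acc <- matrix(0, n_nodes, n_nodes)
  for (t in seq_len(n_t)) {
    ct <- ca[, t]; dim(ct) <- c(n_trials, n_nodes)
    st <- sa[, t]; dim(st) <- c(n_trials, n_nodes)
    re <- crossprod(ct) + crossprod(st)
    sc <- crossprod(st, ct)
    im <- sc - t(sc)
    acc <- acc + sqrt(re * re + im * im)
  }
  acc / (n_t * n_trials)
}

# phase tensor (trials x nodes x time) -> PLV matrix
.plv_from_phase_list <- function(ph_list) {
  lapply(ph_list, function(ph) {
    d <- dim(ph)
    ca <- cos(ph); sa <- sin(ph)
    dim(ca) <- c(d[1L] * d[2L], d[3L])
    dim(sa) <- c(d[1L] * d[2L], d[3L])
    .plv_from_phasors(ca, sa, d[1L], d[2L])
  })
}

#' Per-subject, per-band PLV matrices for a cohort
#'
#' Selects the requested condition (correct trials only), then computes one
#' PLV matrix per subject and band. Subjects with fewer than 2 usable
#' epochs are dropped with a warning.
#'
#' @param epochs_list named list of `epoch_set`, one per subject.
#' @param bands band table as from [band_definitions()].
#' @param window_ms PLV analysis window (ms).
#' @param condition,correct_only trial selection, see [select_condition()];
#'   use `condition = NULL` to skip selection.
#'
#' @return A list with `matrices` (list `[[subject]][[band]]` of
#'   `plv_matrix`), and `info` (data frame of subject, band, trial count).
#' @export
cohort_connectivity <- function(epochs_list, bands = band_definitions(),
                                window_ms = c(200, 700),
                                condition = "NoGo", correct_only = TRUE) {
  subjects <- names(epochs_list)
  if (is.null(subjects)) subjects <- sprintf("S%03d", seq_along(epochs_list))
  n_nodes <- vapply(epochs_list, function(e) dim(e$data)[2L], integer(1))
  if (length(unique(n_nodes)) > 1L)
    stop("all subjects must share one node count", call. = FALSE)
  out <- vector("list", length(epochs_list))
  names(out) <- subjects
  selected <- vector("list", length(epochs_list))
  for (s in seq_along(epochs_list)) {
    ep <- epochs_list[[s]]
    if (!is.null(condition)) {
      ep <- tryCatch(select_condition(ep, condition, correct_only),
                     error = function(e) NULL)
    }
    if (is.null(ep) || n_epochs(ep) < 2L) {
      warning(sprintf("subject %s has < 2 usable epochs and was dropped",
                      subjects[s]), call. = FALSE)
      next
    }
    selected[[s]] <- ep
  }
  usable <- which(!vapply(selected, is.null, logical(1)))
  band_list <- lapply(seq_len(nrow(bands)),
                      function(b) c(bands$f_lo[b], bands$f_hi[b]))
  info <- list()
  # filter subjects in batches sharing one FFT, then fuse bands per subject
  for (chunk in split(usable, ceiling(seq_along(usable) / 16L))) {
    eps <- selected[chunk]
    fs <- eps[[1L]]$sample_rate
    times <- eps[[1L]]$times_ms
    for (e in eps)
      if (e$sample_rate != fs || length(e$times_ms) != length(times))
        stop("all subjects must share sample rate and epoch length",
             call. = FALSE)
    dims <- lapply(eps, function(e) dim(e$data))
    big <- do.call(cbind, lapply(eps, function(e) .epochs_to_mat(e$data)))
    if (any(colSums(abs(big)) == 0))
      stop("phase is undefined for an identically zero signal", call. = FALSE)
    keep_t <- which(times >= window_ms[1L] & times < window_ms[2L])
    if (!length(keep_t))
      stop("analysis window contains no samples", call. = FALSE)
    for (b in band_list)
      if (b[1L] < 0 || b[1L] >= b[2L] || b[2L] >= fs / 2)
        stop("invalid band edges: need 0 <= f_lo < f_hi < sample_rate/2",
             call. = FALSE)
    pinfo <- .band_pad_info(nrow(big), fs, band_list)
    xp <- .reflect_pad(big, pinfo$pad,
                       extra = pinfo$m - nrow(big) - 2L * pinfo$pad)
    ks <- vapply(dims, `[`, integer(1), 1L)
    nn <- dims[[1L]][2L]
    ws_bands <- .cpp_band_plv(xp, fs, do.call(rbind, band_list), 4L,
                              pinfo$pad + keep_t - 1L, ks, nn)
    for (j in seq_along(eps)) {
      mats <- lapply(seq_len(nrow(bands)), function(b)
        structure(ws_bands[[b]][[j]], class = c("plv_matrix", "matrix"),
                  band = bands$name[b], n_trials = ks[j]))
      names(mats) <- bands$name
      out[[chunk[j]]] <- mats
      for (b in seq_len(nrow(bands)))
        info[[length(info) + 1L]] <- list(subject = subjects[chunk[j]],
                                          band = bands$name[b],
                                          n_trials = ks[j])
    }
  }
  info_df <- if (length(info)) {
    data.frame(subject = vapply(info, `[[`, "", "subject"),
               band = vapply(info, `[[`, "", "band"),
               n_trials = vapply(info, function(x) x$n_trials, integer(1)))
  } else {
    data.frame(subject = character(), band = character(),
               n_trials = integer())
  }
  list(matrices = out[usable], info = info_df, window_ms = window_ms)
}
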