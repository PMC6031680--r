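# Instantaneous phase and phase-locking-value connectivity.

test_that("analytic phase of a pure oscillation has the right slope", {
  fs <- 1000
  n <- 1000
  t <- (seq_len(n) - 1) / fs
  arr <- array(0, c(1, 2, n))
  arr[1, 1, ] <- cos(2 * pi * 15 * t)
  arr[1, 2, ] <- sin(2 * pi * 15 * t)
  ep <- new_epoch_set_for_test(arr, fs = fs)
  # full epoch, no band filter needed for an already narrowband signal
  ph <- instantaneous_phase(ep, band = list(name = "b", f_lo = 12, f_hi = 18),
                            window_ms = c(100, 900))
  expect_true(all(ph$phases > -pi & ph$phases <= pi))
  slope <- diff(unwrap_phase(ph$phases[1, 1, ])) * fs
  inner <- 100:600
  expect_equal(mean(slope[inner]), 2 * pi * 15, tolerance = 0.01 * 2 * pi * 15)
  # sin lags cos by pi/2 at every sample
  dphi <- ph$phases[1, 1, ] - ph$phases[1, 2, ]
  dphi <- atan2(sin(dphi), cos(dphi))
  expect_equal(mean(dphi[inner]), pi / 2, tolerance = 0.02)
})

test_that("phase of an identically zero signal is an error", {
  arr <- array(0, c(2, 2, 100))
  arr[, 2, ] <- rnorm(200)
  ep <- new_epoch_set_for_test(arr, fs = 250)
  expect_error(instantaneous_phase(ep, window_ms = c(10, 90)), "zero signal")
})

test_that("PLV is 1 for identical or constant-offset phase patterns", {
  set.seed(3)
  base <- array(runif(40 * 2 * 60, -pi, pi), c(40, 2, 60))
  base[, 2, ] <- base[, 1, ]
  ph <- structure(list(phases = base, times_ms = 1:60, band = "b"),
                  class = "phase_epochs")
  expect_equal(unname(plv_matrix(ph)[1, 2]), 1, tolerance = 1e-12)
  # constant per-trial offset: PLV is invariant to fixed phase lags
  off <- base
  off[, 2, ] <- off[, 1, ] + 1.1
  ph2 <- structure(list(phases = off, times_ms = 1:60, band = "b"),
                   class = "phase_epochs")
  expect_equal(unname(plv_matrix(ph2)[1, 2]), 1, tolerance = 1e-12)
})

test_that("independent uniform phases give the null resultant level", {
  set.seed(7)
  ph <- structure(list(phases = array(runif(100 * 2 * 30, -pi, pi),
                                      c(100, 2, 30)),
                       times_ms = 1:30, band = "b"),
                  class = "phase_epochs")
  w <- plv_matrix(ph)
  # E ~ sqrt(pi)/(2 sqrt(N)) = 0.0886 at N = 100; averaging over window
  # samples shrinks the spread but not the mean
  expect_lt(abs(w[1, 2] - sqrt(pi) / (2 * sqrt(100))), 0.03)
})

test_that("PLV matrix respects its structural invariants", {
  set.seed(9)
  ph_arr <- array(runif(20 * 5 * 25, -pi, pi), c(20, 5, 25))
  ph <- structure(list(phases = ph_arr, times_ms = 1:25, band = "b"),
                  class = "phase_epochs")
  w <- plv_matrix(ph)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(unclass(w), t(unclass(w)))
  expect_equal(unname(diag(w)), rep(0, 5))
  # permuting trials leaves the matrix unchanged
  perm <- sample(20)
  ph_p <- structure(list(phases = ph_arr[perm, , , drop = FALSE],
                         times_ms = 1:25, band = "b"),
                    class = "phase_epochs")
  expect_equal(unclass(plv_matrix(ph_p)), unclass(w), tolerance = 1e-12)
  # a per-trial global phase shift applied to all nodes cancels in the
  # phase differences
  shift <- runif(20, -pi, pi)
  ph_s <- structure(list(phases = ph_arr + array(shift, c(20, 5, 25)),
                         times_ms = 1:25, band = "b"),
                    class = "phase_epochs")
  expect_equal(unclass(plv_matrix(ph_s)), unclass(w), tolerance = 1e-10)
})

test_that("single-trial across-trials PLV is rejected with guidance", {
  ph <- structure(list(phases = array(runif(1 * 3 * 10, -pi, pi),
                                      c(1, 3, 10)),
                       times_ms = 1:10, band = "b"),
                  class = "phase_epochs")
  expect_error(plv_matrix(ph), "within_trial")
  expect_silent(w <- plv_matrix(ph, convention = "within_trial"))
  expect_true(all(w >= 0 & w <= 1))
})

test_that("cohort connectivity yields one matrix per subject and band", {
  cfg <- sim_config(n_subjects_per_group = c(2, 2, 2), n_nodes = 6,
                    n_trials = 12, sample_rate = 125, nogo_only = TRUE)
  eps <- lapply(1:3, function(s) generate_subject_epochs(cfg, 0.4, seed = s))
  names(eps) <- paste0("S", 1:3)
  cc <- cohort_connectivity(eps)
  expect_equal(length(cc$matrices), 3L)
  expect_equal(sum(lengths(cc$matrices)), 12L)
  expect_equal(nrow(cc$info), 12L)
  expect_equal(unique(cc$info$n_trials), 12L)
})

test_that("zero-jitter subjects lock in every band containing a carrier", {
  cfg <- sim_config(n_subjects_per_group = c(2, 2, 2), n_nodes = 5,
                    n_trials = 20, sample_rate = 250,
                    amplitude_noise_sd = 0, nogo_only = TRUE)
  ep <- generate_subject_epochs(cfg, 0, seed = 44)
  cc <- cohort_connectivity(list(S1 = ep))
  for (b in band_definitions()$name) {
    w <- cc$matrices$S1[[b]]
    expect_true(all(w[upper.tri(w)] > 0.95), info = b)
  }
})

test_that("mean PLV decreases monotonically with subject jitter", {
  cfg <- sim_config(n_subjects_per_group = c(2, 2, 2), n_nodes = 8,
                    n_trials = 40, sample_rate = 125, nogo_only = TRUE)
  sigmas <- c(0.2, 0.5, 0.8, 1.1, 1.4)
  mean_plv <- vapply(seq_along(sigmas), function(i) {
    ep <- generate_subject_epochs(cfg, sigmas[i], seed = 100 + i)
    cc <- cohort_connectivity(list(S = ep))
    w <- cc$matrices$S$low_beta
    mean(w[upper.tri(w)])
  }, numeric(1))
  expect_lt(cor(sigmas, mean_plv, method = "spearman"), 0)
  expect_true(all(diff(mean_plv) < 0))
})

test_that("subjects with too few usable epochs are dropped with a warning", {
  cfg <- sim_config(n_subjects_per_group = c(2, 2, 2), n_nodes = 4,
                    n_trials = 10, sample_rate = 125, nogo_only = TRUE)
  ok <- generate_subject_epochs(cfg, 0.5, seed = 1)
  starved <- ok[1]  # a single NoGo epoch
  expect_warning(cc <- cohort_connectivity(list(A = ok, B = starved)),
                 "dropped")
  expect_equal(names(cc$matrices), "A")
})

test_that("batched cohort path agrees with the single-subject path", {
  cfg <- sim_config(n_subjects_per_group = c(2, 2, 2), n_nodes = 6,
                    n_trials = 15, sample_rate = 250, nogo_only = TRUE)
  ep <- generate_subject_epochs(cfg, 0.6, seed = 77)
  cc <- cohort_connectivity(list(S = ep))
  for (b in seq_len(4)) {
    direct <- plv_matrix(instantaneous_phase(ep, band_definitions()[b, ]))
    expect_equal(unclass(cc$matrices$S[[b]]), unclass(direct),
                 tolerance = 0.01)
  }
})
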