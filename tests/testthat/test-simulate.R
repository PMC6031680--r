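# Synthetic cohort generator: analytic PLV law, determinism, cohort
# structure, sensor projection.

test_that("expected_plv follows the wrapped-normal closed form", {
  expect_identical(expected_plv(0, 0), 1)
  # Monte-Carlo oracle of |mean resultant| of eps_i - eps_j at sigma = 0.5
  set.seed(11)
  mc <- mean(replicate(400, {
    d <- rnorm(4000, 0, 0.5) - rnorm(4000, 0, 0.5)
    Mod(mean(exp(1i * d)))
  }))
  expect_equal(expected_plv(0.5, 0.5), 0.7788, tolerance = 1e-4)
  expect_equal(expected_plv(0.5, 0.5), mc, tolerance = 0.005)
  expect_lt(expected_plv(10, 10), 1e-21)
  expect_true(all(diff(expected_plv(c(0, 0.3, 0.7, 1.2), 0)) < 0))
  expect_error(expected_plv(-0.1, 0.5), "non-negative")
})

test_that("zero jitter gives near-perfect phase locking downstream", {
  cfg <- sim_config(n_subjects_per_group = c(2, 2, 2), n_nodes = 5,
                    n_trials = 30, sample_rate = 250,
                    amplitude_noise_sd = 0, nogo_only = TRUE)
  ep <- generate_subject_epochs(cfg, 0, seed = 5)
  for (b in seq_len(4)) {
    w <- plv_matrix(instantaneous_phase(ep, band_definitions()[b, ]))
    off <- w[upper.tri(w)]
    expect_true(all(off > 0.99), info = band_definitions()$name[b])
  }
})

test_that("generated pairs reproduce the analytic PLV within Monte-Carlo error", {
  sig <- c(0, 0.25, 0.5, 1.0)
  cfg <- sim_config(n_subjects_per_group = c(2, 2, 2), n_nodes = 4,
                    n_trials = 500, sample_rate = 250,
                    amplitude_noise_sd = 0, nogo_only = TRUE)
  ep <- generate_subject_epochs(cfg, sig, seed = 21)
  w <- plv_matrix(instantaneous_phase(ep, band_definitions()[2, ]))
  for (i in 1:3) for (j in (i + 1):4) {
    se <- mc_plv_se(sig[i], sig[j], 500, reps = 300)
    expect_lt(abs(w[i, j] - expected_plv(sig[i], sig[j])),
              3 * se + 0.005)
  }
})

test_that("phases with effectively unbounded jitter give the null resultant level", {
  # with sigma >> pi the pairwise phase differences are uniform, so the
  # empirical PLV matches the resultant length of N random unit vectors,
  # E ~ sqrt(pi) / (2 sqrt(N)) ~ 0.089 at N = 100
  cfg <- sim_config(n_subjects_per_group = c(2, 2, 2), n_nodes = 2,
                    n_trials = 100, sample_rate = 250,
                    amplitude_noise_sd = 0, nogo_only = TRUE)
  # the single-pair estimate is Rayleigh with SD ~ sqrt((4-pi)/(4N)), so
  # average over independent subjects to beat the Monte-Carlo spread
  plvs <- vapply(1:10, function(s) {
    ep <- generate_subject_epochs(cfg, 30, seed = 8 + s)
    plv_matrix(instantaneous_phase(ep, band_definitions()[2, ]))[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(plvs) - sqrt(pi) / (2 * sqrt(100))), 0.03)
})

test_that("subject epoch generation is deterministic and validates input", {
  cfg <- sim_config(n_subjects_per_group = c(2, 2, 2), n_nodes = 6,
                    n_trials = 10, sample_rate = 125)
  a <- generate_subject_epochs(cfg, 0.5, seed = 3)
  b <- generate_subject_epochs(cfg, 0.5, seed = 3)
  expect_identical(a, b)
  expect_equal(dim(a$data), c(10L, 6L, 125L))
  expect_equal(a$times_ms[1], -100)
  expect_equal(length(a$times_ms), 125L)  # half-open window at 125 Hz
  expect_error(generate_subject_epochs(cfg, -1, seed = 1), "non-negative")
  expect_error(generate_subject_epochs(cfg, NaN, seed = 1), "finite")
})

test_that("sim_config enforces its invariants", {
  expect_error(sim_config(n_subjects_per_group = c(0, 5, 5)), "positive")
  expect_error(sim_config(go_probability = 1), "strictly")
  expect_error(sim_config(phase_jitter_sigma = c(-0.1, 0.2, 0.3)),
               "non-negative")
  expect_warning(sim_config(phase_jitter_sigma = c(0.9, 0.8, 0.7)),
                 "non-decreasing")
  expect_error(sim_config(sample_rate = 60), "twice the highest carrier")
})

test_that("generate_cohort builds a quartile-consistent, reproducible cohort", {
  cfg <- sim_config(n_subjects_per_group = c(10, 16, 10), n_nodes = 4,
                    n_trials = 6, sample_rate = 125, seed = 42)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1$records, coh2$records)
  expect_identical(coh1$epochs, coh2$epochs)

  rec <- coh1$records
  expect_equal(nrow(rec), 36L)
  expect_equal(as.vector(table(rec$group_label)), c(10L, 16L, 10L))
  sub_cols <- grep("^ctq_(?!total)", names(rec), perl = TRUE, value = TRUE)
  expect_true(all(rec[sub_cols] >= 5 & rec[sub_cols] <= 25))
  expect_equal(rec$ctq_total, rowSums(rec[sub_cols]))
  # totals live inside the quartile intervals that define the groups
  expect_true(all(rec$ctq_total[rec$group_label == "low"] <= 34))
  expect_true(all(rec$ctq_total[rec$group_label == "middle"] > 34 &
                    rec$ctq_total[rec$group_label == "middle"] < 47.5))
  expect_true(all(rec$ctq_total[rec$group_label == "high"] >= 47.5))
})

test_that("cohort covariates rise (or fall) with the trauma-analog group", {
  # records-only cohort, large enough to resolve the smallest planted
  # covariate shift (activation drive, ~0.4 points against SD ~1.9)
  cfg <- sim_config(n_subjects_per_group = c(400, 600, 400), n_nodes = 2,
                    n_trials = 2, seed = 9)
  rec <- generate_cohort(cfg, signals = FALSE)$records
  gm <- function(v) tapply(rec[[v]], rec$group_label, mean)
  for (v in c("sai", "tai", "bdi", "caars_total"))
    expect_lt(gm(v)["low"], gm(v)["high"])
  expect_gt(gm("bas_drive")["low"], gm("bas_drive")["high"])
})

test_that("group jitter ordering carries into subject sigmas", {
  cfg <- sim_config(n_subjects_per_group = c(30, 30, 30), n_nodes = 2,
                    n_trials = 2, seed = 4)
  coh <- generate_cohort(cfg, signals = FALSE)
  sig_by_group <- tapply(coh$sigmas, coh$records$group_label, mean)
  expect_true(sig_by_group["low"] < sig_by_group["middle"])
  expect_true(sig_by_group["middle"] < sig_by_group["high"])
})

test_that("project_to_sensors applies the forward model faithfully", {
  cfg <- sim_config(n_subjects_per_group = c(2, 2, 2), n_nodes = 5,
                    n_trials = 4, sample_rate = 125)
  ep <- generate_subject_epochs(cfg, 0.3, seed = 2)
  ident <- project_to_sensors(ep, diag(5), sensor_noise_sd = 0)
  expect_equal(ident$data, ep$data)
  zero <- project_to_sensors(ep, matrix(0, 3, 5), sensor_noise_sd = 0)
  expect_true(all(zero$data == 0))
  expect_equal(dim(zero$data), c(4L, 3L, 125L))
  expect_error(project_to_sensors(ep, matrix(1, 3, 4)), "gain has 4 columns")
})

test_that("per-edge jitter covariance mode honours its expected PLV law", {
  # jitter covariance S gives pairwise PLV exp(-(S_ii + S_jj - 2 S_ij)/2)
  s <- matrix(c(0.25, 0.15, 0.15, 0.25), 2)
  cfg <- sim_config(n_subjects_per_group = c(2, 2, 2), n_nodes = 2,
                    n_trials = 2000, sample_rate = 125,
                    amplitude_noise_sd = 0, nogo_only = TRUE)
  ep <- generate_subject_epochs(cfg, 0.5, seed = 13, phase_cov = s)
  w <- plv_matrix(instantaneous_phase(ep, band_definitions()[2, ]))
  expect_equal(unname(w[1, 2]), exp(-(s[1, 1] + s[2, 2] - 2 * s[1, 2]) / 2),
               tolerance = 0.02)
})

test_that("simulate_correlated_index plants a recoverable partial dependence", {
  cfg <- sim_config(n_subjects_per_group = c(50, 100, 50), n_nodes = 2,
                    n_trials = 2, seed = 31)
  rec <- generate_cohort(cfg, signals = FALSE)$records
  y <- simulate_correlated_index(rec, target_r = -0.4, seed = 77)
  covs <- rec[, c("sai", "tai", "bdi", "caars_total")]
  r <- partial_correlation(rec$ctq_total, y, covs)$r_partial
  expect_lt(r, 0)
  expect_equal(r, -0.4, tolerance = 0.12)
})
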