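test_that("identical (params, seed) reproduce a patient and a cohort exactly", {
  p <- sim_params(cohort_size = 3, seed = 99)
  a <- simulate_patient(p, 1234L, waveforms = TRUE)
  b <- simulate_patient(p, 1234L, waveforms = TRUE)
  expect_identical(a$truth, b$truth)
  expect_identical(a$beats_true, b$beats_true)
  expect_identical(a$record$channels$ECG$samples, b$record$channels$ECG$samples)
  expect_identical(unclass(a$clinical), unclass(b$clinical))
  c1 <- simulate_cohort(p)
  c2 <- simulate_cohort(p)
  expect_identical(sapply(c1, function(x) x$truth$true_ttd_min),
                   sapply(c2, function(x) x$truth$true_ttd_min))
  c3 <- simulate_cohort(sim_params(cohort_size = 3, seed = 100))
  expect_false(identical(sapply(c1, function(x) x$truth$true_ttd_min),
                         sapply(c3, function(x) x$truth$true_ttd_min)))
})

test_that("invalid simulation parameters and seeds are rejected", {
  expect_error(sim_params(cohort_size = 0), "cohort_size")
  expect_error(sim_params(rr_mean_ms = -1), "positive")
  expect_error(sim_params(ar_phi = 1.2), "ar_phi")
  expect_error(sim_params(pre_wlsm_min = 10), "pre_wlsm_min")
  expect_error(simulate_patient(sim_params(), -5), "patient_seed")
})

test_that("higher frailty shortens time to death (Weibull arm comparison)", {
  p <- sim_params()
  f_hi <- qlnorm(0.99, p$frailty_meanlog, p$frailty_sdlog)
  f_lo <- qlnorm(0.01, p$frailty_meanlog, p$frailty_sdlog)
  draw_ttd <- function(f) {
    vapply(1:200, function(i) {
      simulate_patient(p, 3000L + i, waveforms = FALSE,
                       frailty = f)$truth$true_ttd_min
    }, numeric(1))
  }
  ttd_hi <- draw_ttd(f_hi)
  ttd_lo <- draw_ttd(f_lo)
  expect_lt(median(ttd_hi), median(ttd_lo))
  # Monte-Carlo oracle from the stated Weibull itself
  set.seed(77)
  orc_hi <- median(rweibull(5000, p$ttd_shape,
                            p$ttd_scale0_min / f_hi^p$ttd_frailty_exp))
  orc_lo <- median(rweibull(5000, p$ttd_shape,
                            p$ttd_scale0_min / f_lo^p$ttd_frailty_exp))
  expect_lt(orc_hi, orc_lo)
  expect_lt(abs(median(ttd_hi) - orc_hi) / orc_hi, 0.5)
})

test_that("zero variability and zero noise give a perfectly periodic heart", {
  p <- sim_params(rr_base_sd_ms = 0, press_base_sd_mmHg = 0, noise_sd = 0)
  pat <- simulate_patient(p, 42L, waveforms = TRUE)
  expect_true(all(abs(pat$beats_true$rri_ms[-1] - p$rr_mean_ms) < 1e-9))
  peaks <- suppressWarnings(
    detect_r_peaks(pat$record$channels$ECG$samples, 500))
  rr_det <- diff(peaks) * 1000
  expect_true(all(abs(rr_det - p$rr_mean_ms) <= 4))  # within +/- 2 samples
})

test_that("cohort death frequency by 120 min matches the analytic Weibull mixture", {
  p <- sim_params(cohort_size = 206, seed = 321)
  coh <- simulate_cohort(p)
  emp <- mean(vapply(coh, function(x) x$truth$true_ttd_min <= 120, logical(1)))
  oracle <- integrate(function(f) {
    pweibull(120, p$ttd_shape, p$ttd_scale0_min / f^p$ttd_frailty_exp) *
      dlnorm(f, p$frailty_meanlog, p$frailty_sdlog)
  }, 0, Inf)$value
  expect_lt(abs(emp - oracle), 0.05)
})

test_that("survival indicators are monotone across horizons for every patient", {
  coh <- simulate_cohort(sim_params(cohort_size = 40, seed = 11))
  for (pt in coh) {
    dw <- pt$truth$died_within
    expect_true(all(diff(as.integer(dw)) >= 0))  # once dead, stays dead
    expect_length(dw, 16)
  }
})

test_that("reduced RR variability is associated with shorter time to death", {
  coh <- simulate_cohort(sim_params(cohort_size = 200, seed = 2024))
  rr_sd <- vapply(coh, function(p) sd(p$beats_true$rri_ms, na.rm = TRUE),
                  numeric(1))
  ttd <- vapply(coh, function(p) p$truth$true_ttd_min, numeric(1))
  ct <- suppressWarnings(cor.test(rr_sd, ttd, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("post-WLSM vitals follow the stated decline model", {
  p <- sim_params()
  truth <- list(frailty = 1.5, true_ttd_min = 40)
  traj <- generate_post_wlsm_vitals(truth, p, step_s = 1)
  expect_equal(traj$map[1], p$map_baseline_mmHg, tolerance = 1e-10)
  # pulse pressure hits 5 mm Hg at the true time of death and stays below
  pp <- traj$sbp - traj$dbp
  at_ttd <- which.min(abs(traj$time_s - 40 * 60))
  expect_equal(pp[at_ttd], 5, tolerance = 0.01)
  expect_true(all(pp[traj$time_s > 40 * 60 + 1] < 5))
  # trajectory extends at least 5 min past arrest
  expect_gte(max(traj$time_s), (40 + 5) * 60)
  # doubling the decline rate halves the MAP half-fall time (closed form)
  half_time <- function(rate) {
    pr <- sim_params(decline_rate_per_min = rate)
    tr <- generate_post_wlsm_vitals(truth, pr, step_s = 0.5)
    approx(tr$map, tr$time_s, xout = pr$map_baseline_mmHg / 2)$y
  }
  expect_equal(half_time(0.04) / half_time(0.08), 2, tolerance = 0.01)
})

test_that("generate_post_wlsm_vitals validates its inputs", {
  p <- sim_params()
  expect_error(generate_post_wlsm_vitals(list(frailty = 1), p), "ground truth")
  expect_error(generate_post_wlsm_vitals(list(frailty = 1, true_ttd_min = 10),
                                         p, step_s = 0), "step_s")
})

test_that("a cohort round-trips through its on-disk layout", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(sim_params(cohort_size = 3, seed = 8))
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$truth$true_ttd_min, coh[[i]]$truth$true_ttd_min)
    expect_equal(back[[i]]$beats_true$rri_ms, coh[[i]]$beats_true$rri_ms,
                 tolerance = 1e-8)
    expect_identical(back[[i]]$physician$category, coh[[i]]$physician$category)
  }
})
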