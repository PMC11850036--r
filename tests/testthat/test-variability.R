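test_that("Poincare SD1/SD2 match the rotated point-cloud oracle", {
  set.seed(101)
  for (k in 1:10) {
    x <- 900 + cumsum(rnorm(750, 0, 10))
    got <- poincare_metrics(x)
    want <- oracle_poincare(x)
    expect_equal(got$sd1, want$sd1, tolerance = 1e-10)
    expect_equal(got$sd2, want$sd2, tolerance = 1e-10)
  }
})

test_that("Poincare descriptors obey degeneracy, homogeneity and the rotation identity", {
  expect_equal(poincare_metrics(rep(800, 10)), list(sd1 = 0, sd2 = 0))
  set.seed(7)
  x <- rnorm(500, 900, 40)
  p1 <- poincare_metrics(x)
  p3 <- poincare_metrics(3 * x)
  expect_equal(p3$sd1, 3 * p1$sd1, tolerance = 1e-12)
  expect_equal(p3$sd2, 3 * p1$sd2, tolerance = 1e-12)
  # SD1^2 + SD2^2 = var(lagged) + var(leading): rotation preserves total variance
  expect_equal(p1$sd1^2 + p1$sd2^2,
               var(x[-1]) + var(x[-length(x)]), tolerance = 1e-9)
  expect_error(poincare_metrics(c(1, 2)), "at least 3")
})

test_that("DFA agrees with an independently coded textbook implementation", {
  set.seed(202)
  for (k in 1:10) {
    x <- if (k %% 2) rnorm(1500) else cumsum(rnorm(1500))
    got <- dfa(x)
    want <- oracle_dfa(x)
    expect_equal(got$fluctuation, want$fluctuation, tolerance = 1e-8)
    expect_equal(got$alpha1, want$alpha1, tolerance = 1e-8)
    expect_equal(got$alpha2, want$alpha2, tolerance = 1e-8)
    expect_equal(got$auc, want$auc, tolerance = 1e-8)
  }
})

test_that("DFA is scale-aware: doubling shifts the log-log curve, not the slopes", {
  set.seed(33)
  x <- rnorm(2000, 0, 5)
  d1 <- dfa(x)
  d2 <- dfa(2 * x)
  expect_equal(d2$alpha1, d1$alpha1, tolerance = 1e-9)
  expect_equal(d2$alpha2, d1$alpha2, tolerance = 1e-9)
  width <- log(max(d1$scales)) - log(min(d1$scales))
  expect_equal(d2$auc - d1$auc, log(2) * width, tolerance = 1e-9)
})

test_that("DFA flags degenerate input instead of erroring", {
  d <- dfa(rep(5, 2000))
  expect_true(d$degenerate)
  expect_true(is.na(d$alpha1) && is.na(d$auc))
  expect_error(dfa(rnorm(100)), "too short")
})

test_that("grid count equals brute-force pixel enumeration and saturates correctly", {
  expect_equal(grid_count(rep(800, 50), grid_n = 32), 1 / 32^2)
  # de Bruijn-style sequence visiting all 4 pixels of a 2x2 grid
  expect_equal(grid_count(c(0.25, 0.25, 0.75, 0.75, 0.25), grid_n = 2,
                          range = c(0, 1)), 1)
  set.seed(44)
  for (k in 1:10) {
    x <- rnorm(750, 900, 120)
    expect_identical(grid_count(x, 32, range = c(250, 3000)),
                     oracle_grid_count(x, 32, c(250, 3000)))
  }
  expect_error(grid_count(1, grid_n = 32), "at least 2")
  expect_error(grid_count(c(1, 2), grid_n = 1), "grid_n")
})

test_that("grid occupancy cannot rise when resolution doubles on nested grids", {
  set.seed(55)
  for (k in 1:20) {
    x <- rnorm(400, 900, 150)
    occ <- sapply(c(4, 8, 16, 32, 64), function(g)
      grid_count(x, g, range = c(250, 3000)))
    expect_true(all(diff(occ) <= 1e-12))
  }
})

test_that("sample entropy and band powers behave on structured signals", {
  set.seed(66)
  x <- rnorm(400)
  se <- sample_entropy(x)
  expect_true(is.finite(se) && se > 0)
  expect_true(is.na(sample_entropy(rep(1, 400))))
  mse <- multiscale_entropy(x)
  expect_length(mse$entropies, 5)
  # a slow 0.1 Hz oscillation in the LF band dominates LF over HF
  t <- cumsum(runif(400, 0.7, 1.1))
  lsp <- lomb_band_powers(t, sin(2 * pi * 0.1 * t))
  expect_gt(lsp$lf, 10 * lsp$hf)
  # full-band power approximates the series variance by construction
  expect_equal(lsp$total, var(sin(2 * pi * 0.1 * t)), tolerance = 0.15)
})

test_that("windowize partitions accepted beats and rejects over-long spans", {
  mk <- function(n, dt) {
    clean_beats(beat_series(cumsum(rep(dt, n)), sbp = 120, dbp = 80, map = 93))
  }
  w2 <- windowize(mk(1500, 0.9))
  expect_length(w2$windows, 2)
  expect_null(w2$partial)
  w0 <- suppressWarnings(windowize(mk(749, 0.9)))
  expect_length(w0$windows, 0)
  expect_equal(nrow(w0$partial), 749)
  expect_warning(windowize(mk(700, 0.9)), "accepted beats")
  # 750 beats spanning > 60 min: rejected with reason "span"
  slow <- beat_series(cumsum(rep(5.2, 760)))   # 5.2 s beats, quality accepted
  ws <- windowize(slow)
  expect_length(ws$windows, 0)
  expect_equal(ws$rejected[[1]]$reason, "span")
})

test_that("the panel has exactly 17 named metrics per window and source", {
  pat <- simulate_patient(sim_params(), 808L, waveforms = FALSE)
  panel <- metric_panel(clean_beats(pat$beats_true),
                        sources = c("rri", "sbp", "dbp", "map"))
  expect_true(nrow(panel) > 0)
  for (sp in split(panel, interaction(panel$window_id, panel$source))) {
    expect_setequal(sp$metric, variability_metric_names())
    expect_length(variability_metric_names(), 17)
  }
  expect_true(all(is.finite(panel$value)))
})

test_that("a constant RR series collapses the panel to its degenerate values", {
  bs <- clean_beats(beat_series(cumsum(rep(0.9, 800)), sbp = 120, dbp = 80,
                                map = 93))
  panel <- metric_panel(bs, sources = "rri")
  v <- setNames(panel$value, panel$metric)
  expect_equal(unname(v["sdnn"]), 0)
  expect_equal(unname(v["rmssd"]), 0)
  expect_equal(unname(v["sd1"]), 0)
  expect_equal(unname(v["sd2"]), 0)
  expect_equal(unname(v["grid_count"]), 1 / 32^2)
})

test_that("all panel metrics are invariant to time translation of the window", {
  pat <- simulate_patient(sim_params(), 909L, waveforms = FALSE)
  b0 <- clean_beats(pat$beats_true)
  b1 <- b0
  b1$beat_time_s <- b1$beat_time_s + 5000
  p0 <- metric_panel(b0, sources = c("rri", "sbp"))
  p1 <- metric_panel(b1, sources = c("rri", "sbp"))
  expect_equal(p0$value, p1$value, tolerance = 1e-8)
})

test_that("diastolic Poincare SD2 is lower in the high-frailty stratum", {
  p <- sim_params()
  f_hi <- qlnorm(0.85, p$frailty_meanlog, p$frailty_sdlog)
  f_lo <- qlnorm(0.15, p$frailty_meanlog, p$frailty_sdlog)
  sd2_for <- function(f, off) {
    vapply(1:40, function(i) {
      pt <- simulate_patient(p, 40000L + off + i, waveforms = FALSE, frailty = f)
      poincare_metrics(pt$beats_true$dbp)$sd2
    }, numeric(1))
  }
  expect_lt(mean(sd2_for(f_hi, 0)), mean(sd2_for(f_lo, 1000)))
})

test_that("the panel summary takes per-metric medians over recent windows", {
  panel <- data.frame(window_id = c(1, 2, 3), source = "rri", metric = "sdnn",
                      value = c(10, 20, 30),
                      start_s = c(0, 700, 1400), end_s = c(700, 1400, 2100),
                      n_beats = 750)
  s <- variability_summary(panel, recent_min = 60)
  expect_equal(unname(s["rri_sdnn"]), 20)         # all three windows recent
  s2 <- variability_summary(panel, recent_min = 10)
  expect_equal(unname(s2["rri_sdnn"]), 30)        # only the last one
})
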