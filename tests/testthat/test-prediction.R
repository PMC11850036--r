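test_that("feature encoding follows the documented rules", {
  pp <- physician_prediction("<=2h", "high")
  v <- assemble_features(pp = pp, variant = "physician")
  expect_equal(unname(v), c(120, 3))
  expect_named(v, c("phys_ttd_min", "phys_confidence"))
  # combined schema: 17 metrics x 3 sources + 16 clinical + 2 physician
  sch <- feature_schema("combined")
  expect_length(sch, 17 * 3 + 16 + 2)
  cs <- clinical_snapshot(20, 6, 4, TRUE, FALSE, TRUE, 7.3, 0.4, 25, 2.5,
                          14, 45, 2, 3, 3, FALSE)
  vv <- setNames(rep(1, 51), feature_schema("variability"))
  x <- assemble_features(vv = vv, cs = cs, pp = pp, variant = "combined")
  expect_identical(names(x), sch)
  # two snapshots differing only in lactate differ only at that coordinate
  cs2 <- cs; cs2$lactate_mmol_L <- 9.9
  x2 <- assemble_features(vv = vv, cs = cs2, pp = pp, variant = "combined")
  expect_identical(names(which(x != x2)), "lactate_mmol_L")
})

test_that("missing feature blocks are named in the validation error", {
  expect_error(assemble_features(variant = "variability"), "variability block")
  expect_error(assemble_features(vv = c(a = 1), variant = "combined"),
               "clinical block")
})

test_that("clinical snapshot and physician prediction enforce their domains", {
  expect_error(clinical_snapshot(20, 6, 2, TRUE, TRUE, TRUE, 7.3, 0.4, 25,
                                 2, 14, 45, 2, 3, 3, FALSE), "gcs")
  expect_error(clinical_snapshot(20, 6, 4, TRUE, TRUE, TRUE, 7.3, 0.1, 25,
                                 2, 14, 45, 2, 3, 3, FALSE), "fio2")
  expect_error(clinical_snapshot(20, 6, 4, TRUE, TRUE, TRUE, 7.3, 0.4, 25,
                                 2, 14, 45, -1, 3, 3, FALSE), "ranks")
  expect_error(physician_prediction("tomorrow", "high"))
  expect_error(physician_prediction("<=2h", "certain"))
})

test_that("model fitting is deterministic and enforces preconditions", {
  fe <- quick_clinical_features()
  m1 <- fit_ttd_model(fe$x, fe$time, fe$status, "clinical",
                      num_trees = 100, seed = 3)
  m2 <- fit_ttd_model(fe$x, fe$time, fe$status, "clinical",
                      num_trees = 100, seed = 3)
  p1 <- predict(m1, fe$x[1, , drop = FALSE])
  p2 <- predict(m2, fe$x[1, , drop = FALSE])
  expect_identical(p1$p_death, p2$p_death)
  expect_error(fit_ttd_model(fe$x[1:20, ], fe$time[1:20], fe$status[1:20]),
               "50 training cases")
  expect_error(fit_ttd_model(fe$x, fe$time, rep(0L, nrow(fe$x))),
               "10 events")
})

test_that("predictions are monotone across horizons, within [0,1], and schema-checked", {
  fe <- quick_clinical_features()
  m <- fit_ttd_model(fe$x, fe$time, fe$status, "clinical",
                     num_trees = 100, seed = 3)
  preds <- predict(m, fe$x)
  for (p in preds[1:10]) {
    expect_true(all(p$p_death >= 0 & p$p_death <= 1))
    expect_true(all(diff(p$p_death) >= -1e-12))
    tri <- p$p_death[match(c(30, 120, 240), p$horizons_min)]
    expect_true(tri[3] >= tri[2] && tri[2] >= tri[1])
  }
  bad <- fe$x[1, , drop = FALSE]
  names(bad)[1] <- "not_a_feature"
  err <- tryCatch(predict(m, bad), error = conditionMessage)
  expect_match(err, "schema mismatch")
  expect_match(err, names(fe$x)[1])       # the missing feature is named
  expect_match(err, "not_a_feature")      # the extra feature is named
})

test_that("isotonic calibration recovers a calibrated signal and clips its output", {
  set.seed(12)
  # grouped pairs whose outcome frequency equals the stated probability
  p_grid <- rep(seq(0.05, 0.95, by = 0.05), each = 250)
  y <- rbinom(length(p_grid), 1, p_grid)
  map <- fit_calibrator(p_grid, y)
  probe <- seq(0.1, 0.9, by = 0.1)
  expect_lt(max(abs(apply_calibrator(map, probe) - probe)), 0.05)
  expect_true(all(apply_calibrator(map, c(-0.5, 0.5, 1.7)) >= 0))
  expect_true(all(apply_calibrator(map, c(-0.5, 0.5, 1.7)) <= 1))
  expect_warning(m1 <- fit_calibrator(runif(30), rep(1, 30)), "single-class")
  expect_equal(apply_calibrator(m1, 0.3), 0.3)
})

test_that("serial stability is the per-horizon range of serial probabilities", {
  mk <- function(p120) {
    structure(list(horizons_min = prediction_horizons(),
                   p_death = c(rep(p120 / 2, 7), rep(p120, 9)),
                   variant = "combined", assessed_at = ""),
              class = "survival_prediction")
  }
  s <- serial_stability(list(mk(0.3), mk(0.5), mk(0.45)))
  expect_equal(unname(s["h120"]), 0.2)
  expect_equal(unname(serial_stability(list(mk(0.4), mk(0.4)))["h120"]), 0)
  expect_error(serial_stability(list(mk(0.4))), "at least 2")
  other <- mk(0.4); other$variant <- "variability"
  expect_error(serial_stability(list(mk(0.4), other)), "same model variant")
})

test_that("calibration-in-the-large matches constructed predictions", {
  pm <- matrix(0.5, nrow = 40, ncol = 16)
  ttd <- c(rep(10, 20), rep(1000, 20))   # half die early, half never
  ev <- evaluate_calibration(pm, ttd)
  expect_equal(ev$mean_predicted, rep(0.5, 3))
  expect_equal(ev$observed_frequency, rep(0.5, 3))
  expect_true(all(ev$ci_lo < 0.5 & ev$ci_hi > 0.5))
  expect_error(evaluate_calibration(pm[1:10, ], ttd[1:10]), "20 cases")
  # binomial CI width shrinks like 1/sqrt(n)
  widths <- sapply(c(50, 200, 800), function(n) {
    e <- evaluate_calibration(matrix(0.5, n, 16), rep(c(10, 1000), n / 2))
    e$ci_hi[1] - e$ci_lo[1]
  })
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[1] / widths[3], sqrt(800 / 50), tolerance = 0.25)
})

test_that("physician accuracy scores category-vs-outcome agreement per horizon", {
  pps <- list(physician_prediction("<=0.5h", "high"),
              physician_prediction("<=0.5h", "low"))
  acc <- physician_accuracy(pps, c(10, 10))
  expect_equal(unname(acc), rep(1, 5))
  acc2 <- physician_accuracy(list(physician_prediction(">6h", "high")), 20)
  expect_equal(unname(acc2), rep(0, 5))
  expect_error(physician_accuracy(pps, c(10, 10, 10)), "length")
  # a noise-free assessment of the patient state beats a noisy one, and any
  # assessment noise leaves accuracy below 1 at 2 h
  coh0 <- simulate_cohort(sim_params(cohort_size = 200, seed = 61,
                                     physician_error_sd = 0))
  ttd0 <- sapply(coh0, function(p) p$truth$true_ttd_min)
  acc0 <- physician_accuracy(lapply(coh0, `[[`, "physician"), ttd0)
  coh1 <- simulate_cohort(sim_params(cohort_size = 200, seed = 61,
                                     physician_error_sd = 1))
  ttd1 <- sapply(coh1, function(p) p$truth$true_ttd_min)
  acc1 <- physician_accuracy(lapply(coh1, `[[`, "physician"), ttd1)
  expect_gt(mean(acc0), mean(acc1))
  expect_lt(unname(acc1["h120"]), 1)
})

test_that("model bundles persist with integrity checking", {
  fe <- quick_clinical_features()
  m <- fit_ttd_model(fe$x, fe$time, fe$status, "clinical",
                     num_trees = 50, seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_ttd_model(m, path)
  back <- load_ttd_model(path)
  expect_identical(predict(back, fe$x[2, , drop = FALSE])$p_death,
                   predict(m, fe$x[2, , drop = FALSE])$p_death)
  # corrupt the bundle: integrity check must fail
  writeBin(as.raw(c(1, 2, 3)), path)
  expect_error(load_ttd_model(path), "integrity")
})
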