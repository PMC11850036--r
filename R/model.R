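#' Fit an isotonic probability calibration map
#'
#' Isotonic regression of binary outcomes on out-of-bag predicted
#' probabilities, packaged as a monotone map `[0, 1] -> [0, 1]`. If the
#' outcomes are single-class the identity map is returned with a warning.
#'
#' @param p predicted probabilities in `[0, 1]`.
#' @param y binary outcomes (0/1).
#' @return list of class `calibration_map` with fields `x`, `y` (the
#'   monotone fit) or `identity = TRUE`.
#' @export
fit_calibrator <- function(p, y) {
  stopifnot(length(p) == length(y))
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    warning("single-class outcomes: identity calibration map", call. = FALSE)
    return(structure(list(identity = TRUE), class = "calibration_map"))
  }
  o <- order(p)
  iso <- stats::isoreg(p[o], y[o])
  ux <- iso$x[!duplicated(iso$x)]
  uy <- iso$yf[!duplicated(iso$x)]
  structure(list(identity = FALSE, x = ux, y = pmin(pmax(uy, 0), 1)),
            class = "calibration_map")
}

#' Apply a calibration map
#' @param map a `calibration_map`.
#' @param p probabilities to calibrate.
#' @return calibrated probabilities, clipped to `[0, 1]`.
#' @export
apply_calibrator <- function(map, p) {
  stopifnot(inherits(map, "calibration_map"))
  p <- pmin(pmax(p, 0), 1)
  if (isTRUE(map$identity)) return(p)
  if (length(map$x) == 1) return(rep(map$y, length(p)))
  pmin(pmax(stats::approx(map$x, map$y, xout = p, rule = 2)$y, 0), 1)
}

impute_medians <- function(x, medians = NULL) {
  if (is.null(medians)) {
    medians <- vapply(x, function(col) {
      m <- stats::median(col, na.rm = TRUE)
      if (is.finite(m)) m else 0
    }, numeric(1))
  }
  for (nm in names(x)) {
    bad <- !is.finite(x[[nm]])
    if (any(bad)) x[[nm]][bad] <- medians[[nm]]
  }
  list(x = x, medians = medians)
}

#' Fit a calibrated random survival forest for time to death
#'
#' Fits a ranger random survival forest on right-censored WLSM-to-death
#' times (censoring at 240 min, the 4-h prediction cap), then fits one
#' isotonic calibration map per 15-min horizon on the forest's out-of-bag
#' predicted event probabilities versus the observed binary outcomes.
#' Missing feature values are median-imputed (training medians are stored
#' and reused at prediction time, with a missingness indicator added for
#' features that were ever missing in training).
#'
#' @param x data.frame of features (columns must match
#'   [feature_schema()] for the variant).
#' @param time observed time in minutes, censored at 240.
#' @param status event indicator (1 = died by 240 min).
#' @param variant model variant label.
#' @param num_trees number of trees (default 1000).
#' @param mtry features per split (default `sqrt(p)`).
#' @param min_node_size minimum terminal node size (default 5).
#' @param seed RNG seed: refitting with the same seed reproduces the model.
#' @return object of class `ttd_model`.
#' @export
fit_ttd_model <- function(x, time, status, variant = "combined",
                          num_trees = 1000L, mtry = NULL,
                          min_node_size = 5L, seed = 1L) {
  stopifnot(is.data.frame(x), nrow(x) == length(time),
            length(time) == length(status))
  if (nrow(x) < 50) stop("need at least 50 training cases", call. = FALSE)
  if (sum(status == 1 & time < 240) < 10) {
    stop("need at least 10 events before 240 min", call. = FALSE)
  }
  if (all(status == 1 & time <= 1) || all(status == 0)) {
    stop("degenerate outcomes: cannot fit a survival model", call. = FALSE)
  }
  schema <- names(x)
  imp <- impute_medians(x)
  xi <- imp$x
  miss_cols <- names(x)[vapply(x, function(col) any(!is.finite(col)), logical(1))]
  for (nm in miss_cols) xi[[paste0(nm, "_missing")]] <- as.numeric(!is.finite(x[[nm]]))
  dat <- cbind(data.frame(.time = pmax(time, 1e-3), .status = status), xi)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(xi))))
  forest <- ranger::ranger(
    survival::Surv(.time, .status) ~ ., data = dat,
    num.trees = num_trees, mtry = mtry, min.node.size = min_node_size,
    seed = seed, num.threads = 1, verbose = FALSE)
  horizons <- prediction_horizons()
  oob_p <- oob_event_probs(forest, horizons)
  calibrators <- lapply(seq_along(horizons), function(k) {
    h <- horizons[k]
    y <- as.numeric(time <= h & status == 1)
    # patients censored at 240 are known alive at every horizon <= 240
    fit_calibrator(oob_p[, k], y)
  })
  structure(list(variant = variant, forest = forest, calibrators = calibrators,
                 feature_schema = schema, miss_cols = miss_cols,
                 medians = imp$medians, horizons = horizons,
                 train_meta = list(n = nrow(x), seed = seed,
                                   num_trees = num_trees, mtry = mtry,
                                   min_node_size = min_node_size)),
            class = "ttd_model")
}

# P(death <= h) per horizon from a ranger survival matrix
survival_to_event_probs <- function(surv, death_times, horizons) {
  if (is.null(dim(surv))) surv <- matrix(surv, nrow = 1)
  out <- sapply(horizons, function(h) {
    k <- findInterval(h, death_times)
    if (k == 0) rep(0, nrow(surv)) else 1 - surv[, k]
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  out
}

oob_event_probs <- function(forest, horizons) {
  survival_to_event_probs(forest$survival, forest$unique.death.times, horizons)
}

#' @export
print.ttd_model <- function(x, ...) {
  cat(sprintf("<ttd_model> variant=%s, n=%d, trees=%d, %d features\n",
              x$variant, x$train_meta$n, x$train_meta$num_trees,
              length(x$feature_schema)))
  invisible(x)
}

#' Predict calibrated death probabilities
#'
#' Applies the forest and the per-horizon calibration maps, then restores
#' monotonicity across horizons with the least-squares monotone projection
#' (pool-adjacent-violators) and clips to `[0, 1]`. The reporting triple
#' (30/60/120 min) is a projection of the 16-horizon vector.
#'
#' @param object a [fit_ttd_model()] result.
#' @param newdata data.frame of features (or a single named numeric vector)
#'   whose names match the model's feature schema.
#' @param ... unused.
#' @return for a single case a `survival_prediction` (fields `horizons_min`,
#'   `p_death`, `variant`); for several cases a list of them.
#' @export
predict.ttd_model <- function(object, newdata, ...) {
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    newdata <- as.data.frame(as.list(newdata))
  }
  missing_f <- setdiff(object$feature_schema, names(newdata))
  extra_f <- setdiff(names(newdata), object$feature_schema)
  if (length(missing_f) || length(extra_f)) {
    stop("feature schema mismatch; missing: [",
         paste(missing_f, collapse = ", "), "]; extra: [",
         paste(extra_f, collapse = ", "), "]", call. = FALSE)
  }
  newdata <- newdata[, object$feature_schema, drop = FALSE]
  xi <- impute_medians(newdata, object$medians)$x
  for (nm in object$miss_cols) {
    xi[[paste0(nm, "_missing")]] <- as.numeric(!is.finite(newdata[[nm]]))
  }
  pr <- predict(object$forest, data = xi, num.threads = 1)
  raw <- survival_to_event_probs(pr$survival, pr$unique.death.times,
                                 object$horizons)
  cal <- sapply(seq_along(object$horizons), function(k) {
    apply_calibrator(object$calibrators[[k]], raw[, k])
  })
  if (is.null(dim(cal))) cal <- matrix(cal, nrow = 1)
  # restore cross-horizon monotonicity by the L2 projection onto the
  # monotone cone (pool-adjacent-violators); unlike a running maximum this
  # does not systematically inflate the early horizons
  h_idx <- seq_along(object$horizons)
  cal <- t(apply(cal, 1, function(r) stats::isoreg(h_idx, r)$yf))
  cal <- pmin(pmax(cal, 0), 1)
  preds <- lapply(seq_len(nrow(cal)), function(i) {
    structure(list(horizons_min = object$horizons, p_death = cal[i, ],
                   variant = object$variant, assessed_at = NA_character_),
              class = "survival_prediction")
  })
  if (length(preds) == 1) preds[[1]] else preds
}

#' @export
print.survival_prediction <- function(x, ...) {
  tri <- x$p_death[match(c(30, 60, 120), x$horizons_min)]
  cat(sprintf("<survival_prediction> %s: P(death<=30)=%.2f, <=60=%.2f, <=120=%.2f\n",
              x$variant, tri[1], tri[2], tri[3]))
  invisible(x)
}

#' Concordance index of a risk score for observed survival
#'
#' @param time,status right-censored outcomes.
#' @param risk risk score (higher = expected earlier death).
#' @return Harrell's concordance index.
#' @export
concordance_index <- function(time, status, risk) {
  fit <- survival::concordance(survival::Surv(time, status) ~ risk,
                               reverse = TRUE)
  unname(fit$concordance)
}

#' Serial prediction stability
#'
#' For one patient's serial assessments under one model variant, the maximum
#' absolute change in predicted probability at each horizon across
#' assessment pairs.
#'
#' @param serial list of `survival_prediction` objects (>= 2), same variant.
#' @return named numeric vector of per-horizon maximum absolute changes.
#' @export
serial_stability <- function(serial) {
  if (length(serial) < 2) {
    stop("serial stability needs at least 2 assessments", call. = FALSE)
  }
  variants <- unique(vapply(serial, function(p) p$variant, character(1)))
  if (length(variants) != 1) {
    stop("all assessments must come from the same model variant", call. = FALSE)
  }
  pm <- do.call(rbind, lapply(serial, function(p) p$p_death))
  out <- apply(pm, 2, function(col) max(col) - min(col))
  names(out) <- paste0("h", serial[[1]]$horizons_min)
  out
}

#' Cohort summary of serial stability
#'
#' @param per_patient list over patients of [serial_stability()] vectors.
#' @return list with `per_horizon_median` (median across patients at each
#'   horizon) and `median_max_change` (median across patients of each
#'   patient's maximum change over horizons).
#' @export
cohort_stability <- function(per_patient) {
  m <- do.call(rbind, per_patient)
  list(per_horizon_median = apply(m, 2, stats::median),
       median_max_change = stats::median(apply(m, 1, max)))
}

#' Calibration-in-the-large
#'
#' Mean predicted probability versus empirical event frequency, with exact
#' binomial 95\% confidence intervals, per horizon.
#'
#' @param predictions list of `survival_prediction` objects (or a numeric
#'   matrix, cases by the 16 horizons).
#' @param ttd_min observed minutes to death per case.
#' @param horizons horizons to evaluate (default 30, 60, 120).
#' @return data.frame with `horizon_min`, `mean_predicted`,
#'   `observed_frequency`, `ci_lo`, `ci_hi`, `n`.
#' @export
evaluate_calibration <- function(predictions, ttd_min,
                                 horizons = c(30, 60, 120)) {
  if (is.list(predictions) && inherits(predictions[[1]], "survival_prediction")) {
    pm <- do.call(rbind, lapply(predictions, function(p) p$p_death))
    all_h <- predictions[[1]]$horizons_min
  } else {
    pm <- as.matrix(predictions)
    all_h <- prediction_horizons()
  }
  n <- nrow(pm)
  if (n < 20) stop("calibration evaluation needs at least 20 cases", call. = FALSE)
  if (length(ttd_min) != n) stop("predictions and outcomes differ in length",
                                 call. = FALSE)
  rows <- lapply(horizons, function(h) {
    k <- match(h, all_h)
    events <- sum(ttd_min <= h)
    ci <- stats::binom.test(events, n)$conf.int
    data.frame(horizon_min = h, mean_predicted = mean(pm[, k]),
               observed_frequency = events / n, ci_lo = ci[1], ci_hi = ci[2],
               n = n)
  })
  do.call(rbind, rows)
}

#' Physician prediction accuracy by horizon
#'
#' A categorical prediction is correct at horizon `h` when "predicted death
#' by `h`" (the category's upper bound is at most `h`) matches "actually
#' died by `h`".
#'
#' @param pps list of [physician_prediction()] objects.
#' @param ttd_min observed minutes to death, same length.
#' @param horizons horizons in minutes (default 30, 60, 120, 180, 360).
#' @return named numeric vector of fractions correct.
#' @export
physician_accuracy <- function(pps, ttd_min,
                               horizons = c(30, 60, 120, 180, 360)) {
  if (length(pps) != length(ttd_min)) {
    stop("predictions and outcomes differ in length", call. = FALSE)
  }
  bounds <- physician_category_bounds()
  pred_bound <- vapply(pps, function(p) {
    bounds[match(p$category, physician_categories())]
  }, numeric(1))
  out <- vapply(horizons, function(h) {
    mean((pred_bound <= h) == (ttd_min <= h))
  }, numeric(1))
  setNames(out, paste0("h", horizons))
}

#' Persist / restore a fitted model bundle
#'
#' The bundle carries a format version and an MD5 integrity hash; loading
#' verifies the hash.
#'
#' @param model a `ttd_model`.
#' @param path bundle path (`.rds`).
#' @return `path` (save) or the restored `ttd_model` (load).
#' @export
save_ttd_model <- function(model, path) {
  stopifnot(inherits(model, "ttd_model"))
  saveRDS(list(format = "ttd_model/1", model = model), path)
  hash <- unname(tools::md5sum(path))
  writeLines(hash, paste0(path, ".md5"))
  invisible(path)
}

#' @rdname save_ttd_model
#' @export
load_ttd_model <- function(path) {
  hash_file <- paste0(path, ".md5")
  if (file.exists(hash_file)) {
    expected <- readLines(hash_file, n = 1)
    actual <- unname(tools::md5sum(path))
    if (!identical(expected, actual)) {
      stop("model bundle integrity check failed for ", path, call. = FALSE)
    }
  }
  bundle <- readRDS(path)
  if (!identical(bundle$format, "ttd_model/1")) {
    stop("unrecognised model bundle format", call. = FALSE)
  }
  bundle$model
}
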