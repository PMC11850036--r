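#' Poincare plot dispersion (SD1, SD2)
#'
#' Embeds consecutive pairs \eqn{(x_i, x_{i+1})} of a beat-to-beat series in
#' the Poincare plane and returns the dispersion perpendicular to (SD1) and
#' along (SD2) the line of identity:
#' \deqn{SD1 = sd\{(x_{i+1} - x_i)/\sqrt{2}\}, \quad
#'       SD2 = sd\{(x_{i+1} + x_i)/\sqrt{2}\}.}
#' SD1 captures short-term (beat-to-beat) variability, SD2 longer-term
#' variability along the identity line.
#'
#' @param x numeric series (RR intervals in ms, or per-beat pressures in
#'   mm Hg); length at least 3.
#' @return named list with elements `sd1` and `sd2`, both non-negative.
#' @examples
#' poincare_metrics(c(800, 810, 790, 805, 795))
#' @export
poincare_metrics <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3 || anyNA(x)) {
    stop("poincare_metrics() needs at least 3 non-missing values", call. = FALSE)
  }
  a <- x[-1]
  b <- x[-length(x)]
  list(sd1 = stats::sd((a - b) / sqrt(2)), sd2 = stats::sd((a + b) / sqrt(2)))
}

# Exact white-noise expectation of the squared DFA1 fluctuation at box size n
# (linear detrending of the integrated series): E[F^2(n)] = sigma^2 (n^2-4)/(15 n).
# Used to remove the small-box detrending bias while preserving the asymptotic
# sqrt(n/15) law ("modified DFA").
dfa_wn_correction <- function(n) sqrt(1 - 4 / n^2)

dfa_fluctuation <- function(y, n) {
  # RMS fluctuation at box size n, forward and backward non-overlapping boxes,
  # per-box linear detrend. y is the integrated (profile) series.
  N <- length(y)
  nseg <- N %/% n
  if (nseg < 1) return(NA_real_)
  t <- seq_len(n)
  X <- cbind(1, t)
  M <- diag(n) - X %*% solve(crossprod(X), t(X))  # residual maker
  f2 <- numeric(0)
  for (yy in list(y, rev(y))) {
    Y <- matrix(yy[seq_len(nseg * n)], nrow = n)
    R <- M %*% Y
    f2 <- c(f2, colMeans(R^2))
  }
  sqrt(mean(f2))
}

#' Detrended fluctuation analysis with small-box bias correction
#'
#' Integrates the mean-centred series, detrends it linearly within
#' non-overlapping boxes of each size (forward and backward), and computes the
#' root-mean-square fluctuation \eqn{F(n)}. The raw fluctuation is divided by
#' the exact white-noise detrending bias \eqn{\sqrt{1 - 4/n^2}} so that
#' uncorrelated noise scales at exactly 0.5 down to the smallest boxes.
#'
#' `alpha1` is the least-squares slope of \eqn{\log F} versus \eqn{\log n}
#' over the short-scale boxes, `alpha2` the slope over the long-scale boxes,
#' and `auc` the trapezoidal area under the same log-log curve across all
#' scales (natural logs).
#'
#' @param x numeric series; length must be at least `4 * max(scales)`.
#' @param scales integer box sizes; default log-spaced 4..64 beats.
#' @param fit1,fit2 inclusive box-size ranges for the short- and long-scale
#'   slope fits (defaults 4–16 and 17–64 beats, conventional for beat series).
#' @return list with `alpha1`, `alpha2`, `auc`, `scales`, `fluctuation`.
#'   A zero-variance input yields all-`NA` metrics with a `degenerate` flag
#'   rather than an error.
#' @examples
#' set.seed(1)
#' dfa(rnorm(2000))$alpha1   # near 0.5 for white noise
#' @export
dfa <- function(x, scales = NULL, fit1 = c(4, 16), fit2 = c(17, 64)) {
  x <- as.numeric(x)
  if (is.null(scales)) {
    scales <- sort(unique(round(exp(seq(log(4), log(64), length.out = 14)))))
  }
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < 4)) stop("DFA box sizes must be >= 4", call. = FALSE)
  if (length(x) < 4 * max(scales)) {
    stop("series too short: DFA needs length >= 4 * max(scales)", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    return(list(alpha1 = NA_real_, alpha2 = NA_real_, auc = NA_real_,
                scales = scales, fluctuation = rep(NA_real_, length(scales)),
                degenerate = TRUE))
  }
  y <- cumsum(x - mean(x))
  f <- vapply(scales, function(n) dfa_fluctuation(y, n), numeric(1))
  f <- f / dfa_wn_correction(scales)
  slope_over <- function(rng) {
    keep <- scales >= rng[1] & scales <= rng[2]
    if (sum(keep) < 2) return(NA_real_)
    unname(coef(stats::lm(log(f[keep]) ~ log(scales[keep])))[2])
  }
  ln <- log(scales)
  lf <- log(f)
  auc <- sum(diff(ln) * (head(lf, -1) + tail(lf, -1)) / 2)
  list(alpha1 = slope_over(fit1), alpha2 = slope_over(fit2), auc = auc,
       scales = scales, fluctuation = f, degenerate = FALSE)
}

#' Grid (box) count occupancy of the Poincare embedding
#'
#' Consecutive pairs \eqn{(x_i, x_{i+1})} are binned on a `grid_n` by `grid_n`
#' grid over a fixed range; each pixel is marked visited (1) or not (0) and
#' the visited total divided by the number of pixels is returned — a
#' discretised Poincare occupancy in (0, 1].
#'
#' With `range = NULL` the data range is used; if that range is degenerate
#' (constant series) the embedding occupies a single pixel and `1/grid_n^2`
#' is returned.
#'
#' @param x numeric series, length at least 2.
#' @param grid_n pixels per axis (default 32).
#' @param range length-2 numeric fixed axis range, or `NULL` for data range.
#' @return fraction of visited pixels in (0, 1].
#' @examples
#' grid_count(rep(800, 10), grid_n = 32)          # 1/1024
#' @export
grid_count <- function(x, grid_n = 32L, range = NULL) {
  x <- as.numeric(x)
  grid_n <- as.integer(grid_n)
  if (length(x) < 2) stop("grid_count() needs at least 2 values", call. = FALSE)
  if (grid_n < 2) stop("grid_n must be >= 2", call. = FALSE)
  if (is.null(range)) range <- base::range(x)
  lo <- range[1]; hi <- range[2]
  if (!(hi > lo)) return(1 / grid_n^2)
  bin <- function(v) pmin(pmax(floor((v - lo) / (hi - lo) * grid_n) + 1L, 1L), grid_n)
  ix <- bin(x[-length(x)])
  iy <- bin(x[-1])
  length(unique((ix - 1L) * grid_n + iy)) / grid_n^2
}

#' Sample entropy
#'
#' Negative log of the conditional probability that two template vectors of
#' length `m` within Chebyshev tolerance `r` remain within tolerance at
#' length `m + 1`. Self-matches are excluded.
#'
#' @param x numeric series.
#' @param m template length (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.
#' @return sample entropy, or `NA` when no template matches exist (degenerate
#'   or very short input).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < m + 2 || !is.finite(r) || r <= 0) return(NA_real_)
  ab <- .sampen_counts(x, as.integer(m), r)
  if (ab[2] <= 0 || ab[1] <= 0) return(NA_real_)
  -log(ab[1] / ab[2])
}

#' Multiscale entropy area
#'
#' Coarse-grains the series by non-overlapping averaging at scales
#' `1..max_scale`, computes sample entropy at each scale with the tolerance
#' fixed from the scale-1 SD, and returns the trapezoidal area under the
#' entropy-versus-scale curve.
#'
#' @inheritParams sample_entropy
#' @param max_scale largest coarse-graining factor (default 5).
#' @return list with `entropies` (per scale) and `auc`.
#' @export
multiscale_entropy <- function(x, m = 2L, max_scale = 5L, r = 0.2 * stats::sd(x)) {
  x <- as.numeric(x)
  ent <- vapply(seq_len(max_scale), function(s) {
    if (s == 1) return(sample_entropy(x, m = m, r = r))
    k <- length(x) %/% s
    if (k < m + 2) return(NA_real_)
    cg <- colMeans(matrix(x[seq_len(k * s)], nrow = s))
    sample_entropy(cg, m = m, r = r)
  }, numeric(1))
  sc <- seq_len(max_scale)
  ok <- is.finite(ent)
  auc <- if (sum(ok) >= 2) {
    e <- ent[ok]; s <- sc[ok]
    sum(diff(s) * (head(e, -1) + tail(e, -1)) / 2)
  } else NA_real_
  list(entropies = ent, auc = auc)
}

#' Lomb-Scargle band powers for unevenly sampled beat series
#'
#' Computes the classical Lomb-Scargle periodogram of a beat-indexed series at
#' its (uneven) beat times and integrates the spectral density over the
#' standard low-frequency (0.04–0.15 Hz) and high-frequency (0.15–0.4 Hz)
#' bands, plus the total band (0.003–0.4 Hz). The periodogram is scaled so
#' that the integral over the full evaluated band approximates the series
#' variance, making band powers comparable across windows (units of `x`
#' squared).
#'
#' @param t sample times in seconds (strictly increasing).
#' @param x series values at `t`.
#' @param n_freq number of evaluation frequencies (default 256).
#' @return list with `lf`, `hf`, `total`, `lf_hf`, and the evaluated
#'   `freq`/`power` grids.
#' @export
lomb_band_powers <- function(t, x, n_freq = 256L) {
  t <- as.numeric(t); x <- as.numeric(x)
  stopifnot(length(t) == length(x))
  if (length(x) < 16 || stats::sd(x) == 0) {
    return(list(lf = NA_real_, hf = NA_real_, total = NA_real_,
                lf_hf = NA_real_, freq = numeric(0), power = numeric(0)))
  }
  xc <- x - mean(x)
  v <- stats::var(x)
  freq <- seq(0.003, 0.4, length.out = n_freq)
  w <- 2 * pi * freq
  M <- outer(w, t)                              # n_freq x n
  tau_w <- atan2(rowSums(sin(2 * M)), rowSums(cos(2 * M))) / 2
  A <- M - tau_w                                # w * (t - tau) per row
  ct <- cos(A); st <- sin(A)
  power <- 0.5 * ((as.numeric(ct %*% xc))^2 / rowSums(ct^2) +
                    (as.numeric(st %*% xc))^2 / rowSums(st^2))
  trapz <- function(f, p) sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
  total_raw <- trapz(freq, power)
  if (total_raw <= 0) {
    return(list(lf = NA_real_, hf = NA_real_, total = NA_real_,
                lf_hf = NA_real_, freq = freq, power = power))
  }
  dens <- power * (v / total_raw)   # normalise: full-band integral = variance
  band <- function(lo, hi) {
    keep <- freq >= lo & freq <= hi
    if (sum(keep) < 2) return(0)
    trapz(freq[keep], dens[keep])
  }
  lf <- band(0.04, 0.15); hf <- band(0.15, 0.4)
  list(lf = lf, hf = hf, total = band(0.003, 0.4),
       lf_hf = if (hf > 0) lf / hf else NA_real_, freq = freq, power = dens)
}

#' Split cleaned beats into fixed-size analysis windows
#'
#' Consecutive, non-overlapping windows of exactly `window_beats` accepted
#' beats. A window whose time span exceeds `max_span_min` minutes (severe
#' bradycardia or data gaps) is rejected with reason `"span"`. The trailing
#' partial window is reported separately and never analysed.
#'
#' @param beats a [beat_series] (cleaned; only accepted beats contribute).
#' @param window_beats beats per window (default 750).
#' @param max_span_min maximum permitted window span in minutes (default 60).
#' @return list with `windows` (list of beat-series subsets), `rejected`
#'   (list with `beats` and `reason`), and `partial` (trailing subset or
#'   `NULL`). Fewer than `window_beats` accepted beats in total yields zero
#'   windows with a warning.
#' @export
windowize <- function(beats, window_beats = 750L, max_span_min = 60) {
  stopifnot(inherits(beats, "beat_series"))
  acc <- beats[beats$quality == "accepted", , drop = FALSE]
  n <- nrow(acc)
  out <- list(windows = list(), rejected = list(), partial = NULL)
  if (n < window_beats) {
    warning(sprintf("only %d accepted beats; need %d for one window", n, window_beats),
            call. = FALSE)
    if (n > 0) out$partial <- acc
    return(out)
  }
  n_full <- n %/% window_beats
  for (k in seq_len(n_full)) {
    idx <- ((k - 1L) * window_beats + 1L):(k * window_beats)
    w <- acc[idx, , drop = FALSE]
    span_min <- (max(w$beat_time_s) - min(w$beat_time_s)) / 60
    if (span_min > max_span_min) {
      out$rejected[[length(out$rejected) + 1L]] <- list(beats = w, reason = "span")
    } else {
      out$windows[[length(out$windows) + 1L]] <- w
    }
  }
  if (n %% window_beats > 0) {
    out$partial <- acc[(n_full * window_beats + 1L):n, , drop = FALSE]
  }
  out
}

# fixed physiologic grid-count ranges per source series
grid_range_for_source <- function(source) {
  switch(source,
         rri = c(250, 3000),
         sbp = , dbp = , map = c(0, 250),
         stop("unknown source series: ", source, call. = FALSE))
}

# successive-difference threshold for the pNN-style fraction, per source
pnn_threshold_for_source <- function(source) {
  if (source == "rri") 50 else 2
}

#' Names of the 17-metric variability panel
#' @return character vector of length 17.
#' @export
variability_metric_names <- function() {
  c("sdnn", "rmssd", "pnn_frac", "cv", "sd1", "sd2", "sd1_sd2",
    "dfa_alpha1", "dfa_alpha2", "dfa_auc", "grid_count", "sampen",
    "mse_auc", "lf_power", "hf_power", "lf_hf", "total_power")
}

# compute the full 17-metric panel for one window and one source series
compute_metrics <- function(values, times, source, grid_n = 32L) {
  x <- as.numeric(values)
  out <- setNames(rep(NA_real_, 17L), variability_metric_names())
  if (length(x) < 3) return(out)
  dx <- diff(x)
  out["sdnn"] <- stats::sd(x)
  out["rmssd"] <- sqrt(mean(dx^2))
  out["pnn_frac"] <- mean(abs(dx) > pnn_threshold_for_source(source))
  out["cv"] <- if (mean(x) != 0) stats::sd(x) / mean(x) else NA_real_
  pc <- poincare_metrics(x)
  out["sd1"] <- pc$sd1
  out["sd2"] <- pc$sd2
  out["sd1_sd2"] <- if (pc$sd2 > 0) pc$sd1 / pc$sd2 else NA_real_
  if (length(x) >= 256) {
    d <- dfa(x)
    out["dfa_alpha1"] <- d$alpha1
    out["dfa_alpha2"] <- d$alpha2
    out["dfa_auc"] <- d$auc
  }
  out["grid_count"] <- grid_count(x, grid_n = grid_n,
                                  range = grid_range_for_source(source))
  r0 <- 0.2 * stats::sd(x)
  mse <- multiscale_entropy(x, m = 2L, max_scale = 5L, r = r0)
  out["sampen"] <- mse$entropies[1]   # scale 1 is sample entropy itself
  out["mse_auc"] <- mse$auc
  lsp <- lomb_band_powers(times, x)
  out["lf_power"] <- lsp$lf
  out["hf_power"] <- lsp$hf
  out["lf_hf"] <- lsp$lf_hf
  out["total_power"] <- lsp$total
  out
}

#' Variability panel over windows and source series
#'
#' Splits a cleaned beat series into 750-beat windows ([windowize()]) and
#' computes the 17-metric variability panel for each window and each
#' requested source series (RR interval, systolic, diastolic and mean
#' pressure), returning one tidy row per (window, source, metric).
#'
#' @param beats a cleaned [beat_series].
#' @param sources subset of `c("rri", "sbp", "dbp", "map")`.
#' @param window_beats,max_span_min see [windowize()].
#' @param grid_n grid-count resolution (default 32).
#' @return data.frame with columns `window_id`, `source`, `metric`, `value`,
#'   `start_s`, `end_s`, `n_beats`.
#' @export
metric_panel <- function(beats, sources = c("rri", "sbp", "dbp", "map"),
                         window_beats = 750L, max_span_min = 60, grid_n = 32L) {
  sources <- match.arg(sources, c("rri", "sbp", "dbp", "map"), several.ok = TRUE)
  wz <- windowize(beats, window_beats = window_beats, max_span_min = max_span_min)
  rows <- list()
  for (w_id in seq_along(wz$windows)) {
    w <- wz$windows[[w_id]]
    for (src in sources) {
      if (src == "rri") {
        vals <- w$rri_ms[-1]           # first beat of a window has no interval
        times <- w$beat_time_s[-1]
      } else {
        vals <- w[[paste0(src)]]
        times <- w$beat_time_s
      }
      m <- compute_metrics(vals, times, src, grid_n = grid_n)
      rows[[length(rows) + 1L]] <- data.frame(
        window_id = w_id, source = src, metric = names(m), value = unname(m),
        start_s = min(w$beat_time_s), end_s = max(w$beat_time_s),
        n_beats = nrow(w), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(window_id = integer(0), source = character(0),
                      metric = character(0), value = numeric(0),
                      start_s = numeric(0), end_s = numeric(0),
                      n_beats = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Summarise a variability panel for prediction
#'
#' Per-metric median over the most recent windows: only windows whose end
#' falls within `recent_min` minutes of the latest window end contribute, so
#' each prediction uses up to one hour of the freshest data.
#'
#' @param panel tidy panel from [metric_panel()].
#' @param recent_min recency horizon in minutes (default 60).
#' @return named numeric vector, names `<source>_<metric>`.
#' @export
variability_summary <- function(panel, recent_min = 60) {
  if (!nrow(panel)) return(setNames(numeric(0), character(0)))
  latest <- max(panel$end_s)
  keep <- panel$end_s >= latest - recent_min * 60
  p <- panel[keep, , drop = FALSE]
  key <- paste(p$source, p$metric, sep = "_")
  out <- tapply(p$value, key, function(v) stats::median(v, na.rm = TRUE))
  setNames(as.numeric(out), names(out))
}
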