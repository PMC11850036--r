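# Independent oracles, coded from the definitions rather than mirroring the
# package implementations.

# Poincare SD1/SD2 by explicitly rotating the (x_i, x_{i+1}) point cloud by
# 45 degrees and taking the SDs of the rotated coordinates.
oracle_poincare <- function(x) {
  pts <- rbind(x[-length(x)], x[-1])          # 2 x (n-1): (x_i, x_{i+1})
  th <- pi / 4
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  rp <- rot %*% pts
  # row 1: (x_i cos - x_{i+1} sin) = -(diff)/sqrt2 ; row 2: (sum)/sqrt2
  list(sd1 = sd(rp[1, ]), sd2 = sd(rp[2, ]))
}

# Grid occupancy by brute-force enumeration of the visited pixel set.
oracle_grid_count <- function(x, grid_n, range) {
  lo <- range[1]; hi <- range[2]
  seen <- matrix(FALSE, grid_n, grid_n)
  for (i in seq_len(length(x) - 1)) {
    ix <- min(max(floor((x[i] - lo) / (hi - lo) * grid_n) + 1, 1), grid_n)
    iy <- min(max(floor((x[i + 1] - lo) / (hi - lo) * grid_n) + 1, 1), grid_n)
    seen[ix, iy] <- TRUE
  }
  sum(seen) / grid_n^2
}

# Textbook DFA, written as an explicit per-box loop with lm() detrending,
# forward and backward boxes, the same exact white-noise bias correction,
# slope and trapezoid computed by hand.
oracle_dfa <- function(x, scales = NULL, fit1 = c(4, 16), fit2 = c(17, 64)) {
  if (is.null(scales)) {
    scales <- sort(unique(round(exp(seq(log(4), log(64), length.out = 14)))))
  }
  y <- cumsum(x - mean(x))
  fl <- sapply(scales, function(n) {
    nseg <- floor(length(y) / n)
    t <- seq_len(n)
    tc <- t - mean(t)
    f2 <- c()
    for (yy in list(y, rev(y))) {
      for (k in seq_len(nseg)) {
        seg <- yy[((k - 1) * n + 1):(k * n)]
        # explicit least-squares line fit and residuals
        slope <- sum(tc * seg) / sum(tc^2)
        res <- seg - mean(seg) - slope * tc
        f2 <- c(f2, mean(res^2))
      }
    }
    sqrt(mean(f2)) / sqrt((n^2 - 4) / (15 * n) / (n / 15))
  })
  fit_slope <- function(rng) {
    k <- scales >= rng[1] & scales <= rng[2]
    lx <- log(scales[k]); ly <- log(fl[k])
    sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  }
  ln <- log(scales); lf <- log(fl)
  auc <- 0
  for (i in seq_len(length(ln) - 1)) {
    auc <- auc + (ln[i + 1] - ln[i]) * (lf[i] + lf[i + 1]) / 2
  }
  list(alpha1 = fit_slope(fit1), alpha2 = fit_slope(fit2), auc = auc,
       fluctuation = fl)
}

# Brute-force per-interval pressure extraction with the same half-open
# [peak_i, peak_{i+1}) convention, via explicit time masks.
oracle_pressure_beats <- function(abp, rate_hz, beat_times_s) {
  tt <- (seq_along(abp) - 1) / rate_hz
  n <- length(beat_times_s)
  out <- data.frame(sbp = rep(NA_real_, n), dbp = NA_real_, map = NA_real_)
  for (i in seq_len(n - 1)) {
    mask <- tt >= beat_times_s[i] - 1e-9 & tt < beat_times_s[i + 1] - 1e-9
    if (!any(mask)) next
    out$sbp[i] <- max(abp[mask])
    out$dbp[i] <- min(abp[mask])
    out$map[i] <- mean(abp[mask])
  }
  out
}

# Dense Riemann measure of time below a cutoff for a piecewise-linear signal.
oracle_time_below <- function(time_s, value, cutoff, dt_s = 0.01) {
  tg <- seq(min(time_s), max(time_s), by = dt_s)
  vg <- approx(time_s, value, xout = tg)$y
  mean(vg < cutoff) * (max(time_s) - min(time_s)) / 60
}

# Synthetic single-lead ECG: Gaussian R spike at known beat times plus white
# noise at a requested SNR (dB); independent of the simulator's renderer.
make_test_ecg <- function(beat_times_s, dur_s, fs = 500, snr_db = Inf) {
  n <- round(dur_s * fs)
  ecg <- numeric(n)
  tpl_t <- seq(-0.03, 0.03, by = 1 / fs)
  tpl <- exp(-(tpl_t / 0.01)^2)
  half <- (length(tpl) - 1) %/% 2
  for (bt in beat_times_s) {
    c0 <- round(bt * fs) + 1
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1 & idx <= n
    ecg[idx[ok]] <- ecg[idx[ok]] + tpl[ok]
  }
  if (is.finite(snr_db)) {
    noise_sd <- sqrt(mean(ecg^2) / 10^(snr_db / 10))
    ecg <- ecg + rnorm(n, 0, noise_sd)
  }
  ecg
}

# match detected peaks to truth within a tolerance; returns sensitivity/PPV
peak_match_stats <- function(truth_s, detected_s, tol_s = 0.02) {
  if (!length(detected_s)) return(c(sens = 0, ppv = NA_real_))
  hits <- vapply(truth_s, function(t) any(abs(detected_s - t) <= tol_s),
                 logical(1))
  used <- vapply(detected_s, function(d) any(abs(truth_s - d) <= tol_s),
                 logical(1))
  c(sens = mean(hits), ppv = mean(used))
}

# represent a piecewise-constant signal exactly in the piecewise-linear
# engine: dense 5 s sampling within segments, transition instants duplicated
# a hair apart; times_min has one more entry than values (segment boundaries)
step_signal <- function(times_min, values) {
  eps <- 1e-12 / 60
  t <- numeric(0)
  v <- numeric(0)
  for (i in seq_along(values)) {
    seg <- seq(times_min[i] * 60, times_min[i + 1] * 60, by = 5) / 60
    if (i > 1) seg[1] <- seg[1] + eps
    t <- c(t, seg)
    v <- c(v, rep(values[i], length(seg)))
  }
  list(time_s = t * 60, value = v)
}
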