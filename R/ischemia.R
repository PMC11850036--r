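#' Warm-ischemia thresholds and organ eligibility windows
#'
#' Default cutoffs bracket common functional-warm-ischemia definitions
#' (e.g. SBP < 50 mm Hg, MAP < 60 mm Hg); they are configuration, not
#' authoritative clinical limits. Organ windows default to the conventional
#' 30 min–3 h DCD envelope with organ-specific interior values.
#'
#' @param map_mmHg strictly descending MAP cutoffs.
#' @param sbp_mmHg strictly descending SBP cutoffs.
#' @param spo2_pct strictly descending SpO2 cutoffs.
#' @param organ_windows_min named map organ -> maximum WLSM-to-death minutes.
#' @return list of class `ischemia_thresholds`.
#' @export
ischemia_thresholds <- function(map_mmHg = c(60, 50, 40, 30),
                                sbp_mmHg = c(80, 60, 50),
                                spo2_pct = c(80, 70, 60),
                                organ_windows_min = c(lungs = 60, liver = 60,
                                                      pancreas = 60,
                                                      kidneys = 120)) {
  for (nm in c("map_mmHg", "sbp_mmHg", "spo2_pct")) {
    v <- get(nm)
    if (length(v) && any(diff(v) >= 0)) {
      stop("cutoff list '", nm, "' must be strictly descending", call. = FALSE)
    }
  }
  if (any(organ_windows_min < 30 | organ_windows_min > 180)) {
    stop("organ windows must lie within [30, 180] minutes", call. = FALSE)
  }
  structure(list(map_mmHg = map_mmHg, sbp_mmHg = sbp_mmHg,
                 spo2_pct = spo2_pct, organ_windows_min = organ_windows_min),
            class = "ischemia_thresholds")
}

#' Determine the time of circulatory arrest from a vitals trajectory
#'
#' Death is operationalised as the first instant from which pulse pressure
#' (SBP − DBP) stays below 5 mm Hg continuously for `sustain_min` minutes
#' (default 5, representing the observation period of sustained
#' pulselessness). A shorter dip that recovers does not count.
#'
#' @param traj data.frame with `time_s`, `sbp`, `dbp` (from
#'   [generate_post_wlsm_vitals()] or monitor trends), starting at WLSM.
#' @param pp_mmHg pulse-pressure criterion (default 5 mm Hg).
#' @param sustain_min minutes the criterion must hold (default 5).
#' @return list with `death_time_min` (`NA` when no arrest is observed),
#'   `arrested` flag, and `truncated` flag (criterion never met within the
#'   record).
#' @export
determine_death_time <- function(traj, pp_mmHg = 5, sustain_min = 5) {
  need <- c("time_s", "sbp", "dbp")
  if (!all(need %in% names(traj))) {
    stop("trajectory must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  t_min <- (traj$time_s - traj$time_s[1]) / 60   # minutes from record start
  below <- (traj$sbp - traj$dbp) < pp_mmHg
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  for (k in which(r$values)) {
    dur <- t_min[ends[k]] - t_min[starts[k]]
    # a run truncated by the record end must still show the full sustain
    if (dur >= sustain_min) {
      return(list(death_time_min = t_min[starts[k]], arrested = TRUE,
                  truncated = FALSE))
    }
  }
  list(death_time_min = NA_real_, arrested = FALSE, truncated = TRUE)
}

# measure of {t in [a, b] : value(t) < cutoff} for a piecewise-linear signal,
# with linear interpolation at threshold crossings; returns minutes
segment_time_below <- function(t_min, v, cutoff) {
  n <- length(t_min)
  if (n < 2) return(0)
  t1 <- t_min[-n]; t2 <- t_min[-1]
  v1 <- v[-n]; v2 <- v[-1]
  dt <- t2 - t1
  both_below <- v1 < cutoff & v2 < cutoff
  both_above <- v1 >= cutoff & v2 >= cutoff
  cross <- !(both_below | both_above)
  out <- sum(dt[both_below])
  if (any(cross)) {
    frac_at <- (cutoff - v1[cross]) / (v2[cross] - v1[cross])
    below_first <- v1[cross] < cutoff
    frac_below <- ifelse(below_first, frac_at, 1 - frac_at)
    out <- out + sum(dt[cross] * frac_below)
  }
  out
}

#' Time spent below thresholds
#'
#' Duration (minutes) for which a piecewise-linear vital-sign signal lies
#' below each cutoff within an interval, with linear interpolation at
#' crossings so the result does not depend on the sampling rate. Sampling
#' gaps longer than `max_gap_s` are excluded from the measure and reported.
#'
#' @param time_s sample times in seconds.
#' @param value signal values.
#' @param cutoffs strictly descending cutoffs.
#' @param interval_s length-2 interval `[start, end]` in seconds (default the
#'   record span).
#' @param max_gap_s gap tolerance (default 30 s).
#' @return list with `minutes_below` (named by cutoff), `gap_min` (excluded
#'   time), and `first_crossing_min` (minutes to the first sustained
#'   crossing below each cutoff, `NA` if never).
#' @export
time_below_thresholds <- function(time_s, value, cutoffs,
                                  interval_s = range(time_s),
                                  max_gap_s = 30) {
  stopifnot(length(time_s) == length(value))
  if (length(cutoffs) > 1 && any(diff(cutoffs) >= 0)) {
    stop("cutoffs must be strictly descending", call. = FALSE)
  }
  keep <- time_s >= interval_s[1] - 1e-9 & time_s <= interval_s[2] + 1e-9
  t <- time_s[keep]; v <- value[keep]
  # clip to the interval by interpolating boundary values, so durations are
  # additive over adjacent sub-intervals whose split falls between samples
  if (length(t) >= 1) {
    for (edge in interval_s) {
      inside <- edge > min(time_s) && edge < max(time_s)
      if (inside && !any(abs(t - edge) < 1e-9)) {
        ve <- stats::approx(time_s, value, xout = edge)$y
        t <- c(t, edge); v <- c(v, ve)
      }
    }
    o <- order(t); t <- t[o]; v <- v[o]
  }
  if (length(t) < 2) {
    return(list(minutes_below = setNames(rep(0, length(cutoffs)),
                                         as.character(cutoffs)),
                gap_min = 0,
                first_crossing_min = setNames(rep(NA_real_, length(cutoffs)),
                                              as.character(cutoffs))))
  }
  gaps <- diff(t) > max_gap_s
  gap_min <- sum(diff(t)[gaps]) / 60
  # split into contiguous runs; gap segments contribute nothing
  run_id <- cumsum(c(0, as.integer(gaps)))
  t_min <- t / 60
  minutes <- vapply(cutoffs, function(cut) {
    sum(vapply(split(seq_along(t), run_id), function(idx) {
      segment_time_below(t_min[idx], v[idx], cut)
    }, numeric(1)))
  }, numeric(1))
  first_cross <- vapply(cutoffs, function(cut) {
    first_sustained_crossing(t_min, v, cut)
  }, numeric(1))
  list(minutes_below = setNames(minutes, as.character(cutoffs)),
       gap_min = gap_min,
       first_crossing_min = setNames(first_cross - t_min[1],
                                     as.character(cutoffs)))
}

# first instant (minutes, absolute) from which v < cutoff holds for at least
# sustain_min minutes; linear interpolation at the entry crossing
first_sustained_crossing <- function(t_min, v, cutoff, sustain_min = 0.5) {
  below <- v < cutoff
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    entry <- if (i0 == 1) t_min[1] else {
      # interpolate the crossing between sample i0-1 (>= cutoff) and i0
      t_min[i0 - 1] + (t_min[i0] - t_min[i0 - 1]) *
        (v[i0 - 1] - cutoff) / (v[i0 - 1] - v[i0])
    }
    if (t_min[i1] - entry >= sustain_min) return(entry)
  }
  NA_real_
}

#' Warm-ischemia summary of a post-WLSM record
#'
#' Determines the death time ([determine_death_time()]), measures the time
#' each signal (MAP, SBP, SpO2) spends below each configured cutoff between
#' WLSM and death, records first sustained crossing times, and flags
#' organ-specific eligibility (`ttd_min` within the organ's window).
#'
#' Missing SpO2 yields a pressure-only summary with `complete = FALSE`. If
#' no arrest is observed the summary covers the whole record with
#' `truncated = TRUE`.
#'
#' @param traj post-WLSM trajectory: data.frame with `time_s`, `sbp`, `dbp`,
#'   `map` and optionally `spo2`, starting at WLSM.
#' @param thresholds an [ischemia_thresholds()] object.
#' @return list of class `ischemia_summary`.
#' @export
ischemia_summary <- function(traj, thresholds = ischemia_thresholds()) {
  stopifnot(inherits(thresholds, "ischemia_thresholds"))
  need <- c("time_s", "sbp", "dbp", "map")
  if (!all(need %in% names(traj))) {
    stop("trajectory must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  t0 <- traj$time_s[1]                 # WLSM = record start; translation-safe
  dd <- determine_death_time(traj)
  end_min <- if (dd$arrested) dd$death_time_min
             else (max(traj$time_s) - t0) / 60
  interval <- t0 + c(0, end_min * 60)
  signals <- list(map = list(values = traj$map, cutoffs = thresholds$map_mmHg),
                  sbp = list(values = traj$sbp, cutoffs = thresholds$sbp_mmHg))
  complete <- TRUE
  if ("spo2" %in% names(traj)) {
    signals$spo2 <- list(values = traj$spo2, cutoffs = thresholds$spo2_pct)
  } else {
    complete <- FALSE
  }
  durations <- list(); first_crossing <- list()
  for (nm in names(signals)) {
    tb <- time_below_thresholds(traj$time_s, signals[[nm]]$values,
                                signals[[nm]]$cutoffs, interval_s = interval)
    durations[[nm]] <- tb$minutes_below
    first_crossing[[nm]] <- tb$first_crossing_min
  }
  ttd <- end_min
  organ_flags <- vapply(thresholds$organ_windows_min, function(w) ttd <= w,
                        logical(1))
  structure(list(wlsm_time_min = 0, death_time_min = dd$death_time_min,
                 ttd_min = ttd, arrested = dd$arrested,
                 truncated = dd$truncated, complete = complete,
                 durations = durations, first_crossing = first_crossing,
                 organ_flags = organ_flags, thresholds = thresholds),
            class = "ischemia_summary")
}

#' @export
print.ischemia_summary <- function(x, ...) {
  cat(sprintf("<ischemia_summary> ttd=%.1f min%s\n", x$ttd_min,
              if (x$truncated) " (no arrest observed; truncated)" else ""))
  for (nm in names(x$durations)) {
    d <- x$durations[[nm]]
    cat(sprintf("  %-5s %s\n", nm,
                paste(sprintf("<%s: %.1f min", names(d), d), collapse = ", ")))
  }
  flags <- paste(sprintf("%s=%s", names(x$organ_flags), x$organ_flags),
                 collapse = ", ")
  cat("  organ windows:", flags, "\n")
  invisible(x)
}

#' Flatten an ischemia summary to a tidy table
#'
#' @param summary an [ischemia_summary()].
#' @return data.frame with `signal`, `cutoff`, `minutes_below`,
#'   `first_crossing_min`.
#' @export
ischemia_table <- function(summary) {
  stopifnot(inherits(summary, "ischemia_summary"))
  rows <- lapply(names(summary$durations), function(nm) {
    d <- summary$durations[[nm]]
    data.frame(signal = nm, cutoff = as.numeric(names(d)),
               minutes_below = as.numeric(d),
               first_crossing_min = as.numeric(summary$first_crossing[[nm]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
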