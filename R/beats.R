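#' Construct a beat series
#'
#' Per-beat table aligned to R-peak times: RR interval to the previous beat
#' (`NA` for the first beat), systolic/diastolic/mean pressure over the
#' beat-to-beat interval `[peak_i, peak_{i+1})`, and a quality flag with
#' reason code set by [clean_beats()].
#'
#' @param beat_time_s strictly increasing peak times (s).
#' @param rri_ms RR intervals, `rri_ms[i]` = interval ending at beat `i`
#'   (`NA` at beat 1). Computed from `beat_time_s` when omitted.
#' @param sbp,dbp,map per-beat pressures (mm Hg), `NA` where unavailable.
#' @param quality,reason per-beat quality flag and reason code.
#' @return data.frame of class `beat_series`.
#' @export
beat_series <- function(beat_time_s, rri_ms = NULL, sbp = NA_real_,
                        dbp = NA_real_, map = NA_real_,
                        quality = "accepted", reason = "") {
  n <- length(beat_time_s)
  if (n < 2) stop("a beat series needs at least 2 beats", call. = FALSE)
  if (is.unsorted(beat_time_s, strictly = TRUE)) {
    stop("beat times must be strictly increasing", call. = FALSE)
  }
  if (is.null(rri_ms)) rri_ms <- c(NA_real_, diff(beat_time_s) * 1000)
  if (length(rri_ms) != n) stop("rri_ms must have one entry per beat", call. = FALSE)
  df <- data.frame(beat_time_s = beat_time_s, rri_ms = rri_ms,
                   sbp = rep_len(sbp, n), dbp = rep_len(dbp, n),
                   map = rep_len(map, n),
                   quality = rep_len(quality, n), reason = rep_len(reason, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("beat_series", "data.frame")
  df
}

#' Detect R peaks in a single-lead ECG
#'
#' Pan-Tompkins-style detector: band-pass (5–15 Hz Butterworth, zero-phase),
#' differentiate, square, integrate over a 150 ms moving window, then pick
#' integrated-energy maxima with an adaptive threshold (fraction of the
#' running median of recent peak energies) under a refractory period.
#' Detected peaks are refined to the local ECG maximum within ±80 ms.
#'
#' A flatline or degenerate signal yields an empty result with a
#' signal-quality warning, not an error.
#'
#' @param ecg numeric samples (mV).
#' @param rate_hz sampling rate; at least 10 s of signal required.
#' @param refractory_s minimum peak separation (default 0.2 s).
#' @param threshold_frac adaptive threshold as a fraction of the running
#'   median peak energy (default 0.4).
#' @return strictly increasing peak times in seconds.
#' @export
detect_r_peaks <- function(ecg, rate_hz, refractory_s = 0.2,
                           threshold_frac = 0.4) {
  ecg <- as.numeric(ecg)
  if (length(ecg) < 10 * rate_hz) {
    stop("need at least 10 s of ECG for peak detection", call. = FALSE)
  }
  if (stats::sd(ecg) == 0) {
    warning("flatline ECG: no peaks detectable", call. = FALSE)
    return(numeric(0))
  }
  bf <- signal::butter(2, c(5, 15) / (rate_hz / 2), type = "pass")
  bp <- signal::filtfilt(bf, ecg)
  d <- c(0, diff(bp))
  sq <- d^2
  w <- max(1L, round(0.15 * rate_hz))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  ref_n <- max(1L, round(refractory_s * rate_hz))

  # candidate local maxima of the integrated energy
  is_max <- integ > c(-Inf, integ[-length(integ)]) &
    integ >= c(integ[-1], -Inf)
  cand <- which(is_max & integ > 0.05 * max(integ))
  if (!length(cand)) {
    warning("no QRS energy above noise floor", call. = FALSE)
    return(numeric(0))
  }
  # adaptive threshold pass with refractory: accept a candidate if above
  # threshold_frac x running median of the last 8 accepted peak energies
  peaks <- integer(0)
  recent <- rep(stats::quantile(integ[cand], 0.75), 8)
  last <- -Inf
  for (i in cand) {
    thr <- threshold_frac * stats::median(recent)
    if (integ[i] < thr) next
    if (i - last < ref_n) {
      if (length(peaks) && integ[i] > integ[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- i   # keep the larger of two close peaks
        last <- i
      }
      next
    }
    peaks <- c(peaks, i)
    last <- i
    recent <- c(recent[-1], integ[i])
  }
  if (!length(peaks)) {
    warning("no peaks passed the adaptive threshold", call. = FALSE)
    return(numeric(0))
  }
  # refine to the raw-ECG maximum in a +/-80 ms neighbourhood
  half <- round(0.08 * rate_hz)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(length(ecg), i + half)
    as.integer(lo + which.max(ecg[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # collapse refinements that merged within the refractory period
  if (length(refined) > 1) {
    keep <- c(TRUE, diff(refined) >= ref_n)
    refined <- refined[keep]
  }
  (refined - 1) / rate_hz
}

#' Extract per-beat pressures from an arterial waveform
#'
#' For beat `i` over the half-open interval `[peak_i, peak_{i+1})`:
#' SBP = maximum, DBP = minimum, MAP = time average of the ABP samples in the
#' interval. The final beat has no closing interval and, like any beat whose
#' interval falls outside the record, is flagged missing (`NA`) rather than
#' silently dropped.
#'
#' @param abp numeric arterial-pressure samples (mm Hg).
#' @param rate_hz ABP sampling rate.
#' @param beat_times_s R-peak times from [detect_r_peaks()].
#' @return data.frame with `sbp`, `dbp`, `map`, and logical `missing`, one
#'   row per beat.
#' @export
extract_pressure_beats <- function(abp, rate_hz, beat_times_s) {
  abp <- as.numeric(abp)
  n_beat <- length(beat_times_s)
  out <- data.frame(sbp = rep(NA_real_, n_beat), dbp = NA_real_,
                    map = NA_real_, missing = TRUE)
  if (n_beat < 2) return(out)
  dur_s <- length(abp) / rate_hz
  for (i in seq_len(n_beat - 1)) {
    lo <- beat_times_s[i]; hi <- beat_times_s[i + 1]
    if (lo < 0 || hi > dur_s + 1e-9) next
    i0 <- floor(lo * rate_hz) + 1L
    i1 <- ceiling(hi * rate_hz)      # samples with index time in [lo, hi)
    i1 <- min(i1, length(abp))
    idx <- i0:i1
    tt <- (idx - 1) / rate_hz
    idx <- idx[tt >= lo - 1e-9 & tt < hi - 1e-9]
    if (!length(idx)) next
    seg <- abp[idx]
    out$sbp[i] <- max(seg); out$dbp[i] <- min(seg); out$map[i] <- mean(seg)
    out$missing[i] <- FALSE
  }
  out
}

#' Flag artifact beats
#'
#' Applies the configured artifact rules and sets `quality`/`reason` per
#' beat; values are never altered or removed, so the operation is idempotent.
#' Rules (defaults, all configurable):
#' \itemize{
#'   \item `rr_range`: RR outside `[250, 3000]` ms;
#'   \item `rr_jump`: successive RR change greater than 30\% of the previous
#'     interval;
#'   \item `pressure_order`: SBP not greater than DBP, or MAP outside
#'     `[DBP, SBP]`.
#' }
#'
#' @param raw a [beat_series].
#' @param rules list overriding `rr_min_ms`, `rr_max_ms`, `rr_jump_frac`,
#'   `max_artifact_frac`.
#' @return the beat series with updated `quality` and `reason`.
#'   More than `max_artifact_frac` (default 50\%) flagged beats raises a
#'   quality error advising the window be discarded.
#' @export
clean_beats <- function(raw, rules = list()) {
  stopifnot(inherits(raw, "beat_series"))
  cfg <- utils::modifyList(
    list(rr_min_ms = 250, rr_max_ms = 3000, rr_jump_frac = 0.3,
         max_artifact_frac = 0.5), rules)
  n <- nrow(raw)
  quality <- rep("accepted", n)
  reason <- rep("", n)
  rr <- raw$rri_ms
  bad_rr <- !is.na(rr) & (rr < cfg$rr_min_ms | rr > cfg$rr_max_ms)
  quality[bad_rr] <- "artifact"; reason[bad_rr] <- "rr_range"
  jump <- c(NA, abs(diff(rr)) > cfg$rr_jump_frac * abs(rr[-n]))
  bad_jump <- !is.na(jump) & jump & quality == "accepted"
  quality[bad_jump] <- "artifact"; reason[bad_jump] <- "rr_jump"
  bad_p <- !is.na(raw$sbp) & !is.na(raw$dbp) &
    (raw$sbp <= raw$dbp |
       (!is.na(raw$map) & (raw$map > raw$sbp | raw$map < raw$dbp)))
  quality[bad_p & quality == "accepted"] <- "artifact"
  reason[bad_p & reason == ""] <- "pressure_order"
  frac <- mean(quality == "artifact")
  if (frac > cfg$max_artifact_frac) {
    stop(sprintf(
      "quality error: %.0f%% of beats flagged as artifact; discard this window",
      100 * frac), call. = FALSE)
  }
  raw$quality <- quality
  raw$reason <- reason
  raw
}

#' Extract a cleaned beat series from a waveform record
#'
#' Convenience wrapper: R-peak detection on the ECG channel, per-beat
#' pressure extraction from ABP, artifact flagging.
#'
#' @param record a [waveform_record] with `ECG` and (optionally) `ABP`.
#' @param rules artifact rules for [clean_beats()].
#' @return a cleaned [beat_series].
#' @export
extract_beats <- function(record, rules = list()) {
  stopifnot(inherits(record, "waveform_record"))
  ecg <- record$channels$ECG
  if (is.null(ecg)) stop("record has no ECG channel", call. = FALSE)
  peaks <- detect_r_peaks(ecg$samples, ecg$rate_hz)
  if (length(peaks) < 2) stop("too few beats detected", call. = FALSE)
  if (!is.null(record$channels$ABP)) {
    ab <- record$channels$ABP
    pr <- extract_pressure_beats(ab$samples, ab$rate_hz, peaks)
    bs <- beat_series(peaks, sbp = pr$sbp, dbp = pr$dbp, map = pr$map)
  } else {
    bs <- beat_series(peaks)
  }
  clean_beats(bs, rules)
}

#' Write / read a beat series as CSV
#'
#' Columns `beat_time_s, rri_ms, sbp, dbp, map, quality, reason`.
#' @param beats a [beat_series].
#' @param path file path.
#' @return `path` (write) or a [beat_series] (read).
#' @export
write_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  utils::write.csv(as.data.frame(beats), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats
#' @export
read_beats <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("beat_time_s", "rri_ms", "sbp", "dbp", "map", "quality", "reason")
  if (!all(need %in% names(df))) {
    stop("format error: beat CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df$reason[is.na(df$reason)] <- ""
  out <- beat_series(df$beat_time_s, rri_ms = df$rri_ms, sbp = df$sbp,
                     dbp = df$dbp, map = df$map, quality = df$quality,
                     reason = df$reason)
  out
}
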