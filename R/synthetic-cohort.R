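#' Simulation parameters for a synthetic DCD cohort
#'
#' A single latent frailty (lognormal across patients) drives all three
#' feature families the predictor exploits: it scales down beat-to-beat
#' variability, worsens the clinical snapshot, and shortens the Weibull time
#' to death after withdrawal — the direction in which reduced variability
#' accompanies reduced physiological reserve and faster death.
#'
#' Defaults are anchored to typical adult DCD donor cohorts (median MAP
#' ~83 mm Hg, HR ~67/min, APACHE II ~24, GCS ~4, FiO2 ~30\%, median time to
#' death a few tens of minutes with ~70\% dying within 2 h).
#'
#' @param cohort_size number of patients (>= 1).
#' @param seed master seed; per-patient streams are derived from it.
#' @param frailty_meanlog,frailty_sdlog lognormal parameters of the latent
#'   frailty.
#' @param rr_mean_ms baseline RR interval (ms).
#' @param rr_base_sd_ms AR(1) innovation SD of the RR series at frailty 1;
#'   scaled by `frailty^-variability_exp`. Zero gives a perfectly periodic
#'   heart.
#' @param variability_exp exponent coupling frailty to variability (> 0
#'   means higher frailty, lower variability).
#' @param ar_phi AR(1) coefficient of the beat-to-beat series.
#' @param map_baseline_mmHg pre-WLSM mean arterial pressure.
#' @param pulse_pressure_mmHg pre-WLSM pulse pressure.
#' @param press_base_sd_mmHg AR(1) innovation SD of per-beat MAP at frailty 1.
#' @param ttd_shape,ttd_scale0_min,ttd_frailty_exp Weibull time-to-death
#'   model: shape, scale at frailty 1 (min), and the exponent by which the
#'   scale shrinks with frailty (`scale = scale0 / frailty^exp`).
#' @param decline_rate_per_min post-WLSM exponential MAP decay constant at
#'   frailty 1 (1/min); multiplied by frailty.
#' @param arrest_plateau_mmHg MAP plateau approached after arrest.
#' @param noise_sd additive ECG waveform noise SD (mV).
#' @param physician_error_sd SD (in log-frailty units) of the simulated
#'   physician's noisy assessment of the patient's state; their category is
#'   the implied median survival of that assessment.
#' @param pre_wlsm_min minutes of pre-WLSM recording (>= 30).
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(cohort_size = 27L,
                       seed = 1L,
                       frailty_meanlog = 0,
                       frailty_sdlog = 0.6,
                       rr_mean_ms = 900,
                       rr_base_sd_ms = 35,
                       variability_exp = 0.8,
                       ar_phi = 0.85,
                       map_baseline_mmHg = 83,
                       pulse_pressure_mmHg = 45,
                       press_base_sd_mmHg = 6,
                       ttd_shape = 1.1,
                       ttd_scale0_min = 70,
                       ttd_frailty_exp = 1.2,
                       decline_rate_per_min = 0.05,
                       arrest_plateau_mmHg = 8,
                       noise_sd = 0.02,
                       physician_error_sd = 0.7,
                       pre_wlsm_min = 32) {
  p <- as.list(environment())
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (p$cohort_size < 1) stop("cohort_size must be >= 1", call. = FALSE)
  if (p$seed < 1 || p$seed >= 2^31) stop("seed must be in [1, 2^31)", call. = FALSE)
  pos <- c("frailty_sdlog", "rr_mean_ms", "map_baseline_mmHg",
           "pulse_pressure_mmHg", "ttd_shape", "ttd_scale0_min",
           "decline_rate_per_min", "arrest_plateau_mmHg")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop("sim_params: '", nm, "' must be positive", call. = FALSE)
    }
  }
  nonneg <- c("rr_base_sd_ms", "press_base_sd_mmHg", "noise_sd",
              "physician_error_sd", "variability_exp", "ttd_frailty_exp")
  for (nm in nonneg) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop("sim_params: '", nm, "' must be non-negative", call. = FALSE)
    }
  }
  if (abs(p$ar_phi) >= 1) stop("ar_phi must lie in (-1, 1)", call. = FALSE)
  if (p$pre_wlsm_min < 30) stop("pre_wlsm_min must be >= 30", call. = FALSE)
  invisible(TRUE)
}

#' Prediction horizons (minutes)
#'
#' The 16 15-minute horizons, 15 to 240 min after WLSM.
#' @return integer vector.
#' @export
prediction_horizons <- function() seq(15L, 240L, by = 15L)

# deterministic per-patient seed stream derived from the cohort seed
patient_seed_for <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483629) + 1L
}

rr_sd_for_frailty <- function(params, frailty) {
  params$rr_base_sd_ms * frailty^(-params$variability_exp)
}

ttd_scale_for_frailty <- function(params, frailty) {
  params$ttd_scale0_min / frailty^params$ttd_frailty_exp
}

ar1 <- function(n, mean, phi, innov_sd) {
  if (innov_sd == 0) return(rep(mean, n))
  x <- numeric(n)
  x[1] <- mean + rnorm(1, 0, innov_sd / sqrt(1 - phi^2))
  eps <- rnorm(n - 1, 0, innov_sd)
  for (i in 2:n) x[i] <- mean + phi * (x[i - 1] - mean) + eps[i - 1]
  x
}

# ground-truth pre-WLSM beat series: RR AR(1), per-beat MAP and pulse
# pressure AR(1), SBP/DBP derived by the MAP = DBP + PP/3 convention
simulate_pre_wlsm_beats <- function(params, frailty) {
  dur_s <- params$pre_wlsm_min * 60
  n <- ceiling(dur_s / (params$rr_mean_ms / 1000)) + 10L
  rr_sd <- rr_sd_for_frailty(params, frailty)
  rr <- ar1(n, params$rr_mean_ms, params$ar_phi, rr_sd)
  rr <- pmin(pmax(rr, 300), 2500)
  bt <- cumsum(rr) / 1000
  bt <- bt[bt <= dur_s]
  bt <- round(bt * 500) / 500   # align to the ECG sample grid (2 ms)
  rr <- c(NA, diff(bt) * 1000)
  nb <- length(bt)
  # smooth beat-to-beat pressure dynamics: high AR coefficient with the
  # innovation scaled to keep the marginal SD at the frailty-adjusted value
  phi_p <- 0.98
  p_sd <- params$press_base_sd_mmHg * frailty^(-params$variability_exp)
  innov <- p_sd * sqrt(1 - phi_p^2)
  map <- ar1(nb, params$map_baseline_mmHg, phi_p, innov)
  pp <- pmax(ar1(nb, params$pulse_pressure_mmHg, phi_p, innov / 2), 10)
  beat_series(bt, rri_ms = c(NA, rr[-1]),
              sbp = map + 2 * pp / 3, dbp = map - pp / 3, map = map)
}

simulate_clinical <- function(params, frailty) {
  lf <- log(frailty)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  clinical_snapshot(
    pip_cmH2O = clamp(20 + 3 * lf + rnorm(1, 0, 3), 5, 60),
    peep_cmH2O = clamp(6 + 1.5 * lf + rnorm(1, 0, 1.5), 0, 20),
    gcs = as.integer(clamp(round(4 - 2 * lf + rnorm(1, 0, 1.2)), 3, 15)),
    gag_absent = runif(1) < plogis(1.7 + 1.2 * lf),
    cough_absent = runif(1) < plogis(0.1 + 1.2 * lf),
    pupil_absent = runif(1) < plogis(-0.1 + 1.2 * lf),
    ph = clamp(7.35 - 0.05 * lf + rnorm(1, 0, 0.04), 6.8, 7.7),
    fio2_frac = clamp(0.30 + 0.15 * lf + rnorm(1, 0, 0.08), 0.21, 1.0),
    apache2 = as.integer(clamp(round(24 + 7 * lf + rnorm(1, 0, 3.5)), 0, 71)),
    lactate_mmol_L = exp(log(2.0) + 0.8 * lf + rnorm(1, 0, 0.35)),
    spont_rr_per_min = clamp(16 - 3 * lf + rnorm(1, 0, 3), 0, 40),
    pco2_mmHg = clamp(42 + 4 * lf + rnorm(1, 0, 5), 20, 90),
    rank_circ = as.integer(clamp(round(2 + lf + rnorm(1, 0, 1)), 0, 8)),
    rank_analg = as.integer(clamp(round(3 + 0.5 * lf + rnorm(1, 0, 1)), 0, 8)),
    rank_sedat = as.integer(clamp(round(3 + 0.5 * lf + rnorm(1, 0, 1)), 0, 8)),
    on_pressors = runif(1) < plogis(-1.45 + 0.5 * lf),
    timestamp = "pre-WLSM")
}

physician_category_bounds <- function() c(30, 60, 120, 180, 360, Inf)

# The simulated physician is future-blind: they assess the patient's state
# (a noisy read of the latent frailty), convert it to the implied median
# survival, and report the matching category. Stated confidence tracks the
# (unobservable) assessment error only loosely.
simulate_physician <- function(params, frailty) {
  e <- rnorm(1, 0, params$physician_error_sd)
  f_hat <- exp(log(frailty) + e)
  med_ttd <- ttd_scale_for_frailty(params, f_hat) *
    log(2)^(1 / params$ttd_shape)
  cat_i <- which(med_ttd <= physician_category_bounds())[1]
  score <- -0.5 * abs(e) + rnorm(1)
  conf <- if (score > 0) "high" else if (score > -1.2) "moderate" else "low"
  physician_prediction(category = physician_categories()[cat_i],
                       confidence = conf)
}

#' Simulate one dying patient
#'
#' Draws the latent frailty, the pre-WLSM beat-level physiology, the clinical
#' snapshot, the physician prediction and the post-WLSM ground truth from one
#' deterministic per-patient stream. Identical `(params, patient_seed)`
#' reproduce the patient exactly.
#'
#' @param params a [sim_params()] object.
#' @param patient_seed positive integer stream seed.
#' @param waveforms render full-rate waveform channels (ECG 500 Hz, ABP
#'   125 Hz, PLETH 125 Hz, RESP 62.5 Hz)? Beat-level truth is always kept;
#'   the rendering is deterministic either way.
#' @param frailty optional fixed frailty, overriding the random draw (used
#'   for stratified experiments).
#' @return list of class `dcd_patient` with elements `id`, `seed`, `truth`
#'   (frailty, `true_ttd_min`, `died_within` over the 16 horizons),
#'   `beats_true` (a [beat_series]), `clinical`, `physician`, and `record`
#'   (a [waveform_record] or `NULL`).
#' @export
simulate_patient <- function(params, patient_seed, waveforms = TRUE,
                             frailty = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (patient_seed < 1 || patient_seed >= 2^31) {
    stop("patient_seed must be in [1, 2^31)", call. = FALSE)
  }
  set.seed(patient_seed)
  if (is.null(frailty)) {
    frailty <- stats::rlnorm(1, params$frailty_meanlog, params$frailty_sdlog)
  }
  true_ttd <- stats::rweibull(1, shape = params$ttd_shape,
                              scale = ttd_scale_for_frailty(params, frailty))
  true_ttd <- max(true_ttd, 1)   # death cannot precede withdrawal
  horizons <- prediction_horizons()
  truth <- list(frailty = frailty, true_ttd_min = true_ttd,
                died_within = setNames(true_ttd <= horizons,
                                       paste0("h", horizons)))
  beats <- simulate_pre_wlsm_beats(params, frailty)
  clinical <- simulate_clinical(params, frailty)
  physician <- simulate_physician(params, frailty)
  record <- if (waveforms) render_waveform(beats, params, seed = patient_seed + 500009L)
            else NULL
  structure(list(id = sprintf("P%09d", patient_seed), seed = patient_seed,
                 truth = truth, beats_true = beats, clinical = clinical,
                 physician = physician, record = record),
            class = "dcd_patient")
}

#' Render full-rate waveforms from a ground-truth beat series
#'
#' ECG: a fixed QRS template (smooth R spike with Q and S deflections) placed
#' at each beat time on the 500 Hz grid plus white noise. ABP: a pulse-wave
#' template (flat-top systolic peak, exponential diastolic decay with a
#' dicrotic bump, returning to diastolic pressure at the next beat) scaled
#' between the per-beat DBP and SBP at 125 Hz. PLETH mirrors the normalised
#' pulse wave; RESP is a 15/min sinusoid.
#'
#' @param beats ground-truth [beat_series].
#' @param params [sim_params()] (for noise amplitude and record span).
#' @param seed RNG seed for the additive noise.
#' @return a [waveform_record] with `wlsm_time` at the record end.
#' @export
render_waveform <- function(beats, params, seed = 1L) {
  set.seed(seed)
  dur_s <- params$pre_wlsm_min * 60
  fs_ecg <- 500; fs_abp <- 125; fs_resp <- 62.5
  n_ecg <- round(dur_s * fs_ecg)
  ecg <- rnorm(n_ecg, 0, params$noise_sd)
  tpl_t <- seq(-0.04, 0.04, by = 1 / fs_ecg)
  qrs <- 1.0 * exp(-(tpl_t / 0.005)^2) -
    0.15 * exp(-((tpl_t + 0.025) / 0.01)^2) -
    0.25 * exp(-((tpl_t - 0.025) / 0.01)^2)
  half <- (length(qrs) - 1L) %/% 2L
  centers <- round(beats$beat_time_s * fs_ecg) + 1L
  for (c0 in centers) {
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1L & idx <= n_ecg
    ecg[idx[ok]] <- ecg[idx[ok]] + qrs[ok]
  }
  n_abp <- round(dur_s * fs_abp)
  abp <- rep(beats$dbp[1], n_abp)
  pleth <- numeric(n_abp)
  bt <- beats$beat_time_s
  for (i in seq_len(nrow(beats) - 1L)) {
    # samples k with bt[i] <= (k-1)/fs < bt[i+1]  (tolerant of fp jitter)
    i0 <- as.integer(ceiling(bt[i] * fs_abp - 1e-6)) + 1L
    i1 <- min(as.integer(ceiling(bt[i + 1] * fs_abp - 1e-6)), n_abp)
    if (i1 < i0) next
    tt <- ((i0:i1) - 1) / fs_abp
    phi <- (tt - bt[i]) / (bt[i + 1] - bt[i])
    shape <- pulse_wave_shape(pmin(pmax(phi, 0), 1))
    abp[i0:i1] <- beats$dbp[i] + (beats$sbp[i] - beats$dbp[i]) * shape
    pleth[i0:i1] <- shape
  }
  abp <- abp + rnorm(n_abp, 0, params$noise_sd * 5)
  n_resp <- round(dur_s * fs_resp)
  resp <- sin(2 * pi * 0.25 * (seq_len(n_resp) - 1) / fs_resp) +
    rnorm(n_resp, 0, params$noise_sd)
  waveform_record(
    list(ECG = list(samples = ecg, rate_hz = fs_ecg),
         ABP = list(samples = abp, rate_hz = fs_abp),
         PLETH = list(samples = pleth, rate_hz = fs_abp),
         RESP = list(samples = resp, rate_hz = fs_resp)),
    wlsm_time = dur_s,
    meta = list(synthetic = TRUE))
}

# arterial pulse shape on beat phase [0, 1]: smooth upstroke, flat systolic
# top (robust SBP sampling), exponential decay with dicrotic bump, exact
# return to 0 at the next beat (robust DBP sampling)
pulse_wave_shape <- function(phi) {
  out <- numeric(length(phi))
  up <- phi < 0.10
  out[up] <- 0.5 * (1 - cos(pi * phi[up] / 0.10))
  top <- phi >= 0.10 & phi <= 0.16
  out[top] <- 1
  dec <- phi > 0.16
  tail1 <- exp(-3 * (1 - 0.16))
  raw <- exp(-3 * (phi[dec] - 0.16)) + 0.06 * exp(-((phi[dec] - 0.45) / 0.05)^2)
  out[dec] <- pmin((raw - tail1) / (1 - tail1), 1)
  pmax(out, 0)
}

#' Simulate a cohort of dying patients
#'
#' `cohort_size` patients with independent, deterministically derived
#' per-patient seed streams; identical `(params, seed)` reproduce the cohort
#' exactly.
#'
#' @param params a [sim_params()] object.
#' @param waveforms render full-rate waveforms per patient (default `FALSE`:
#'   cohort-scale work consumes the beat-level series; rendering remains
#'   available per patient via [render_waveform()]).
#' @return list of [simulate_patient()] results, class `dcd_cohort`.
#' @export
simulate_cohort <- function(params, waveforms = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  out <- lapply(seq_len(params$cohort_size), function(i) {
    simulate_patient(params, patient_seed_for(params$seed, i),
                     waveforms = waveforms)
  })
  class(out) <- c("dcd_cohort", "list")
  out
}

#' Re-sample a patient's pre-WLSM beat series for a serial assessment
#'
#' Draws a fresh realisation of the beat-to-beat process with the same
#' latent frailty (the patient's state), emulating a repeated recording on a
#' later occasion before WLSM. Deterministic per `(patient, assessment)`.
#'
#' @param params a [sim_params()] object.
#' @param patient a `dcd_patient`.
#' @param assessment assessment index (1 = the original series).
#' @return a [beat_series].
#' @export
simulate_assessment_beats <- function(params, patient, assessment) {
  stopifnot(inherits(patient, "dcd_patient"))
  if (assessment == 1) return(patient$beats_true)
  set.seed(patient$seed %% 2000000000L + 104729L * as.integer(assessment))
  simulate_pre_wlsm_beats(params, patient$truth$frailty)
}

#' Post-WLSM vitals trajectory
#'
#' Deterministic decline model from the patient's ground truth: MAP decays
#' exponentially at `decline_rate_per_min * frailty` toward the arrest
#' plateau; pulse pressure decays exponentially so that it reaches exactly
#' 5 mm Hg at the true time of death and keeps falling; SBP/DBP follow the
#' MAP = DBP + PP/3 convention; SpO2 declines sigmoidally. The trajectory
#' extends 10 min past arrest.
#'
#' @param truth ground-truth list from [simulate_patient()] (`$truth`), or a
#'   `dcd_patient`.
#' @param params a [sim_params()] object.
#' @param step_s sampling step in seconds (> 0, default 1).
#' @return data.frame with `time_s`, `sbp`, `dbp`, `map`, `spo2`.
#' @export
generate_post_wlsm_vitals <- function(truth, params, step_s = 1) {
  if (inherits(truth, "dcd_patient")) truth <- truth$truth
  if (is.null(truth$true_ttd_min) || is.null(truth$frailty)) {
    stop("ground truth with true_ttd_min and frailty is required", call. = FALSE)
  }
  if (!is.finite(step_s) || step_s <= 0) stop("step_s must be > 0", call. = FALSE)
  ttd <- truth$true_ttd_min
  f <- truth$frailty
  t_min <- seq(0, ttd + 10, by = step_s / 60)
  map0 <- params$map_baseline_mmHg
  plateau <- params$arrest_plateau_mmHg
  map <- plateau + (map0 - plateau) * exp(-params$decline_rate_per_min * f * t_min)
  pp0 <- params$pulse_pressure_mmHg
  pp <- pp0 * exp(-t_min * log(pp0 / 5) / ttd)
  spo2_floor <- 15
  spo2 <- spo2_floor + (97.5 - spo2_floor) / (1 + exp((t_min - 0.5 * ttd) / (ttd / 8)))
  data.frame(time_s = t_min * 60,
             sbp = map + 2 * pp / 3,
             dbp = map - pp / 3,
             map = map,
             spo2 = spo2)
}

#' Write a simulated cohort to disk
#'
#' One directory per patient holding `beats.csv` (ground-truth beat series),
#' `clinical.json`, `physician.json`, `truth.json` and, when waveforms were
#' rendered, `waveform.csv` in the long CSV dialect; plus a cohort
#' `manifest.csv`.
#'
#' @param cohort a `dcd_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dcd_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(p) {
    pd <- file.path(dir, p$id)
    dir.create(pd, showWarnings = FALSE)
    write_beats(p$beats_true, file.path(pd, "beats.csv"))
    jsonlite::write_json(unclass(p$clinical), file.path(pd, "clinical.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(p$physician), file.path(pd, "physician.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(p$truth, file.path(pd, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(p$record)) write_waveform(p$record, file.path(pd, "waveform.csv"))
    data.frame(id = p$id, seed = p$seed, frailty = p$truth$frailty,
               true_ttd_min = p$truth$true_ttd_min,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir cohort directory.
#' @return a `dcd_cohort` (without waveform records).
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(man)), function(i) {
    pd <- file.path(dir, man$id[i])
    truth <- jsonlite::read_json(file.path(pd, "truth.json"), simplifyVector = TRUE)
    truth$died_within <- as.logical(truth$died_within)
    names(truth$died_within) <- paste0("h", prediction_horizons())
    cl <- jsonlite::read_json(file.path(pd, "clinical.json"), simplifyVector = TRUE)
    ph <- jsonlite::read_json(file.path(pd, "physician.json"), simplifyVector = TRUE)
    structure(list(id = man$id[i], seed = man$seed[i], truth = truth,
                   beats_true = read_beats(file.path(pd, "beats.csv")),
                   clinical = do.call(clinical_snapshot, cl),
                   physician = physician_prediction(ph$category, ph$confidence),
                   record = NULL),
              class = "dcd_patient")
  })
  class(out) <- c("dcd_cohort", "list")
  out
}
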