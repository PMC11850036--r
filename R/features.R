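#' Clinical snapshot of a DCD candidate
#'
#' Ventilatory pressures, neurologic examination, gas exchange, severity
#' scores and ranked vasoactive/analgesic/sedative dose scores recorded
#' before withdrawal.
#'
#' @param pip_cmH2O peak inspiratory pressure.
#' @param peep_cmH2O positive end-expiratory pressure.
#' @param gcs Glasgow Coma Scale, 3–15.
#' @param gag_absent,cough_absent,pupil_absent absent brainstem reflexes.
#' @param ph arterial pH.
#' @param fio2_frac inspired oxygen fraction, 0.21–1.
#' @param apache2 APACHE II score.
#' @param lactate_mmol_L arterial lactate.
#' @param spont_rr_per_min spontaneous respiratory rate.
#' @param pco2_mmHg arterial CO2 tension.
#' @param rank_circ,rank_analg,rank_sedat ranked total dose scores
#'   (non-negative).
#' @param on_pressors on vasopressors/inotropes.
#' @param timestamp free-form assessment time label.
#' @return list of class `clinical_snapshot`.
#' @export
clinical_snapshot <- function(pip_cmH2O, peep_cmH2O, gcs, gag_absent,
                              cough_absent, pupil_absent, ph, fio2_frac,
                              apache2, lactate_mmol_L, spont_rr_per_min,
                              pco2_mmHg, rank_circ, rank_analg, rank_sedat,
                              on_pressors, timestamp = "") {
  if (gcs < 3 || gcs > 15) stop("gcs must be in [3, 15]", call. = FALSE)
  if (fio2_frac < 0.21 || fio2_frac > 1) {
    stop("fio2_frac must be in [0.21, 1]", call. = FALSE)
  }
  if (min(rank_circ, rank_analg, rank_sedat) < 0) {
    stop("dose ranks must be non-negative", call. = FALSE)
  }
  structure(list(pip_cmH2O = pip_cmH2O, peep_cmH2O = peep_cmH2O, gcs = gcs,
                 gag_absent = isTRUE(gag_absent),
                 cough_absent = isTRUE(cough_absent),
                 pupil_absent = isTRUE(pupil_absent), ph = ph,
                 fio2_frac = fio2_frac, apache2 = apache2,
                 lactate_mmol_L = lactate_mmol_L,
                 spont_rr_per_min = spont_rr_per_min, pco2_mmHg = pco2_mmHg,
                 rank_circ = rank_circ, rank_analg = rank_analg,
                 rank_sedat = rank_sedat, on_pressors = isTRUE(on_pressors),
                 timestamp = timestamp),
            class = "clinical_snapshot")
}

#' Physician time-to-death categories
#'
#' The closed prediction set: death within 0.5, 1, 2, 3, 6, or more than 6
#' hours of withdrawal.
#' @return character vector of the six category labels.
#' @export
physician_categories <- function() {
  c("<=0.5h", "<=1h", "<=2h", "<=3h", "<=6h", ">6h")
}

# ordinal midpoint minutes used when the category enters a feature vector
physician_category_midpoints <- function() c(30, 60, 120, 180, 360, 480)

#' Physician prediction of time to death
#'
#' @param category one of [physician_categories()].
#' @param confidence `"low"`, `"moderate"` or `"high"`.
#' @return list of class `physician_prediction`.
#' @export
physician_prediction <- function(category, confidence) {
  category <- match.arg(category, physician_categories())
  confidence <- match.arg(confidence, c("low", "moderate", "high"))
  structure(list(category = category, confidence = confidence),
            class = "physician_prediction")
}

clinical_feature_names <- function() {
  c("pip_cmH2O", "peep_cmH2O", "gcs", "gag_absent", "cough_absent",
    "pupil_absent", "ph", "fio2_frac", "apache2", "lactate_mmol_L",
    "spont_rr_per_min", "pco2_mmHg", "rank_circ", "rank_analg",
    "rank_sedat", "on_pressors")
}

#' Ordered feature schema for a model variant
#'
#' @param variant `"variability"`, `"clinical"`, `"physician"` or
#'   `"combined"`.
#' @param sources variability source series included (default RRI, SBP, DBP).
#' @return character vector of feature names in canonical order.
#' @export
feature_schema <- function(variant = c("variability", "clinical", "physician",
                                       "combined"),
                           sources = c("rri", "sbp", "dbp")) {
  variant <- match.arg(variant)
  vv <- as.vector(t(outer(sources, variability_metric_names(), paste, sep = "_")))
  switch(variant,
         variability = vv,
         clinical = clinical_feature_names(),
         physician = c("phys_ttd_min", "phys_confidence"),
         combined = c(vv, clinical_feature_names(),
                      "phys_ttd_min", "phys_confidence"))
}

#' Assemble a model feature vector
#'
#' Encodes the blocks a variant requires into one fixed-order numeric
#' vector: variability as the per-metric summary from
#' [variability_summary()] (median over the most recent hour of windows),
#' clinical booleans as 0/1, the physician category as its ordinal midpoint
#' in minutes (30, 60, 120, 180, 360, 480) and confidence as 1–3.
#'
#' @param vv named variability summary (required by `variability` and
#'   `combined`).
#' @param cs a [clinical_snapshot()] (required by `clinical` and `combined`).
#' @param pp a [physician_prediction()] (required by `physician` and
#'   `combined`).
#' @param variant model variant.
#' @param sources variability sources in the schema.
#' @return named numeric vector matching [feature_schema()].
#' @export
assemble_features <- function(vv = NULL, cs = NULL, pp = NULL,
                              variant = c("variability", "clinical",
                                          "physician", "combined"),
                              sources = c("rri", "sbp", "dbp")) {
  variant <- match.arg(variant)
  need_vv <- variant %in% c("variability", "combined")
  need_cs <- variant %in% c("clinical", "combined")
  need_pp <- variant %in% c("physician", "combined")
  if (need_vv && is.null(vv)) stop("variant '", variant,
                                   "' requires the variability block", call. = FALSE)
  if (need_cs && is.null(cs)) stop("variant '", variant,
                                   "' requires the clinical block", call. = FALSE)
  if (need_pp && is.null(pp)) stop("variant '", variant,
                                   "' requires the physician block", call. = FALSE)
  out <- numeric(0)
  if (need_vv) {
    nm <- as.vector(t(outer(sources, variability_metric_names(), paste, sep = "_")))
    block <- setNames(rep(NA_real_, length(nm)), nm)
    shared <- intersect(nm, names(vv))
    block[shared] <- vv[shared]
    out <- c(out, block)
  }
  if (need_cs) {
    stopifnot(inherits(cs, "clinical_snapshot"))
    block <- vapply(clinical_feature_names(),
                    function(f) as.numeric(cs[[f]]), numeric(1))
    out <- c(out, block)
  }
  if (need_pp) {
    stopifnot(inherits(pp, "physician_prediction"))
    cat_i <- match(pp$category, physician_categories())
    conf_i <- match(pp$confidence, c("low", "moderate", "high"))
    out <- c(out, phys_ttd_min = physician_category_midpoints()[cat_i],
             phys_confidence = conf_i)
  }
  out
}

#' Feature matrix for a cohort
#'
#' Runs the variability panel on each patient's (cleaned) beat series,
#' summarises it, and assembles per-patient feature vectors for a variant,
#' alongside the observed time to death.
#'
#' @param cohort a `dcd_cohort`.
#' @param variant model variant.
#' @param sources variability sources.
#' @param beats_list optional list of beat series overriding each patient's
#'   `beats_true` (e.g. serial assessments).
#' @return list with `x` (data.frame of features), `time` (minutes,
#'   censored at 240), `status` (1 = died by 240 min), `ttd` (uncensored
#'   true minutes).
#' @export
cohort_features <- function(cohort, variant = "combined",
                            sources = c("rri", "sbp", "dbp"),
                            beats_list = NULL) {
  stopifnot(inherits(cohort, "dcd_cohort"))
  rows <- lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    vv <- NULL
    if (variant %in% c("variability", "combined")) {
      beats <- if (is.null(beats_list)) p$beats_true else beats_list[[i]]
      panel <- metric_panel(clean_beats(beats), sources = sources)
      vv <- variability_summary(panel)
    }
    assemble_features(vv = vv, cs = p$clinical, pp = p$physician,
                      variant = variant, sources = sources)
  })
  x <- as.data.frame(do.call(rbind, rows))
  ttd <- vapply(cohort, function(p) p$truth$true_ttd_min, numeric(1))
  list(x = x, time = pmin(ttd, 240), status = as.integer(ttd <= 240), ttd = ttd)
}
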