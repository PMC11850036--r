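#' Content hash of a report payload
#'
#' MD5 of the canonical JSON serialisation; links every rendered number to
#' the pipeline artifact it came from.
#' @param payload list to hash.
#' @return hex string.
#' @export
payload_hash <- function(payload) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# section orders per audience: the data payload is identical, only the
# presentation order and appendix differ
pre_wlsm_sections <- function(audience) {
  base <- c("prediction", "clinical_summary", "data_quality")
  if (audience == "transplant") c("prediction", "data_quality",
                                  "clinical_summary", "organ_appendix")
  else base
}

#' Render a pre-WLSM prediction report
#'
#' Data-first report: the JSON payload is identical for every audience
#' (donation/ICU and transplant teams must see the same numbers); the
#' audience only selects section ordering and whether the organ-focused
#' appendix is included. The prediction block leads. The headline triple is
#' the probability of death within 30, 60 and 120 min.
#'
#' @param patient_id identifier.
#' @param predictions named list, model variant -> `survival_prediction`.
#'   The headline comes from `combined` when present, else the first
#'   variant.
#' @param clinical a [clinical_snapshot()] or `NULL`.
#' @param data_quality list (e.g. windows used, artifact fraction).
#' @param audience `"icu"` or `"transplant"`.
#' @param assessed_at assessment label.
#' @return list of class `da_report` with `payload` (audience-independent),
#'   `audience`, `sections`, and `text` (rendered document).
#' @export
render_pre_wlsm_report <- function(patient_id, predictions, clinical = NULL,
                                   data_quality = list(),
                                   audience = c("icu", "transplant"),
                                   assessed_at = "") {
  audience <- match.arg(audience)
  if (!length(predictions)) stop("no predictions supplied", call. = FALSE)
  stopifnot(all(vapply(predictions, inherits, logical(1), "survival_prediction")))
  headline_from <- if ("combined" %in% names(predictions)) "combined"
                   else names(predictions)[1]
  hp <- predictions[[headline_from]]
  tri <- hp$p_death[match(c(30, 60, 120), hp$horizons_min)]
  prob_table <- lapply(predictions, function(p) {
    list(horizons_min = p$horizons_min, p_death = p$p_death)
  })
  payload <- list(
    report_type = "pre_wlsm",
    patient_id = patient_id,
    assessed_at = assessed_at,
    headline = list(variant = headline_from,
                    p30 = tri[1], p60 = tri[2], p120 = tri[3]),
    probability_table = prob_table,
    clinical_summary = if (!is.null(clinical)) unclass(clinical) else NULL,
    data_quality = data_quality)
  payload$content_hash <- payload_hash(payload[setdiff(names(payload),
                                                       "content_hash")])
  sections <- pre_wlsm_sections(audience)
  structure(list(payload = payload, audience = audience, sections = sections,
                 text = render_pre_wlsm_text(payload, sections)),
            class = "da_report")
}

render_pre_wlsm_text <- function(payload, sections) {
  lines <- c(sprintf("PRE-WLSM PREDICTION REPORT  patient %s  (%s)",
                     payload$patient_id, payload$assessed_at))
  for (sec in sections) {
    lines <- c(lines, switch(
      sec,
      prediction = c(
        sprintf("Probability of death after WLSM (%s model):",
                payload$headline$variant),
        sprintf("  within 30 min: %.2f", payload$headline$p30),
        sprintf("  within 60 min: %.2f", payload$headline$p60),
        sprintf("  within 120 min: %.2f", payload$headline$p120)),
      clinical_summary = if (!is.null(payload$clinical_summary)) {
        c("Clinical summary:",
          sprintf("  GCS %s, APACHE II %s, lactate %.1f mmol/L, FiO2 %.2f",
                  payload$clinical_summary$gcs, payload$clinical_summary$apache2,
                  payload$clinical_summary$lactate_mmol_L,
                  payload$clinical_summary$fio2_frac))
      } else "Clinical summary: not available",
      data_quality = c("Data quality:",
                       sprintf("  %s = %s", names(payload$data_quality),
                               unlist(payload$data_quality))),
      organ_appendix = "Organ-focused appendix: see probability table.",
      character(0)))
  }
  c(lines, sprintf("content hash: %s", payload$content_hash))
}

#' Render a post-WLSM ischemia report
#'
#' JSON payload plus a colour-coded text table of time below each threshold
#' (green: no exposure; amber/red: increasing exposure) and the
#' organ-window flags. A truncated summary (no observed arrest) is rendered
#' with a prominent banner.
#'
#' @param summary an [ischemia_summary()].
#' @param patient_id identifier.
#' @param audience `"icu"` or `"transplant"`.
#' @param withdrawal_details free-text description of how support was
#'   withdrawn.
#' @return list of class `da_report`.
#' @export
render_post_wlsm_report <- function(summary, patient_id = "",
                                    audience = c("icu", "transplant"),
                                    withdrawal_details = "") {
  audience <- match.arg(audience)
  stopifnot(inherits(summary, "ischemia_summary"))
  tab <- ischemia_table(summary)
  payload <- list(
    report_type = "post_wlsm",
    patient_id = patient_id,
    wlsm_time_min = summary$wlsm_time_min,
    death_time_min = summary$death_time_min,
    ttd_min = summary$ttd_min,
    truncated = summary$truncated,
    complete = summary$complete,
    ischemia = tab,
    organ_flags = as.list(summary$organ_flags),
    organ_windows_min = as.list(summary$thresholds$organ_windows_min),
    withdrawal_details = withdrawal_details)
  payload$content_hash <- payload_hash(payload[setdiff(names(payload),
                                                       "content_hash")])
  structure(list(payload = payload, audience = audience,
                 sections = c("ischemia", "organ_flags"),
                 text = render_post_wlsm_text(payload)),
            class = "da_report")
}

render_post_wlsm_text <- function(payload) {
  colour <- function(m) if (m <= 0) "green" else if (m < 10) "amber" else "red"
  lines <- sprintf("POST-WLSM ISCHEMIA REPORT  patient %s", payload$patient_id)
  if (isTRUE(payload$truncated)) {
    lines <- c(lines, "*** NO ARREST OBSERVED WITHIN RECORD: SUMMARY TRUNCATED ***")
  } else {
    lines <- c(lines, sprintf("WLSM to death: %.1f min", payload$ttd_min))
  }
  tab <- payload$ischemia
  lines <- c(lines, "Time below thresholds:",
             sprintf("  %-5s < %3g : %6.1f min [%s]", tab$signal, tab$cutoff,
                     tab$minutes_below, vapply(tab$minutes_below, colour,
                                               character(1))))
  flags <- unlist(payload$organ_flags)
  wins <- unlist(payload$organ_windows_min)
  lines <- c(lines, "Organ windows:",
             sprintf("  %-9s (<= %3g min): %s", names(flags), wins[names(flags)],
                     ifelse(flags, "within window", "out of window")))
  c(lines, sprintf("content hash: %s", payload$content_hash))
}

#' Write a report's JSON payload
#' @param report a `da_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "da_report"))
  jsonlite::write_json(report$payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a report payload
#' @param path JSON file written by [write_report_json()].
#' @return payload list.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Validate a report payload against the shipped JSON schema
#'
#' Structural validation against the schema files under
#' `inst/schema/` (a pragmatic subset of JSON Schema: `type`, `required`,
#' `properties`, `minimum`, `maximum`, `enum`).
#'
#' @param payload report payload list.
#' @param schema schema name (`"pre_wlsm"` or `"post_wlsm"`) or a path.
#' @return `TRUE` invisibly; aborts with the list of violations otherwise.
#' @export
validate_report <- function(payload, schema = payload$report_type) {
  path <- if (file.exists(schema)) schema else {
    system.file("schema", paste0(schema, "_report.schema.json"),
                package = "dcdtools", mustWork = TRUE)
  }
  sch <- jsonlite::read_json(path, simplifyVector = FALSE)
  errs <- character(0)
  check <- function(node, sc, where) {
    ty <- sc$type
    if (!is.null(ty)) {
      ok <- switch(ty,
                   object = is.list(node),
                   array = is.list(node) || (is.atomic(node) && length(node) != 1),
                   string = is.character(node) && length(node) == 1,
                   number = is.numeric(node) && length(node) == 1,
                   boolean = is.logical(node) && length(node) == 1,
                   TRUE)
      if (!ok && !(identical(ty, "number") && is.null(node))) {
        errs <<- c(errs, sprintf("%s: expected %s", where, ty))
        return(invisible(NULL))
      }
    }
    if (!is.null(sc$enum) && !(node %in% unlist(sc$enum))) {
      errs <<- c(errs, sprintf("%s: value not in enum", where))
    }
    if (!is.null(sc$minimum) && is.numeric(node) &&
        any(node < sc$minimum - 1e-12, na.rm = TRUE)) {
      errs <<- c(errs, sprintf("%s: below minimum %s", where, sc$minimum))
    }
    if (!is.null(sc$maximum) && is.numeric(node) &&
        any(node > sc$maximum + 1e-12, na.rm = TRUE)) {
      errs <<- c(errs, sprintf("%s: above maximum %s", where, sc$maximum))
    }
    if (!is.null(sc$required)) {
      for (rq in unlist(sc$required)) {
        if (is.null(node[[rq]])) errs <<- c(errs, sprintf("%s: missing required '%s'",
                                                          where, rq))
      }
    }
    if (!is.null(sc$properties) && is.list(node)) {
      for (pn in names(sc$properties)) {
        if (!is.null(node[[pn]])) {
          check(node[[pn]], sc$properties[[pn]], paste0(where, ".", pn))
        }
      }
    }
  }
  check(payload, sch, "$")
  if (length(errs)) {
    stop("report payload fails schema validation:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}
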