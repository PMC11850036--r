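#' Construct a multichannel waveform record
#'
#' Container for synchronously started, independently sampled monitor
#' channels. Conventional channels and native rates: ECG 500 Hz, invasive
#' arterial pressure (ABP) 125 Hz, plethysmogram (PLETH) 125 Hz, respiratory
#' (RESP) 62.5 Hz.
#'
#' @param channels named list; each element a list with numeric `samples`
#'   and positive `rate_hz`.
#' @param t0 record start time in seconds (default 0).
#' @param wlsm_time optional time of withdrawal of life-sustaining measures,
#'   seconds from `t0`; must not lie beyond the record span.
#' @param meta free-form provenance list.
#' @return object of class `waveform_record`.
#' @export
waveform_record <- function(channels, t0 = 0, wlsm_time = NULL, meta = list()) {
  if (!length(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    stop("channels must be a non-empty named list", call. = FALSE)
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (is.null(ch$samples) || !length(ch$samples)) {
      stop("channel '", nm, "' is empty", call. = FALSE)
    }
    if (is.null(ch$rate_hz) || !is.finite(ch$rate_hz) || ch$rate_hz <= 0) {
      stop("channel '", nm, "' has no positive rate_hz", call. = FALSE)
    }
  }
  span <- max(vapply(channels, function(ch) length(ch$samples) / ch$rate_hz,
                     numeric(1)))
  if (!is.null(wlsm_time) && wlsm_time > span + 1e-9) {
    stop("wlsm_time lies beyond the record span", call. = FALSE)
  }
  structure(list(channels = channels, t0 = t0, wlsm_time = wlsm_time,
                 meta = meta, span_s = span),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat("<waveform_record>", sprintf("%.1f s", x$span_s), "\n")
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-6s %8d samples @ %.1f Hz\n", nm, length(ch$samples), ch$rate_hz))
  }
  if (!is.null(x$wlsm_time)) cat(sprintf("  WLSM at %.1f s\n", x$wlsm_time))
  invisible(x)
}

#' Write a waveform record in the long CSV dialect
#'
#' Dialect: optional `# key=value` header comment lines carrying `t0`,
#' `wlsm_time` and per-channel rates, then a header row
#' `time_s,channel,value`, one sample per row, UTF-8, `.` decimal. Long
#' format stores the multi-rate channels unambiguously in one file; the
#' round trip through [read_waveform()] is lossless.
#'
#' @param record a [waveform_record].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# t0=%.10g", record$t0), con)
  if (!is.null(record$wlsm_time)) {
    writeLines(sprintf("# wlsm_time=%.10g", record$wlsm_time), con)
  }
  for (nm in names(record$channels)) {
    writeLines(sprintf("# rate_hz.%s=%.10g", nm, record$channels[[nm]]$rate_hz), con)
  }
  writeLines("time_s,channel,value", con)
  for (nm in names(record$channels)) {
    ch <- record$channels[[nm]]
    t <- (seq_along(ch$samples) - 1) / ch$rate_hz
    writeLines(sprintf("%.10g,%s,%.10g", t, nm, ch$samples), con)
  }
  invisible(path)
}

#' Read a waveform record
#'
#' @param path file path.
#' @param format only the `"csv"` long dialect of [write_waveform()] is
#'   supported; `"wfdb"` is recognised but unsupported in this build and
#'   raises an error.
#' @param required_channels channels that must be present (default `"ECG"`);
#'   a missing one raises a format error naming it.
#' @return a [waveform_record].
#' @export
read_waveform <- function(path, format = c("csv", "wfdb"),
                          required_channels = "ECG") {
  format <- match.arg(format)
  if (format == "wfdb") {
    stop("WFDB input is not supported by this build; use the CSV dialect",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || body[1] != "time_s,channel,value") {
    stop("format error: expected header row 'time_s,channel,value'", call. = FALSE)
  }
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (!all(c("time_s", "channel", "value") %in% names(df))) {
    stop("format error: missing column(s) in CSV body", call. = FALSE)
  }
  channels <- list()
  for (nm in unique(df$channel)) {
    sub <- df[df$channel == nm, , drop = FALSE]
    if (is.unsorted(sub$time_s, strictly = TRUE)) {
      stop("format error: non-monotone timestamps in channel '", nm, "'",
           call. = FALSE)
    }
    rate_key <- paste0("rate_hz.", nm)
    rate <- if (!is.null(meta[[rate_key]])) as.numeric(meta[[rate_key]]) else {
      if (nrow(sub) < 2) stop("format error: missing rate for channel '", nm,
                              "'", call. = FALSE)
      1 / stats::median(diff(sub$time_s))
    }
    channels[[nm]] <- list(samples = sub$value, rate_hz = rate)
  }
  missing <- setdiff(required_channels, names(channels))
  if (length(missing)) {
    stop("format error: required channel(s) missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  waveform_record(
    channels,
    t0 = if (!is.null(meta$t0)) as.numeric(meta$t0) else 0,
    wlsm_time = if (!is.null(meta$wlsm_time)) as.numeric(meta$wlsm_time) else NULL,
    meta = meta)
}
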