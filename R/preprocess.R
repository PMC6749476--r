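#' Resting-period baseline of a wearable signal
#'
#' The baseline of a signal within one trial is the median of its present
#' samples restricted to the resting period. In deployment this is the
#' signal's equilibrium value during rest or sleep.
#'
#' @param values Signal samples.
#' @param rest_mask Logical, `TRUE` where the trial is at rest.
#' @param missing_mask Logical mask of missing samples; defaults to
#'   `is.na(values)`.
#' @return The baseline value (signal units).
#' @export
#' @examples
#' compute_baseline(c(70, 72, 74, 130), rest_mask = c(TRUE, TRUE, TRUE, FALSE))
compute_baseline <- function(values, rest_mask, missing_mask = is.na(values)) {
  stopifnot(length(values) == length(rest_mask),
            length(values) == length(missing_mask))
  use <- rest_mask & !missing_mask
  if (!any(use))
    stop("baseline undefined: no present rest-period samples")
  stats::median(values[use])
}

#' Baseline table for a set of streams
#'
#' One row per (stream, signal) with the rest-period median baseline.
#' Signals with data but no present rest-period sample get an `NA` baseline
#' (unusable for that stream) with a warning.
#'
#' @param streams List of [trial_stream()] objects.
#' @param codes Signal codes to include; defaults to those present.
#' @return Data frame `stream_id`, `signal`, `baseline`.
#' @export
baseline_table <- function(streams, codes = NULL) {
  rows <- lapply(streams, function(s) {
    d <- s$data
    sc <- if (is.null(codes)) intersect(SIGNAL_CODES, names(d)) else codes
    rest <- d$exercise == 0L
    b <- vapply(sc, function(code) {
      if (!any(rest & !is.na(d[[code]]))) {
        warning("no rest-period samples for ", code, " in stream ",
                s$stream_id, "; baseline NA")
        return(NA_real_)
      }
      compute_baseline(d[[code]], rest)
    }, numeric(1))
    data.frame(stream_id = s$stream_id, signal = sc, baseline = unname(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove per-trial signal baselines
#'
#' Subtracts each signal's rest-period baseline from its present samples;
#' missingness, CGM and reference glucose are untouched. Applying the
#' operation twice (with baselines recomputed) is the identity, since the
#' rest-period median of a baseline-removed signal is 0.
#'
#' @param stream A [trial_stream()].
#' @param baselines A [baseline_table()] covering this stream, or `NULL` to
#'   compute it from the stream itself.
#' @return The transformed stream, with attribute `baseline_removed = TRUE`.
#' @export
remove_baseline <- function(stream, baselines = NULL) {
  stopifnot(inherits(stream, "trial_stream"))
  if (is.null(baselines)) baselines <- baseline_table(list(stream))
  d <- stream$data
  for (code in intersect(SIGNAL_CODES, names(d))) {
    if (!any(!is.na(d[[code]]))) next
    b <- baselines$baseline[baselines$stream_id == stream$stream_id &
                              baselines$signal == code]
    if (length(b) != 1 || is.na(b))
      stop("missing baseline entry for signal ", code, " in stream ",
           stream$stream_id)
    d[[code]] <- d[[code]] - b
  }
  out <- trial_stream(stream$stream_id, d,
                      generative = attr(stream, "generative"))
  attr(out, "baseline_removed") <- TRUE
  out
}

#' Signal availability
#'
#' Complement of the percentage of missing samples.
#'
#' @param values Signal samples.
#' @param missing_mask Logical mask of missing samples; defaults to
#'   `is.na(values)`.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' availability(c(1, NA, 3, NA, NA, 6, 7, 8, 9, 10)) # 70
availability <- function(values, missing_mask = is.na(values)) {
  if (!length(values)) stop("availability undefined for an empty series")
  100 * mean(!missing_mask)
}

#' Pooled per-signal availability across streams
#'
#' @param streams List of [trial_stream()] objects.
#' @param codes Signal codes to report.
#' @return Named numeric vector of percentages (samples pooled over streams).
#' @export
pooled_availability <- function(streams, codes = SIGNAL_CODES) {
  vapply(codes, function(code) {
    x <- unlist(lapply(streams, function(s)
      if (code %in% names(s$data)) s$data[[code]] else NULL))
    if (!length(x)) return(NA_real_)
    availability(x)
  }, numeric(1))
}
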