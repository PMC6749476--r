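#' Align raw CGM samples onto the 1-minute grid
#'
#' CGM devices report at irregular (typically 5-min) cadence; the reference
#' analyzer at 15-min cadence. To pair the two, the raw CGM trace is linearly
#' interpolated and rounded to one sample per minute. No extrapolation is
#' performed beyond the first and last raw sample.
#'
#' @param raw_times Sampling times in minutes, strictly increasing.
#' @param raw_values CGM values in mg/dL, same length.
#' @return Data frame with columns `minute` (integer grid spanning the raw
#'   time range) and `cgm_mgdl`.
#' @export
#' @examples
#' align_cgm(c(0, 2), c(100, 110)) # minutes 0,1,2 -> 100, 105, 110
align_cgm <- function(raw_times, raw_values) {
  stopifnot(length(raw_times) == length(raw_values))
  if (length(raw_times) < 2)
    stop("insufficient data: at least 2 raw CGM samples are required")
  if (any(diff(raw_times) <= 0))
    stop("raw_times must be strictly increasing")
  grid <- seq.int(ceiling(min(raw_times)), floor(max(raw_times)))
  data.frame(minute = as.integer(grid),
             cgm_mgdl = stats::approx(raw_times, raw_values, xout = grid,
                                      rule = 1)$y)
}

#' Pair CGM with reference plasma glucose
#'
#' One paired sample per reference instant at which both the gridded CGM and
#' the reference glucose are present, with the estimation error
#' `error = cgm - pg` and the wearable values of the same minute attached.
#' Pairs whose absolute error exceeds `outlier_limit` (physically implausible
#' sensor excursions) are excluded.
#'
#' @param stream A [trial_stream()] on the 1-minute grid.
#' @param outlier_limit Absolute error bound in mg/dL (default 100); `NULL`
#'   disables the exclusion.
#' @return Data frame with columns `stream_id`, `minute`, `cgm`, `pg`,
#'   `error`, `in_exercise` and one column per signal present in the stream
#'   (missing wearable samples stay `NA`). Zero rows are possible.
#' @export
pair_with_reference <- function(stream, outlier_limit = 100) {
  stopifnot(inherits(stream, "trial_stream"))
  d <- stream$data
  idx <- which(!is.na(d$pg_mgdl) & !is.na(d$cgm_mgdl))
  codes <- intersect(SIGNAL_CODES, names(d))
  out <- data.frame(stream_id = rep(stream$stream_id, length(idx)),
                    minute = d$minute[idx],
                    cgm = d$cgm_mgdl[idx],
                    pg = d$pg_mgdl[idx],
                    error = d$cgm_mgdl[idx] - d$pg_mgdl[idx],
                    in_exercise = d$exercise[idx] == 1L,
                    stringsAsFactors = FALSE)
  for (code in codes) out[[code]] <- d[[code]][idx]
  if (!is.null(outlier_limit))
    out <- out[abs(out$error) <= outlier_limit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stream-level quality filter
#'
#' Discards data streams unusable for model fitting: streams whose CGM trace
#' or reference trace is entirely absent (sensor / analyzer malfunction) and
#' streams with more than `max_faulty_frac` of samples flagged faulty.
#' Retained streams are returned unmodified.
#'
#' @param streams List of [trial_stream()] objects.
#' @param max_faulty_frac Faulty-sample fraction above which (strictly) a
#'   stream is discarded; default 0.30, i.e. 30% or more unusable data leads
#'   to removal once the fraction exceeds the bound.
#' @return List with `retained` and `rejected` (lists of streams) and `log`,
#'   a data frame of `stream_id`, `reason` for every rejected stream
#'   (`"cgm_malfunction"`, `"reference_malfunction"`, `"faulty_fraction"`).
#' @export
qc_filter <- function(streams, max_faulty_frac = 0.30) {
  stopifnot(is.list(streams))
  reasons <- vapply(streams, function(s) {
    d <- s$data
    if (all(is.na(d$cgm_mgdl))) return("cgm_malfunction")
    if (all(is.na(d$pg_mgdl))) return("reference_malfunction")
    if (mean(d$faulty == 1L) > max_faulty_frac) return("faulty_fraction")
    ""
  }, character(1))
  keep <- reasons == ""
  list(retained = streams[keep],
       rejected = streams[!keep],
       log = data.frame(
         stream_id = vapply(streams[!keep], function(s) s$stream_id, ""),
         reason = reasons[!keep],
         stringsAsFactors = FALSE))
}
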