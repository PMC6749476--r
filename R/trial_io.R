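#' Trial stream container
#'
#' A trial stream is one experiment x one CGM sensor: an aligned 1-minute
#' grid carrying the CGM trace (mg/dL), the reference plasma glucose at its
#' sampling instants (every 15 min; `NA` elsewhere), the exercise-period
#' mask, the wearable signals (missing samples as `NA`) and a per-sample
#' faulty flag.
#'
#' @param stream_id Identifier.
#' @param data Data frame with columns `minute`, `cgm_mgdl`, `pg_mgdl`,
#'   `exercise`, the signal columns (any subset of [SIGNAL_CODES]) and
#'   optionally `faulty` (defaults to 0).
#' @param generative Optional list of generator ground truth (kept as an
#'   attribute; not serialized by [write_trial()]).
#' @return An object of class `trial_stream`.
#' @export
trial_stream <- function(stream_id, data, generative = NULL) {
  stopifnot(is.character(stream_id), length(stream_id) == 1, is.data.frame(data))
  required <- c("minute", "cgm_mgdl", "pg_mgdl", "exercise")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("trial data lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(data$faulty)) data$faulty <- 0L
  extra <- setdiff(names(data), c(required, SIGNAL_CODES, "faulty"))
  if (length(extra))
    stop("unknown column(s) in trial data: ", paste(extra, collapse = ", "))
  stp <- diff(data$minute)
  if (nrow(data) > 1 && any(stp != 1))
    stop("minute grid violation: non-unit step at row ",
         which(stp != 1)[1] + 1)
  for (col in c("cgm_mgdl", "pg_mgdl")) {
    bad <- which(!is.na(data[[col]]) & data[[col]] <= 0)
    if (length(bad))
      stop("non-positive glucose in column ", col, " at row ", bad[1])
  }
  if (any(!data$exercise %in% c(0L, 1L)))
    stop("exercise mask must be 0/1 at every minute")
  x <- structure(list(stream_id = stream_id, data = data),
                 class = "trial_stream")
  if (!is.null(generative)) attr(x, "generative") <- generative
  x
}

#' @export
print.trial_stream <- function(x, ...) {
  d <- x$data
  codes <- intersect(SIGNAL_CODES, names(d))
  cat(sprintf(
    "<trial_stream %s: %d min, %d reference samples, %d exercise min, %d signals%s>\n",
    x$stream_id, nrow(d), sum(!is.na(d$pg_mgdl)), sum(d$exercise == 1),
    length(codes),
    if (isTRUE(attr(x, "baseline_removed"))) ", baseline-removed" else ""))
  invisible(x)
}

# Shortest-exact decimal formatting: %.17g round-trips doubles exactly.
fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write / read a trial stream as CSV
#'
#' One CSV per stream with columns `minute, cgm_mgdl, pg_mgdl, exercise,
#' FHR, FST, FLV, FME, FCA, MHR, MTM, MGS, MST, MMO, PHR, faulty`; an empty
#' cell is a missing sample. Numeric values are written with enough digits
#' that `write_trial()` followed by [read_trial()] is the identity on all
#' fields.
#'
#' @param stream A [trial_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(stream, path) {
  stopifnot(inherits(stream, "trial_stream"))
  d <- stream$data
  cols <- c("minute", "cgm_mgdl", "pg_mgdl", "exercise",
            intersect(SIGNAL_CODES, names(d)), "faulty")
  out <- data.frame(minute = as.integer(d$minute),
                    cgm_mgdl = fmt_num(d$cgm_mgdl),
                    pg_mgdl = fmt_num(d$pg_mgdl),
                    exercise = as.integer(d$exercise),
                    stringsAsFactors = FALSE)
  for (code in intersect(SIGNAL_CODES, names(d))) out[[code]] <- fmt_num(d[[code]])
  out$faulty <- as.integer(d$faulty)
  utils::write.table(out[cols], path, sep = ",", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_trial
#' @param stream_id Identifier for the read stream; defaults to the file name
#'   without extension.
#' @return `read_trial()` returns a [trial_stream()]; malformed input
#'   (unknown header, non-monotone minutes, non-positive glucose) raises a
#'   format error naming the offending row or column.
#' @export
read_trial <- function(path, stream_id = NULL) {
  if (is.null(stream_id))
    stream_id <- sub("\\.[^.]*$", "", basename(path))
  d <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  required <- c("minute", "cgm_mgdl", "pg_mgdl", "exercise")
  if (!all(required %in% names(d)))
    stop("malformed header in ", path, ": missing ",
         paste(setdiff(required, names(d)), collapse = ", "))
  for (col in setdiff(names(d), character(0))) {
    if (!is.numeric(d[[col]]) && !all(is.na(d[[col]])))
      stop("non-numeric values in column ", col, " of ", path)
    d[[col]] <- as.numeric(d[[col]])
  }
  d$minute <- as.integer(d$minute)
  d$exercise <- as.integer(d$exercise)
  if (!is.null(d$faulty)) d$faulty <- as.integer(d$faulty)
  trial_stream(stream_id, d)
}
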