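#' Mean absolute relative deviation (MARD)
#'
#' The standard CGM accuracy metric: the mean over paired samples of
#' `|error| / PG`, expressed in percent.
#'
#' @param errors Per-pair errors `cgm - pg`, mg/dL.
#' @param pg Reference plasma glucose per pair, mg/dL, all positive.
#' @return MARD in percent.
#' @export
#' @examples
#' mard(c(10, 10), c(100, 200)) # 7.5
mard <- function(errors, pg) {
  if (!length(errors)) stop("mard undefined for empty input")
  if (length(errors) != length(pg)) stop("errors and pg length mismatch")
  if (any(is.na(errors)) || any(is.na(pg))) stop("missing values in mard input")
  if (any(pg <= 0)) stop("reference glucose must be positive")
  100 * mean(abs(errors) / pg)
}

#' Glycemic coefficient of variation
#'
#' `100 * SD(CGM) / mean(CGM)`, the usual glycemic-variability summary. The
#' standard deviation uses the n-1 denominator.
#'
#' @param values CGM (or eCGM) values, mg/dL.
#' @return CV in percent.
#' @export
#' @examples
#' glycemic_cv(c(90, 110)) # 14.14
glycemic_cv <- function(values) {
  if (length(values) < 2) stop("glycemic_cv needs at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("glycemic_cv undefined for non-positive mean")
  100 * stats::sd(values) / m
}

# MARD split by trial period; NA (with no warning) for an absent period.
mard_by_period <- function(pg, meas, in_exercise) {
  f <- function(sel) if (any(sel)) mard(meas[sel] - pg[sel], pg[sel]) else NA_real_
  c(exercise = f(in_exercise), rest = f(!in_exercise),
    total = f(rep(TRUE, length(pg))))
}

#' Random fitting/validation partitions of a stream cohort
#'
#' @param n_streams Number of streams.
#' @param n_validation Streams per validation set.
#' @param n_repeats Number of repeats.
#' @param seed Integer seed; the same seed yields the same partitions, which
#'   is how competing models are compared on common random numbers.
#' @return List of integer index vectors (the validation streams per repeat).
#' @export
cv_partitions <- function(n_streams, n_validation, n_repeats, seed) {
  stopifnot(n_streams > n_validation, n_validation >= 1, n_repeats >= 1)
  set.seed(as.integer(seed))
  lapply(seq_len(n_repeats), function(i) sort(sample.int(n_streams, n_validation)))
}

#' Leave-nine-out cross-validation of the error correction
#'
#' Repeatedly partitions the cohort into a fitting set and a validation set
#' (by default 18 fitting / 9 validation streams, 20 repeats), fits the
#' zero-intercept model on the pooled fitting-set pairs (complete cases over
#' the model signals), corrects the validation-set CGM values, and evaluates
#' MARD by period (exercise / rest / total) and glycemic CV for the original
#' and enhanced CGM on the pooled validation pairs. Reported summary metrics
#' are means over repeats; per-stream MARDs (averaged over the repeats in
#' which a stream was validated) feed the paired significance test.
#'
#' @param streams List of baseline-removed [trial_stream()] objects.
#' @param signal_codes Character vector of model inputs.
#' @param n_repeats,n_validation Cross-validation shape (defaults 20 and 9).
#' @param seed Seed for the random partitions (ignored when `partitions` is
#'   supplied).
#' @param partitions Optional pre-drawn [cv_partitions()] result, used to
#'   compare candidate models on identical splits.
#' @param outlier_limit Passed to [pair_with_reference()].
#' @param keep_pairs Keep the pooled validation pairs (with `ecgm`) in the
#'   report, e.g. for error-grid analysis.
#' @return A `crossval_report`: `per_repeat` (metrics and coefficients per
#'   repeat), `summary` (means over repeats), `per_stream` (per-stream MARD
#'   and CV for original and enhanced CGM), `p_values` (paired Wilcoxon,
#'   original vs enhanced, per metric), `partitions`, `signal_codes`, and
#'   optionally `pairs`.
#' @export
crossvalidate <- function(streams, signal_codes, n_repeats = 20,
                          n_validation = 9, seed = 1L, partitions = NULL,
                          outlier_limit = 100, keep_pairs = TRUE) {
  n <- length(streams)
  if (n < n_validation + 1)
    stop("insufficient streams: need more than n_validation = ", n_validation)
  stopifnot(length(signal_codes) >= 1)
  ids <- vapply(streams, function(s) s$stream_id, character(1))
  pairs <- do.call(rbind, lapply(streams, pair_with_reference,
                                 outlier_limit = outlier_limit))
  missing_codes <- setdiff(signal_codes, names(pairs))
  if (length(missing_codes))
    stop("signal(s) absent from streams: ", paste(missing_codes, collapse = ", "))
  if (is.null(partitions))
    partitions <- cv_partitions(n, n_validation, n_repeats, seed)

  metric_names <- c("mard_exercise_cgm", "mard_exercise_ecgm",
                    "mard_rest_cgm", "mard_rest_ecgm",
                    "mard_total_cgm", "mard_total_ecgm",
                    "cv_cgm", "cv_ecgm")
  per_repeat <- matrix(NA_real_, length(partitions), length(metric_names),
                       dimnames = list(NULL, metric_names))
  coefs <- matrix(NA_real_, length(partitions), length(signal_codes),
                  dimnames = list(NULL, signal_codes))
  stream_names <- c("mard_exercise_cgm", "mard_exercise_ecgm",
                    "mard_rest_cgm", "mard_rest_ecgm",
                    "mard_total_cgm", "mard_total_ecgm", "cv_cgm", "cv_ecgm")
  acc_sum <- matrix(0, n, length(stream_names),
                    dimnames = list(ids, stream_names))
  acc_n <- matrix(0L, n, length(stream_names), dimnames = list(ids, stream_names))
  pooled_pairs <- if (keep_pairs) vector("list", length(partitions)) else NULL

  for (r in seq_along(partitions)) {
    val_ids <- ids[partitions[[r]]]
    fit_df <- pairs[!(pairs$stream_id %in% val_ids), , drop = FALSE]
    cc <- stats::complete.cases(fit_df[signal_codes])
    model <- fit_zero_intercept(
      as.matrix(fit_df[cc, signal_codes, drop = FALSE]), fit_df$error[cc])
    coefs[r, ] <- model$coefficients
    val <- pairs[pairs$stream_id %in% val_ids, , drop = FALSE]
    val$ecgm <- correct_cgm(val$cgm, predict_error(model, val[signal_codes]))

    m_cgm <- mard_by_period(val$pg, val$cgm, val$in_exercise)
    m_ecgm <- mard_by_period(val$pg, val$ecgm, val$in_exercise)
    per_repeat[r, ] <- c(m_cgm["exercise"], m_ecgm["exercise"],
                         m_cgm["rest"], m_ecgm["rest"],
                         m_cgm["total"], m_ecgm["total"],
                         glycemic_cv(val$cgm), glycemic_cv(val$ecgm))
    for (sid in val_ids) {
      v <- val[val$stream_id == sid, , drop = FALSE]
      if (!nrow(v)) next
      sm_c <- mard_by_period(v$pg, v$cgm, v$in_exercise)
      sm_e <- mard_by_period(v$pg, v$ecgm, v$in_exercise)
      row <- c(sm_c["exercise"], sm_e["exercise"], sm_c["rest"], sm_e["rest"],
               sm_c["total"], sm_e["total"],
               if (nrow(v) > 1) glycemic_cv(v$cgm) else NA_real_,
               if (nrow(v) > 1) glycemic_cv(v$ecgm) else NA_real_)
      ok <- !is.na(row)
      acc_sum[sid, ok] <- acc_sum[sid, ok] + row[ok]
      acc_n[sid, ok] <- acc_n[sid, ok] + 1L
    }
    if (keep_pairs)
      pooled_pairs[[r]] <- data.frame(repeat_idx = r, val[c("stream_id",
        "minute", "pg", "cgm", "ecgm", "in_exercise")])
  }

  per_stream <- as.data.frame(acc_sum / ifelse(acc_n > 0, acc_n, NA))
  per_stream <- cbind(stream_id = ids, per_stream, row.names = NULL)
  sig <- function(a, b)
    tryCatch(mard_significance(a, b), error = function(e) NA_real_)
  p_values <- c(
    mard_exercise = sig(per_stream$mard_exercise_cgm,
                        per_stream$mard_exercise_ecgm),
    mard_rest = sig(per_stream$mard_rest_cgm, per_stream$mard_rest_ecgm),
    mard_total = sig(per_stream$mard_total_cgm, per_stream$mard_total_ecgm),
    cv = sig(per_stream$cv_cgm, per_stream$cv_ecgm))

  out <- list(per_repeat = cbind(data.frame(repeat_idx = seq_along(partitions)),
                                 as.data.frame(per_repeat),
                                 stats::setNames(as.data.frame(coefs),
                                                 paste0("coef_", signal_codes))),
              summary = colMeans(per_repeat),
              coefficients = colMeans(coefs),
              per_stream = per_stream,
              p_values = p_values,
              partitions = partitions,
              signal_codes = signal_codes)
  if (keep_pairs) out$pairs <- do.call(rbind, pooled_pairs)
  structure(out, class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<crossval_report: %d repeats, model [%s]>\n",
              nrow(x$per_repeat), paste(x$signal_codes, collapse = ", ")))
  tab <- data.frame(
    period = c("Exercise", "Rest", "Total", "CV"),
    original = sprintf("%.2f%%", c(s["mard_exercise_cgm"], s["mard_rest_cgm"],
                                   s["mard_total_cgm"], s["cv_cgm"])),
    enhanced = sprintf("%.2f%%", c(s["mard_exercise_ecgm"], s["mard_rest_ecgm"],
                                   s["mard_total_ecgm"], s["cv_ecgm"])),
    p_value = signif(x$p_values[c("mard_exercise", "mard_rest",
                                  "mard_total", "cv")], 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Paired significance of a metric change
#'
#' Two-sided paired test on per-stream metric values before and after
#' correction. Wilcoxon signed rank by default (robust at small n; the
#' normal approximation is used so ties and small samples are handled
#' uniformly); a paired t-test is available. All-zero differences return
#' p = 1 by convention. Stream pairs with missing values are dropped.
#'
#' @param original,enhanced Per-stream metric values, equal length.
#' @param method `"wilcoxon"` or `"ttest"`.
#' @return The p-value.
#' @export
mard_significance <- function(original, enhanced,
                              method = c("wilcoxon", "ttest")) {
  method <- match.arg(method)
  ok <- !is.na(original) & !is.na(enhanced)
  original <- original[ok]; enhanced <- enhanced[ok]
  if (length(original) < 5)
    stop("at least 5 paired streams are required for the significance test")
  d <- original - enhanced
  if (all(d == 0)) return(1)
  # a constant non-zero difference is degenerate for the t-test; its p-value
  # tends to 0
  if (stats::sd(d) == 0 && method == "ttest") return(0)
  if (method == "wilcoxon")
    stats::wilcox.test(original, enhanced, paired = TRUE, exact = FALSE,
                       correct = TRUE)$p.value
  else
    stats::t.test(original, enhanced, paired = TRUE)$p.value
}
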