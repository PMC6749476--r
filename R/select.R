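#' Availability filter
#'
#' First elimination criterion: any wearable with 30% or more of its samples
#' unusable (missing, disconnected, out of bounds) is discarded from the
#' model fit, i.e. signals strictly below the availability threshold are
#' removed and a signal at exactly the threshold is kept.
#'
#' @param availabilities Named numeric vector of availability percentages.
#' @param threshold_pct Threshold in percent (default 70).
#' @return List with `kept` and `removed` (data frame of `signal`,
#'   `availability`).
#' @export
filter_by_availability <- function(availabilities, threshold_pct = 70) {
  stopifnot(!is.null(names(availabilities)))
  drop <- availabilities < threshold_pct
  list(kept = names(availabilities)[!drop],
       removed = data.frame(signal = names(availabilities)[drop],
                            availability = unname(availabilities[drop]),
                            stringsAsFactors = FALSE))
}

#' Pairwise Pearson correlation of wearable signals
#'
#' Symmetric unit-diagonal matrix over pairwise-complete observations.
#' Correlations undefined because a signal is constant (or a pair has fewer
#' than 3 complete observations) are returned as `NA`; the elimination step
#' treats them as 0.
#'
#' @param pairs Data frame of pooled paired samples (or any per-minute
#'   table) containing the signal columns.
#' @param codes Signal columns to correlate.
#' @return m x m correlation matrix.
#' @export
correlation_matrix <- function(pairs, codes) {
  stopifnot(all(codes %in% names(pairs)))
  x <- as.matrix(pairs[codes])
  suppressWarnings(r <- stats::cor(x, use = "pairwise.complete.obs"))
  # cor() leaves the diagonal NA for constant columns; pin it to 1.
  diag(r) <- 1
  r
}

#' Eliminate one member of each highly correlated signal pair
#'
#' Two signals carrying essentially the same information (|r| at or above the
#' threshold) are redundant; the less preferable member of each such pair is
#' removed. Preference: (a) higher availability, then (b) membership in
#' `preferred` — the normalized/continuous signals (METs are normalized per
#' patient; Fitbit heart rate is the continuous, widely available heart-rate
#' source) — then (c) alphabetical order, for determinism. Pairs are
#' processed from the highest |r| down.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param availabilities Named availability percentages for the same signals.
#' @param r_threshold Absolute correlation at or above which a pair is
#'   redundant (default 0.85).
#' @param preferred Signals favored at equal availability.
#' @return List with `kept` and `removed` (data frame `signal`, `partner`,
#'   `r`).
#' @export
eliminate_correlated <- function(corr, availabilities, r_threshold = 0.85,
                                 preferred = c("FME", "FHR")) {
  codes <- colnames(corr)
  stopifnot(!is.null(codes), all(codes %in% names(availabilities)))
  r <- corr
  r[is.na(r)] <- 0
  diag(r) <- 0
  kept <- codes
  removed <- data.frame(signal = character(0), partner = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  repeat {
    sub <- abs(r[kept, kept, drop = FALSE])
    if (!length(sub) || max(sub) < r_threshold) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- kept[ij[1]]; b <- kept[ij[2]]
    loser <- pick_loser(a, b, availabilities, preferred)
    removed <- rbind(removed,
                     data.frame(signal = loser,
                                partner = if (loser == a) b else a,
                                r = r[a, b], stringsAsFactors = FALSE))
    kept <- setdiff(kept, loser)
  }
  list(kept = kept, removed = removed)
}

pick_loser <- function(a, b, availabilities, preferred) {
  av_a <- availabilities[[a]]; av_b <- availabilities[[b]]
  if (av_a != av_b) return(if (av_a > av_b) b else a)
  pa <- a %in% preferred; pb <- b %in% preferred
  if (pa != pb) return(if (pa) b else a)
  sort(c(a, b))[2]
}

#' Eliminate signals unrepresentative of the exercise performed
#'
#' Second elimination criterion: a signal that does not respond to the
#' activity actually performed carries no exercise information (step counts
#' during cycloergometer exercise are the canonical case — the subject is
#' static, so the signal sits at its resting value throughout the bouts).
#' A signal is removed when the median absolute baseline-removed value over
#' the exercise period is below `floor_frac` of the signal's overall
#' interquartile range (both pooled over streams).
#'
#' @param streams List of baseline-removed [trial_stream()] objects.
#' @param codes Candidate signal codes.
#' @param floor_frac Relevance floor as a fraction of the overall IQR
#'   (default 0.05).
#' @return List with `kept` and `removed` (data frame `signal`,
#'   `exercise_median_abs`, `iqr`). Raises an error if nothing survives.
#' @export
eliminate_irrelevant <- function(streams, codes, floor_frac = 0.05) {
  stats_tab <- t(vapply(codes, function(code) {
    x <- unlist(lapply(streams, function(s) s$data[[code]]))
    ex <- unlist(lapply(streams, function(s) s$data$exercise == 1L))
    x_ex <- x[ex & !is.na(x)]
    x_all <- x[!is.na(x)]
    c(med = if (length(x_ex)) stats::median(abs(x_ex)) else 0,
      iqr = if (length(x_all)) stats::IQR(x_all) else 0)
  }, numeric(2)))
  drop <- stats_tab[, "med"] < floor_frac * stats_tab[, "iqr"] |
    (stats_tab[, "iqr"] == 0 & stats_tab[, "med"] == 0)
  kept <- codes[!drop]
  if (!length(kept))
    stop("no signal shows exercise-period activity; nothing survives the ",
         "relevance criterion")
  list(kept = kept,
       removed = data.frame(signal = codes[drop],
                            exercise_median_abs = unname(stats_tab[drop, "med"]),
                            iqr = unname(stats_tab[drop, "iqr"]),
                            stringsAsFactors = FALSE))
}

# Cross-validated MARD (exercise, total) of a candidate input set on fixed
# partitions; the workhorse of the backwards MARD loop.
cv_mard <- function(streams, codes, partitions, outlier_limit = 100) {
  rep <- crossvalidate(streams, codes, partitions = partitions,
                       outlier_limit = outlier_limit, keep_pairs = FALSE)
  c(exercise = unname(rep$summary["mard_exercise_ecgm"]),
    total = unname(rep$summary["mard_total_ecgm"]))
}

#' Backwards elimination on validation MARD
#'
#' Fourth elimination criterion. At each cycle every remaining signal is
#' tentatively removed and the reduced model is cross-validated on the same
#' partitions (common random numbers, so candidates are compared on
#' identical splits). A removal is eligible when it improves the validation
#' MARD both in the exercise period and in global (whole-trial) terms; among
#' eligible removals the one yielding the lowest exercise-period MARD — ties
#' broken by the lowest global MARD — is made permanent, and the cycle
#' repeats until no single removal improves the error, or one signal is
#' left. With `require_global_improvement = FALSE` only the exercise-period
#' MARD has to improve (an alternative reading of the protocol; the global
#' criterion then acts only as the tie-break).
#'
#' @param streams List of baseline-removed [trial_stream()] objects.
#' @param candidates Character vector of starting signals (at least 2).
#' @param n_repeats,n_validation,seed Cross-validation settings (see
#'   [crossvalidate()]).
#' @param outlier_limit Passed to [pair_with_reference()].
#' @param require_global_improvement Require the whole-trial MARD to improve
#'   as well (default `TRUE`).
#' @return An `elimination_trace` whose `steps` data frame has one row per
#'   removed signal (`signal`, `criterion = "mard"`, and the validation
#'   exercise/total MARD after the removal) and whose `surviving` field
#'   lists the final input set.
#' @export
backward_eliminate_by_mard <- function(streams, candidates, n_repeats = 20,
                                       n_validation = 9, seed = 1L,
                                       outlier_limit = 100,
                                       require_global_improvement = TRUE) {
  if (length(candidates) < 2)
    stop("backwards elimination needs at least 2 candidate signals")
  partitions <- cv_partitions(length(streams), n_validation, n_repeats, seed)
  current <- candidates
  base <- cv_mard(streams, current, partitions, outlier_limit)
  steps <- data.frame(signal = character(0), criterion = character(0),
                      mard_exercise = numeric(0), mard_total = numeric(0),
                      stringsAsFactors = FALSE)
  while (length(current) >= 2) {
    trial <- t(vapply(current, function(code)
      cv_mard(streams, setdiff(current, code), partitions, outlier_limit),
      numeric(2)))
    eligible <- trial[, "exercise"] < base[["exercise"]]
    if (require_global_improvement)
      eligible <- eligible & trial[, "total"] < base[["total"]]
    if (!any(eligible)) break
    idx <- which(eligible)
    best <- idx[order(trial[idx, "exercise"], trial[idx, "total"])[1]]
    steps <- rbind(steps, data.frame(signal = current[best],
                                     criterion = "mard",
                                     mard_exercise = trial[best, "exercise"],
                                     mard_total = trial[best, "total"],
                                     stringsAsFactors = FALSE))
    base <- trial[best, ]
    current <- setdiff(current, current[best])
  }
  elimination_trace(steps, surviving = current, candidates = candidates)
}

elimination_trace <- function(steps, surviving, candidates) {
  rownames(steps) <- NULL
  stopifnot(!anyDuplicated(steps$signal),
            !length(intersect(steps$signal, surviving)),
            setequal(c(steps$signal, surviving), candidates))
  structure(list(steps = steps, surviving = surviving,
                 candidates = candidates),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("<elimination_trace: %d of %d signals removed; surviving [%s]>\n",
              nrow(x$steps), length(x$candidates),
              paste(x$surviving, collapse = ", ")))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Full four-criterion input selection
#'
#' Runs the backwards elimination protocol end to end: (1) availability
#' filter, (2) high-correlation redundancy removal, (3) exercise-relevance
#' check, (4) cross-validated MARD loop. Returns the combined trace; each
#' step records the criterion that removed the signal and, for MARD steps,
#' the validation MARD after removal.
#'
#' @param streams Baseline-removed [trial_stream()] objects.
#' @param codes Starting signal set (defaults to the signals present).
#' @param availability_threshold Percent, criterion 1 (default 70).
#' @param r_threshold Criterion 3 redundancy bound (default 0.85).
#' @param relevance_floor Criterion 2 floor fraction (default 0.05).
#' @param n_repeats,n_validation,seed Cross-validation settings for the MARD
#'   loop.
#' @param outlier_limit Passed to [pair_with_reference()].
#' @return An `elimination_trace` over all four criteria.
#' @export
select_inputs <- function(streams, codes = NULL, availability_threshold = 70,
                          r_threshold = 0.85, relevance_floor = 0.05,
                          n_repeats = 20, n_validation = 9, seed = 1L,
                          outlier_limit = 100) {
  if (is.null(codes))
    codes <- intersect(SIGNAL_CODES, names(streams[[1]]$data))
  avail <- pooled_availability(streams, codes)
  st_avail <- filter_by_availability(avail, availability_threshold)
  steps <- if (nrow(st_avail$removed))
    data.frame(signal = st_avail$removed$signal, criterion = "availability",
               mard_exercise = NA_real_, mard_total = NA_real_,
               stringsAsFactors = FALSE)
  else
    data.frame(signal = character(0), criterion = character(0),
               mard_exercise = numeric(0), mard_total = numeric(0),
               stringsAsFactors = FALSE)

  pairs <- do.call(rbind, lapply(streams, pair_with_reference,
                                 outlier_limit = outlier_limit))
  corr <- correlation_matrix(pairs, st_avail$kept)
  st_corr <- eliminate_correlated(corr, avail, r_threshold)
  if (nrow(st_corr$removed))
    steps <- rbind(steps, data.frame(signal = st_corr$removed$signal,
                                     criterion = "correlation",
                                     mard_exercise = NA_real_,
                                     mard_total = NA_real_,
                                     stringsAsFactors = FALSE))

  st_rel <- eliminate_irrelevant(streams, st_corr$kept, relevance_floor)
  if (nrow(st_rel$removed))
    steps <- rbind(steps, data.frame(signal = st_rel$removed$signal,
                                     criterion = "relevance",
                                     mard_exercise = NA_real_,
                                     mard_total = NA_real_,
                                     stringsAsFactors = FALSE))

  tr <- backward_eliminate_by_mard(streams, st_rel$kept, n_repeats,
                                   n_validation, seed, outlier_limit)
  steps <- rbind(steps, tr$steps)
  elimination_trace(steps, surviving = tr$surviving, candidates = codes)
}

#' Serialize an elimination trace as JSON
#'
#' @param trace An `elimination_trace`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "elimination_trace"))
  jsonlite::write_json(list(steps = trace$steps, surviving = trace$surviving,
                            candidates = trace$candidates),
                       path, digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}
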