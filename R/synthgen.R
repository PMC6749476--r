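#' Patient profile for exercise-intensity prescription
#'
#' Holds the demographic quantities needed to convert a percentage exercise
#' intensity into a target heart rate: resting heart rate and the age- and
#' sex-predicted maximum heart rate (`226 - age` for females, `220 - age` for
#' males).
#'
#' @param patient_id Identifier.
#' @param age_years Age in years; study eligibility restricts it to 18--60.
#' @param sex `"male"` or `"female"`.
#' @param resting_hr Resting heart rate in beats per minute, measured at the
#'   start of the experiment; must lie strictly between 0 and the predicted
#'   maximum.
#' @return An object of class `patient_profile`.
#' @export
#' @examples
#' patient_profile("P1", 40, "male", 60)
patient_profile <- function(patient_id, age_years,
                            sex = c("male", "female"), resting_hr) {
  sex <- match.arg(sex)
  stopifnot(length(age_years) == 1, length(resting_hr) == 1)
  if (age_years < 18 || age_years > 60)
    stop("age_years must be within [18, 60]")
  hr_max <- if (sex == "female") 226 - age_years else 220 - age_years
  if (resting_hr <= 0 || resting_hr >= hr_max)
    stop("resting_hr must lie strictly between 0 and hr_max (", hr_max, ")")
  structure(list(patient_id = patient_id, age_years = age_years, sex = sex,
                 resting_hr = resting_hr, hr_max = hr_max),
            class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient_profile %s: %s, %d y, resting HR %g, max HR %g>\n",
              x$patient_id, x$sex, x$age_years, x$resting_hr, x$hr_max))
  invisible(x)
}

#' Target exercise heart rate at a given percentage intensity
#'
#' Linear heart-rate reserve prescription: the target is
#' `intensity/100 * (hr_max - resting_hr) + resting_hr`.
#'
#' @param profile A [patient_profile()].
#' @param intensity_pct Exercise intensity as a percentage of capacity,
#'   in \[0, 100\].
#' @return Target heart rate in beats per minute.
#' @export
#' @examples
#' p <- patient_profile("P1", 40, "male", 60)
#' target_exercise_hr(p, 60) # 132 bpm
target_exercise_hr <- function(profile, intensity_pct) {
  stopifnot(inherits(profile, "patient_profile"))
  if (any(intensity_pct < 0 | intensity_pct > 100))
    stop("intensity_pct must be within [0, 100]")
  intensity_pct / 100 * (profile$hr_max - profile$resting_hr) +
    profile$resting_hr
}

#' Build a study exercise schedule
#'
#' The aerobic routine is three 15-min cycloergometer bouts at 60% capacity
#' separated by 5-min rests (bouts at relative minutes \[0,15), \[20,35),
#' \[40,55)). The anaerobic (resistance) routine is generated for completeness
#' only and is not modeled downstream: five 15-min sets at 70% capacity with
#' 90-s rests.
#'
#' @param kind `"aerobic"` or `"anaerobic"`.
#' @return An `exercise_schedule` with fields `kind`, `bouts` (data frame of
#'   `start_min`, `duration_min`, relative to exercise onset),
#'   `inter_bout_rest_min` and `intensity_pct`.
#' @export
build_schedule <- function(kind = c("aerobic", "anaerobic")) {
  kind <- match.arg(kind)
  if (kind == "aerobic") {
    bouts <- data.frame(start_min = c(0, 20, 40), duration_min = 15)
    rest <- 5
    intensity <- 60
  } else {
    bouts <- data.frame(start_min = (0:4) * 16.5, duration_min = 15)
    rest <- 1.5
    intensity <- 70
  }
  stopifnot(all(diff(bouts$start_min) >= bouts$duration_min[-nrow(bouts)]))
  structure(list(kind = kind, bouts = bouts, inter_bout_rest_min = rest,
                 intensity_pct = intensity), class = "exercise_schedule")
}

#' Default per-signal availability fractions
#'
#' Fraction of minutes each wearable signal is present, mirroring the
#' availability profile observed in clinic (step counting on the Microsoft
#' Band and the chest-strap Polar monitor are the least reliable).
#'
#' @return Named numeric vector over [SIGNAL_CODES], values in \[0, 1\].
#' @export
default_availability <- function() {
  c(FHR = 0.964, FST = 1, FLV = 1, FME = 1, FCA = 1,
    MHR = 0.787, MTM = 0.733, MGS = 0.787, MST = 0.147,
    MMO = 0.733, PHR = 0.553)
}

#' Configuration of the synthetic trial generator
#'
#' @param n_streams Number of data streams (one experiment x one CGM sensor)
#'   to generate. Two consecutive streams share one experiment (two sensors
#'   worn simultaneously); streams are generated independently.
#' @param true_coefficients Named vector, signal code -> generative error
#'   coefficient in mg/dL per signal unit. The CGM error is exactly the
#'   linear combination of the baseline-removed signals with these
#'   coefficients, plus noise. The default couples the error to energy
#'   expenditure (`FME`, METs) and to the skin-temperature drop (`MTM`, raw
#'   device counts) with magnitudes chosen so that exercise inflates MARD by
#'   roughly 4 percentage points over the resting level.
#' @param noise_sd Additional white CGM noise, mg/dL.
#' @param cgm_baseline_error_sd Standard deviation of the exercise-independent
#'   CGM error (AR(1)-smoothed), mg/dL. The default reproduces a resting MARD
#'   of 12--14% at typical glucose levels.
#' @param availability Named vector of per-signal presence fractions in
#'   \[0, 1\]; minutes are dropped i.i.d. per signal.
#' @param pg_trajectory List with `initial_mgdl` (starting plasma glucose),
#'   `exercise_decline` (mg/dL per minute of decline while the exercise window
#'   is active) and `smoothness` (moving-average width, minutes, applied to
#'   the random-walk increments).
#' @param signal_noise_scale Multiplier on all wearable measurement noise;
#'   set 0 for fully deterministic signal shapes.
#' @param exercise_start_min Minute at which the first bout starts.
#' @param duration_min Total trial length in minutes (grid is
#'   `0:duration_min`).
#' @param schedule_kind Passed to [build_schedule()].
#' @param n_faulty_streams Number of streams in which a contiguous block of
#'   ~35% of samples is flagged faulty (so that [qc_filter()] discards them).
#' @param seed Integer; fully determines the generated cohort.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_streams = 27,
                         true_coefficients = c(FME = 1.55, MTM = -0.009),
                         noise_sd = 0,
                         cgm_baseline_error_sd = 20,
                         availability = default_availability(),
                         pg_trajectory = list(initial_mgdl = 145,
                                              exercise_decline = 0.50,
                                              smoothness = 8),
                         signal_noise_scale = 1,
                         exercise_start_min = 59,
                         duration_min = 240,
                         schedule_kind = "aerobic",
                         n_faulty_streams = 0,
                         seed = 1L) {
  stopifnot(n_streams >= 0, noise_sd >= 0, cgm_baseline_error_sd >= 0,
            signal_noise_scale >= 0, n_faulty_streams >= 0,
            n_faulty_streams <= n_streams, duration_min >= 60,
            exercise_start_min >= 0)
  if (length(availability) && (any(availability < 0) || any(availability > 1)))
    stop("availability fractions must be within [0, 1]")
  if (!all(names(availability) %in% SIGNAL_CODES))
    stop("unknown signal code in availability: ",
         paste(setdiff(names(availability), SIGNAL_CODES), collapse = ", "))
  if (length(true_coefficients) &&
      !all(names(true_coefficients) %in% SIGNAL_CODES))
    stop("unknown signal code in true_coefficients")
  stopifnot(is.list(pg_trajectory),
            all(c("initial_mgdl", "exercise_decline", "smoothness") %in%
                  names(pg_trajectory)))
  structure(list(n_streams = as.integer(n_streams),
                 true_coefficients = true_coefficients,
                 noise_sd = noise_sd,
                 cgm_baseline_error_sd = cgm_baseline_error_sd,
                 availability = availability,
                 pg_trajectory = pg_trajectory,
                 signal_noise_scale = signal_noise_scale,
                 exercise_start_min = exercise_start_min,
                 duration_min = as.integer(duration_min),
                 schedule_kind = schedule_kind,
                 n_faulty_streams = as.integer(n_faulty_streams),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Discrete first-order lag toward a target, with separate onset/offset time
# constants (minutes). Signals rise quickly at bout onset and decay at their
# own physiological pace.
first_order <- function(target, tau_on, tau_off) {
  a <- numeric(length(target))
  for (k in seq_along(target)[-1]) {
    tau <- if (target[k] > a[k - 1]) tau_on else tau_off
    a[k] <- a[k - 1] + (target[k] - a[k - 1]) / tau
  }
  a
}

# AR(1)-smoothed gaussian noise with (asymptotic) unit sd.
ar1_noise <- function(n, phi = 0.8) {
  as.numeric(stats::filter(stats::rnorm(n), phi, method = "recursive")) *
    sqrt(1 - phi^2)
}

#' Generate one synthetic exercise trial stream
#'
#' Produces a 1-min-grid trial in which the CGM error is, by construction,
#' the zero-intercept linear model the analysis assumes:
#' `CGM(k) = PG(k) + noise(k) + sum_s p_s * (signal_s(k) - rest baseline of s)`.
#' Plasma glucose follows a smoothed random walk that declines during the
#' exercise window; heart-rate signals rise toward [target_exercise_hr()]
#' during bouts; `FME` (METs) rises above its resting value of 1 during bouts
#' and `FCA`/`FLV` are derived from it; `MTM` (skin temperature, raw counts)
#' drops slowly over the exercise window as sweat evaporates and recovers
#' slowly afterwards; galvanic response and movement rise with bouts; step
#' counts stay near zero (cycloergometer). The reference plasma glucose is
#' reported every 15 minutes. Per-signal minutes are masked missing i.i.d.
#' at `1 - availability`.
#'
#' @param profile A [patient_profile()].
#' @param schedule An [build_schedule()] result; must fit in the trial.
#' @param config A [synth_config()].
#' @param stream_id Identifier for the stream.
#' @param seed Optional integer; if given, seeds the RNG for this stream.
#' @param faulty If `TRUE`, flag a contiguous ~35% block of samples faulty.
#' @return A [trial_stream()] whose attribute `"generative"` records the true
#'   coefficients, the generative rest baselines, the generative error series
#'   and the full-resolution plasma glucose.
#' @export
generate_trial <- function(profile, schedule, config, stream_id = "S01",
                           seed = NULL, faulty = FALSE) {
  stopifnot(inherits(profile, "patient_profile"),
            inherits(schedule, "exercise_schedule"),
            inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  dur <- config$duration_min
  minute <- 0:dur
  n <- length(minute)
  bout_start <- config$exercise_start_min + schedule$bouts$start_min
  bout_end <- bout_start + schedule$bouts$duration_min
  if (max(bout_end) > dur)
    stop("exercise schedule does not fit within the trial duration")
  in_bout <- Reduce(`|`, Map(function(s, e) minute >= s & minute < e,
                             bout_start, bout_end))
  # Exercise period: first bout start through last bout end, inter-bout rests
  # included.
  exercise <- minute >= min(bout_start) & minute < max(bout_end)
  s <- config$signal_noise_scale

  tp <- config$pg_trajectory
  incr <- stats::rnorm(n, 0, 0.9)
  if (tp$smoothness > 1) {
    incr <- as.numeric(stats::filter(incr, rep(1 / tp$smoothness,
                                               tp$smoothness), sides = 1))
    incr[is.na(incr)] <- 0
  }
  pg <- tp$initial_mgdl + cumsum(incr - tp$exercise_decline * exercise)
  pg <- pmax(pg, 60)

  hr_target <- target_exercise_hr(profile, schedule$intensity_pct)
  a_hr <- first_order(as.numeric(in_bout), tau_on = 4, tau_off = 12)
  a_me <- first_order(as.numeric(in_bout), tau_on = 2, tau_off = 1.5)
  a_tm <- first_order(as.numeric(exercise), tau_on = 12, tau_off = 25)
  a_gs <- first_order(as.numeric(in_bout), tau_on = 6, tau_off = 18)

  # Per-stream and per-bout physiological draws. Bout-to-bout effort jitter
  # and cardiovascular drift (heart rate creeping up over successive bouts
  # at fixed workload) decouple the heart-rate signals from the energy
  # expenditure signals, as observed between distinct sensing modalities.
  me_peak <- 6.5 + stats::rnorm(1, 0, 0.8)
  me_bout <- stats::rnorm(nrow(schedule$bouts), 0, 1.0)
  hr_drift_bout <- c(0, 6, 12)[seq_len(nrow(schedule$bouts))] +
    stats::rnorm(nrow(schedule$bouts), 0, 6)
  hr_drift_bout[is.na(hr_drift_bout)] <- 0
  mtm_base <- 31000 + stats::rnorm(1, 0, 400)
  mtm_drop <- 1700 + stats::rnorm(1, 0, 200)
  mgs_amp <- 6 + stats::rnorm(1, 0, 2)
  mmo_amp <- 600 + stats::rnorm(1, 0, 80)
  hr_amp <- (hr_target - profile$resting_hr) * (1 + stats::rnorm(1, 0, 0.25) * s)
  hr_wander <- ar1_noise(n, 0.95) * 12 * s
  mtm_wander <- ar1_noise(n, 0.92) * 500 * s  # vasomotor skin-temp drift
  mgs_wander <- ar1_noise(n, 0.92) * 1.5 * s

  bout_of <- rep(NA_integer_, n)
  for (b in seq_len(nrow(schedule$bouts)))
    bout_of[minute >= bout_start[b] & minute < bout_end[b]] <- b
  per_bout <- function(amp) ifelse(is.na(bout_of), 0, amp[bout_of] * s)

  sig <- list()
  sig$FHR <- profile$resting_hr +
    a_hr * (hr_amp + per_bout(hr_drift_bout)) +
    hr_wander + stats::rnorm(n, 0, 2) * s
  sig$MHR <- sig$FHR + stats::rnorm(n, 0, 3) * s
  sig$PHR <- sig$FHR + stats::rnorm(n, 0, 2) * s
  sig$FME <- pmax(1 + a_me * (me_peak - 1 + per_bout(me_bout)) +
                    stats::rnorm(n, 0, 0.25) * s, 0)
  sig$FCA <- pmax(1.2 * sig$FME + stats::rnorm(n, 0, 0.08) * s, 0)
  sig$FLV <- round(pmax(0.45 * (sig$FME - 1) + stats::rnorm(n, 0, 0.25) * s, 0))
  sig$MTM <- mtm_base - a_tm * mtm_drop + mtm_wander +
    stats::rnorm(n, 0, 40) * s
  sig$MGS <- pmax(2 + mgs_amp * a_gs + mgs_wander +
                    stats::rnorm(n, 0, 2) * s, 0)
  sig$MMO <- pmax(mmo_amp * a_me + stats::rnorm(n, 0, 350) * s, 0)
  sig$FST <- round(s * (!in_bout) * stats::rbinom(n, 1, 0.05) *
                     stats::rexp(n, 1 / 12))
  sig$MST <- round(s * (!in_bout) * stats::rbinom(n, 1, 0.05) *
                     stats::rexp(n, 1 / 12))

  baselines <- c(FHR = profile$resting_hr, FST = 0, FLV = 0, FME = 1,
                 FCA = 1.2, MHR = profile$resting_hr, MTM = mtm_base,
                 MGS = 2, MST = 0, MMO = 0, PHR = profile$resting_hr)
  err <- numeric(n)
  for (code in names(config$true_coefficients))
    err <- err + config$true_coefficients[[code]] *
      (sig[[code]] - baselines[[code]])
  cgm <- pg + ar1_noise(n, 0.8) * config$cgm_baseline_error_sd + err +
    stats::rnorm(n, 0, config$noise_sd)

  for (code in SIGNAL_CODES) {
    avail <- if (code %in% names(config$availability))
      config$availability[[code]] else 1
    if (avail < 1) sig[[code]][stats::runif(n) >= avail] <- NA
  }

  faulty_flag <- integer(n)
  if (faulty) {
    len <- ceiling(0.35 * n)
    start <- sample.int(n - len + 1L, 1L)
    faulty_flag[start:(start + len - 1L)] <- 1L
  }

  dat <- data.frame(minute = minute, cgm_mgdl = cgm,
                    pg_mgdl = ifelse(minute %% 15L == 0L, pg, NA_real_),
                    exercise = as.integer(exercise))
  for (code in SIGNAL_CODES) dat[[code]] <- sig[[code]]
  dat$faulty <- faulty_flag
  trial_stream(stream_id, dat,
               generative = list(true_coefficients = config$true_coefficients,
                                 baselines = baselines, error = err,
                                 pg_full = pg, profile = profile))
}

#' Generate a synthetic exercise-trial cohort
#'
#' Builds six patient profiles (ages around 37 +/- 9 years, one female, as in
#' a small T1D exercise cohort) and generates `n_streams` trial streams, two
#' consecutive streams per experiment (two CGM sensors worn simultaneously,
#' modeled as independent). The configuration seed fully determines the
#' output; the same config yields an identical cohort.
#'
#' @param config A [synth_config()].
#' @return A list of [trial_stream()] objects (empty if `n_streams` is 0).
#' @export
#' @examples
#' streams <- generate_cohort(synth_config(n_streams = 2, seed = 7))
#' length(streams)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ages <- round(pmin(pmax(stats::rnorm(6, 36.7, 8.9), 18), 60))
  sexes <- c("female", rep("male", 5))
  rhr <- round(stats::rnorm(6, 62, 5))
  profiles <- lapply(1:6, function(i)
    patient_profile(sprintf("P%d", i), ages[i], sexes[i], rhr[i]))
  schedule <- build_schedule(config$schedule_kind)
  if (config$n_streams == 0L) return(list())
  faulty_idx <- if (config$n_faulty_streams > 0L)
    sort(sample.int(config$n_streams, config$n_faulty_streams))
  else integer(0)
  lapply(seq_len(config$n_streams), function(i) {
    expid <- (i + 1L) %/% 2L
    sensor <- 2L - i %% 2L
    generate_trial(profiles[[(expid - 1L) %% 6L + 1L]], schedule, config,
                   stream_id = sprintf("E%02d_C%d", expid, sensor),
                   seed = derive_seed(config$seed, sprintf("stream%03d", i)),
                   faulty = i %in% faulty_idx)
  })
}
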