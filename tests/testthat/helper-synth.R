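# Small builders shared across the test files.

# A deterministic, noise-free configuration: signal shapes are pure first-order
# responses, no missingness, no CGM noise.
noise_free_config <- function(n_streams = 2, coefs = c(FME = 1.55, MTM = -0.009),
                              seed = 1) {
  synth_config(n_streams = n_streams, true_coefficients = coefs,
               noise_sd = 0, cgm_baseline_error_sd = 0,
               availability = stats::setNames(rep(1, length(SIGNAL_CODES)),
                                              SIGNAL_CODES),
               signal_noise_scale = 0, seed = seed)
}

default_profile <- function() patient_profile("P1", 40, "male", 60)

# One tiny hand-built trial stream on a 30-min grid: reference samples at
# minutes 0, 15, 30; a 10-min exercise block at minutes 10-19.
tiny_stream <- function(stream_id = "T1", cgm_at_ref = c(120, 130, 95),
                        pg_at_ref = c(100, 110, 100)) {
  minute <- 0:30
  pg <- rep(NA_real_, 31)
  pg[minute %% 15 == 0] <- pg_at_ref
  cgm <- rep(110, 31)
  cgm[minute %% 15 == 0] <- cgm_at_ref
  d <- data.frame(minute = minute, cgm_mgdl = cgm, pg_mgdl = pg,
                  exercise = as.integer(minute >= 10 & minute < 20),
                  FME = rep(1, 31), MTM = rep(31000, 31))
  trial_stream(stream_id, d)
}

# In-bout minute mask for a generated stream under the aerobic schedule with
# the given exercise start (inter-bout rests excluded).
minute_in_bout <- function(stream, start = 59) {
  m <- stream$data$minute
  sched <- build_schedule("aerobic")
  Reduce(`|`, Map(function(s, e) m >= s & m < e,
                  start + sched$bouts$start_min,
                  start + sched$bouts$start_min + sched$bouts$duration_min))
}

# Pooled baseline-removed paired samples of a cohort.
cohort_pairs <- function(config) {
  prepped <- lapply(generate_cohort(config), remove_baseline)
  do.call(rbind, lapply(prepped, pair_with_reference))
}
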