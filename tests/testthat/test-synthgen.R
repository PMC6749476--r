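test_that("target exercise heart rate follows the heart-rate-reserve formula", {
  male40 <- patient_profile("P1", 40, "male", 60)
  expect_equal(male40$hr_max, 180)
  expect_equal(target_exercise_hr(male40, 60), 132)
  female26 <- patient_profile("P2", 26, "female", 70)
  expect_equal(female26$hr_max, 200)
  expect_equal(target_exercise_hr(female26, 70), 161)
  expect_equal(target_exercise_hr(male40, 0), 60)
  expect_equal(target_exercise_hr(male40, 100), male40$hr_max)
  # monotone in intensity and bounded by [resting, max]
  hr <- target_exercise_hr(male40, seq(0, 100, by = 5))
  expect_true(all(diff(hr) > 0))
  expect_true(all(hr >= 60 & hr <= 180))
  expect_error(target_exercise_hr(male40, 120), "intensity")
  expect_error(patient_profile("P3", 70, "male", 60), "age")
  expect_error(patient_profile("P4", 40, "male", 200), "resting_hr")
})

test_that("aerobic and anaerobic schedules match the study protocol", {
  aer <- build_schedule("aerobic")
  expect_equal(aer$bouts$start_min, c(0, 20, 40))
  expect_equal(unique(aer$bouts$duration_min), 15)
  expect_equal(aer$inter_bout_rest_min, 5)
  expect_equal(aer$intensity_pct, 60)
  expect_equal(sum(aer$bouts$duration_min), 45)
  # total exercise window (first start to last end)
  expect_equal(max(aer$bouts$start_min + aer$bouts$duration_min), 55)
  ana <- build_schedule("anaerobic")
  expect_equal(ana$intensity_pct, 70)
  expect_equal(nrow(ana$bouts), 5)
  expect_equal(ana$inter_bout_rest_min, 1.5)
  expect_error(build_schedule("swimming"))
})

test_that("noise-free generation reproduces the generative error model exactly", {
  # all coefficients zero, no noise: CGM equals PG everywhere
  cfg0 <- noise_free_config(coefs = c(FME = 0, MTM = 0))
  s <- generate_cohort(cfg0)[[1]]
  g <- attr(s, "generative")
  expect_equal(s$data$cgm_mgdl, g$pg_full)
  ref <- !is.na(s$data$pg_mgdl)
  expect_equal(s$data$cgm_mgdl[ref], s$data$pg_mgdl[ref])

  # nonzero coefficients: CGM - PG equals Theta %*% p at machine precision,
  # with Theta the signals minus their generative rest baselines
  cfg <- noise_free_config(coefs = c(FME = 1.55, MTM = -0.009, FHR = 0.1))
  s <- generate_cohort(cfg)[[1]]
  g <- attr(s, "generative")
  theta_p <- 1.55 * (s$data$FME - g$baselines[["FME"]]) +
    -0.009 * (s$data$MTM - g$baselines[["MTM"]]) +
    0.1 * (s$data$FHR - g$baselines[["FHR"]])
  expect_equal(s$data$cgm_mgdl - g$pg_full, theta_p, tolerance = 1e-12)
  expect_equal(g$error, theta_p, tolerance = 1e-12)
})

test_that("generated in-bout error matches the configured coefficients on average", {
  # Monte-Carlo check over >= 1e4 in-bout minutes, coefficient magnitudes of
  # the all-data fit scale
  cfg <- synth_config(n_streams = 250, seed = 42,
                      true_coefficients = c(FME = 0.3, MTM = -0.005),
                      noise_sd = 4, cgm_baseline_error_sd = 0,
                      availability = c(MST = 0.147))
  streams <- generate_cohort(cfg)
  acc <- lapply(streams, function(s) {
    g <- attr(s, "generative")
    sched <- minute_in_bout(s)
    data.frame(err = s$data$cgm_mgdl[sched] - g$pg_full[sched],
               dFME = s$data$FME[sched] - g$baselines[["FME"]],
               dMTM = s$data$MTM[sched] - g$baselines[["MTM"]])
  })
  df <- do.call(rbind, acc)
  expect_gt(nrow(df), 1e4)
  expect_equal(mean(df$err), 0.3 * mean(df$dFME) - 0.005 * mean(df$dMTM),
               tolerance = 0.02)

  # missingness rate converges to the configured availability (binomial tol)
  mst <- unlist(lapply(streams, function(s) s$data$MST))
  frac_present <- mean(!is.na(mst))
  expect_equal(frac_present, 0.147,
               tolerance = 4 * sqrt(0.147 * 0.853 / length(mst)) / 0.147)
})

test_that("cohort generation is deterministic and respects n_streams", {
  cfg <- synth_config(n_streams = 27, seed = 1)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_length(c1, 27)
  expect_length(generate_cohort(synth_config(n_streams = 0)), 0)
  # different seed produces different data
  c3 <- generate_cohort(synth_config(n_streams = 27, seed = 2))
  expect_false(identical(c1[[1]]$data$cgm_mgdl, c3[[1]]$data$cgm_mgdl))
})

test_that("signal shapes behave as their physiology dictates", {
  cfg <- synth_config(n_streams = 2, seed = 9,
                      availability = c(MST = 1), n_faulty_streams = 0)
  s <- generate_cohort(cfg)[[1]]
  d <- s$data
  bout <- minute_in_bout(s)
  rest_pre <- d$minute < cfg$exercise_start_min
  # heart rate and METs rise during bouts; steps stay ~0 on a cycloergometer
  expect_gt(mean(d$FHR[bout], na.rm = TRUE), mean(d$FHR[rest_pre], na.rm = TRUE) + 30)
  expect_gt(mean(d$FME[bout], na.rm = TRUE), 3)
  expect_lt(stats::median(d$FST[bout], na.rm = TRUE), 1)
  # skin temperature drops during the exercise window
  expect_lt(mean(d$MTM[d$exercise == 1], na.rm = TRUE),
            mean(d$MTM[rest_pre], na.rm = TRUE))
  # galvanic response and movement rise with bouts
  expect_gt(mean(d$MGS[bout], na.rm = TRUE), mean(d$MGS[rest_pre], na.rm = TRUE))
  expect_gt(mean(d$MMO[bout], na.rm = TRUE), mean(d$MMO[rest_pre], na.rm = TRUE))
  # exercise mask covers first bout start to last bout end
  expect_equal(sum(d$exercise), 55)
})
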