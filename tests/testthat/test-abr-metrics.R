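test_that("baseline statistics follow the sample-SD convention", {
  w <- make_waveform(rep(5, 50))
  b <- baseline_stats(w, c(0, 1))
  expect_equal(b$mean, 5)
  expect_equal(b$sd, 0)

  w2 <- waveform(c(0, 0.5), c(1, -1), 50)
  b2 <- baseline_stats(w2, c(0, 1))
  expect_equal(b2$mean, 0)
  expect_equal(b2$sd, sqrt(2))
  b2p <- baseline_stats(w2, c(0, 1), sd_type = "population")
  expect_equal(b2p$sd, 1)

  set.seed(1)
  w3 <- make_waveform(rnorm(10000), rate = 1000)
  b3 <- baseline_stats(w3, c(0, 10))
  expect_gt(b3$sd, 0.97)
  expect_lt(b3$sd, 1.03)

  expect_error(baseline_stats(w, c(2, 1)), "interval")
})

test_that("response detection gates on window, run length and criterion", {
  b <- structure(list(mean = 0, sd = 1, window = c(0, 1), n = 24),
                 class = "baseline_stats")
  flat <- make_waveform(rep(0, 244))
  expect_false(as.logical(detect_response(flat, b)))

  ## single supra-criterion sample inside the window
  v <- rep(0, 244)
  v[round(2.5 * 24.4)] <- 3
  expect_true(as.logical(detect_response(make_waveform(v), b,
                                         min_run = 1)))
  expect_false(as.logical(detect_response(make_waveform(v), b,
                                          min_run = 2)))
  ## same excursion at 1.0 ms: outside the 1.4-5 ms window
  v2 <- rep(0, 244)
  v2[round(1.0 * 24.4)] <- 3
  expect_false(as.logical(detect_response(make_waveform(v2), b,
                                          min_run = 1)))

  ## degenerate baseline: any deviation counts, and is flagged
  b0 <- structure(list(mean = 0, sd = 0, window = c(0, 1), n = 24),
                  class = "baseline_stats")
  r <- detect_response(make_waveform(v), b0)
  expect_true(as.logical(r))
  expect_true(attr(r, "degenerate_baseline"))
  r0 <- detect_response(flat, b0)
  expect_false(as.logical(r0))
})

test_that("detection agrees with the exhaustive brute-force scan", {
  set.seed(42)
  b <- structure(list(mean = 0, sd = 1, window = c(0, 1), n = 24),
                 class = "baseline_stats")
  for (i in 1:200) {
    v <- rnorm(244, sd = runif(1, 0.5, 3))
    w <- make_waveform(v)
    for (mr in c(1, 3, 5)) {
      expect_identical(
        as.logical(detect_response(w, b, min_run = mr)),
        oracle_detect(w, b, min_run = mr))
    }
  }
})

test_that("raising the criterion multiplier never creates a response", {
  set.seed(7)
  b <- structure(list(mean = 0, sd = 1, window = c(0, 1), n = 24),
                 class = "baseline_stats")
  for (i in 1:50) {
    w <- make_waveform(rnorm(244, sd = 2))
    calls <- vapply(c(1, 1.5, 2, 2.5, 3), function(k)
      as.logical(detect_response(w, b, k = k, min_run = 3)), logical(1))
    ## once false at some k, must stay false for every larger k
    expect_true(all(calls == cummin(calls)))
  }
})

test_that("threshold is the lowest responding level, with censoring", {
  mk_series <- function(responding) {
    wfs <- lapply(seq_along(responding), function(i) {
      v <- rep(0, 244)
      if (responding[i]) v[40:60] <- 5
      waveform((0:243) / 24.4, v, i * 10)
    })
    abr_series(wfs)
  }
  r <- estimate_threshold(mk_series(c(F, F, T, T, T, T, T, T, T)))
  expect_equal(r$threshold, 30)
  expect_false(r$censored)
  expect_true(r$calls[["30"]])

  r2 <- estimate_threshold(mk_series(rep(FALSE, 9)))
  expect_true(r2$censored)
  expect_true(is.na(r2$threshold))

  ## spurious low-level call: minimal vs monotone policy
  r3 <- estimate_threshold(mk_series(c(F, T, F, T, T, T, T, T, T)))
  expect_equal(r3$threshold, 20)
  r4 <- estimate_threshold(mk_series(c(F, T, F, T, T, T, T, T, T)),
                           policy = "monotone")
  expect_equal(r4$threshold, 40)
})

test_that("wave metrics recover a constructed biphasic transient", {
  t_grid <- seq(0, 10, by = 0.05)
  v <- approx(c(0, 1.5, 2.0, 2.5, 3.0, 10), c(0, 0, -2, 3, 0, 0),
              xout = t_grid)$y
  w <- waveform(t_grid, v, 80)
  m <- wave_metrics(w)
  expect_equal(nrow(m), 1)
  expect_equal(m$latency_ms, 2.5)
  expect_equal(m$trough_ms, 2.0)
  expect_equal(m$amplitude_uv, 5)

  ## pure noise below the prominence floor yields nothing
  set.seed(3)
  wn <- make_waveform(rnorm(244, sd = 0.1))
  bn <- baseline_stats(wn)
  mn <- wave_metrics(wn, prominence = 10 * bn$sd)
  expect_equal(nrow(mn), 0)
})

test_that("simulated wave latency and amplitude are recovered", {
  cfg <- abr_sim_config(true_threshold = 30, noise_sd = 0.01, seed = 5)
  sim <- simulate_abr_series(cfg)
  w90 <- sim$series$waveforms[[9]]
  truth <- sim$truth$waves[sim$truth$waves$level_db == 90, ]
  m <- wave_metrics(w90, prominence = 0.3)
  ## the largest measured wave should sit at the largest rendered wave
  big <- m[which.max(m$amplitude_uv), ]
  big_true <- truth[which.max(truth$amplitude_uv), ]
  expect_lt(abs(big$latency_ms - big_true$latency_ms), 0.25)
  expect_lt(abs(big$amplitude_uv - big_true$amplitude_uv),
            0.1 * big_true$amplitude_uv + 2 * cfg$noise_sd)
})

test_that("threshold shifts subtract the day-0 baseline and propagate censoring", {
  thr <- data.frame(
    animal = rep(c("a1", "a2"), each = 3),
    group = "AT",
    timepoint_day = rep(c(0, 13, 26), 2),
    threshold_db = c(10, 40, 10, 10, NA, 20))
  s <- threshold_shift_table(thr)
  expect_equal(s$shift_db[s$animal == "a1" & s$timepoint_day == 13], 30)
  expect_equal(s$shift_db[s$animal == "a1" & s$timepoint_day == 0], 0)
  expect_true(s$censored[s$animal == "a2" & s$timepoint_day == 13])
  expect_equal(s$shift_db[s$animal == "a2" & s$timepoint_day == 26], 10)

  ## identical thresholds: all shifts zero
  thr2 <- data.frame(animal = "a", group = "SC",
                     timepoint_day = c(0, 13, 26),
                     threshold_db = c(10, 10, 10))
  expect_true(all(threshold_shift_table(thr2)$shift_db == 0))

  ## animal without baseline is excluded with a warning
  thr3 <- rbind(thr, data.frame(animal = "a3", group = "AT",
                                timepoint_day = 13, threshold_db = 30))
  expect_warning(s3 <- threshold_shift_table(thr3), "a3")
  expect_false("a3" %in% s3$animal)
})

test_that("zero-phase bandpass preserves the time grid and attenuates drift", {
  set.seed(11)
  t_grid <- (0:999) / 24.4
  drift <- sin(2 * pi * 0.01 * t_grid)        # ~10 Hz, below band
  v <- drift + rnorm(1000, sd = 0.01)
  w <- waveform(t_grid, v, 50)
  f <- bandpass_waveform(w)
  expect_equal(f$time, w$time)
  expect_lt(stats::sd(f$voltage), stats::sd(w$voltage) / 2)
})
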