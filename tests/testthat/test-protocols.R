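# Protocol analysis: S2/S1 restitution, AERP, SNRT, episodes, flux rates.

test_that("S2/S1 ratio follows its definition on constructed amplitudes", {
  amp <- array(NA_real_, c(5, 8, 8))
  for (b in 1:4) amp[b, , ] <- 1
  amp[5, , ] <- 0.5
  lab <- data.frame(type = c(rep("S1", 4), "S2"), train = 1L,
                    interval = c(rep(NA, 4), 60))
  rr <- s2s1_ratio(amp, lab)
  expect_equal(rr$ratio, 0.5)
  expect_true(rr$captured)
})

test_that("generator S2/S1 ratios match the closed-form recovery", {
  sim <- quick_sim(grid = 12, beats = 4, aerp = 30,
                   params = restitution_params(apd_max = 45, tau_rest = 40,
                                               cat_amp_tau_refr = 60,
                                               cat_decay_tau = 0.01,
                                               cat90_scale = 1),
                   mode = "S1S2_extrastimulus",
                   s2_intervals = c(150, 90, 60))
  mc <- spatial_gaussian3(sim$calcium)
  wins <- segment_beats(mc)
  sched <- sim$truth$schedule
  lab <- data.frame(type = sched$type, train = sched$train,
                    interval = sched$interval)
  rr <- s2s1_ratio(beat_amplitudes(mc, wins), lab,
                   sites = list(c(3, 3), c(3, 9), c(9, 3), c(9, 9)))
  expect_equal(rr$ratio[rr$interval == 60], 1 - exp(-1), tolerance = 0.02)
  expect_gt(rr$ratio[rr$interval == 150], 0.9)   # full recovery limit
  expect_true(all(diff(rr$ratio[order(rr$interval)]) > 0))  # monotone
  expect_equal(unname(vapply(rr[1, paste0("site", 1:4)], c, 0)),
               rep(rr$ratio[1], 4), tolerance = 0.05)
})

test_that("restitution fit recovers noiseless parameters within 1%", {
  d <- c(150, 120, 90, 70, 60, 50, 40)
  y <- 0.95 * (1 - exp(-(d - 10) / 60))
  f <- fit_restitution(d, y)
  expect_true(f$converged)
  expect_lt(abs(f$tau_r - 60) / 60, 0.01)
  expect_lt(abs(f$A - 0.95) / 0.95, 0.01)
  expect_lt(abs(f$d0 - 10), 1)
  # steeper generator tau -> larger steepness statistic
  y40 <- 0.95 * (1 - exp(-(d - 10) / 40))
  f40 <- fit_restitution(d, y40)
  expect_gt(f40$steepness, f$steepness)
})

test_that("degenerate restitution curves are flagged", {
  f <- fit_restitution(c(40, 60, 80, 100), rep(0.8, 4))
  expect_false(f$converged)
  expect_match(f$flag, "unidentifiable")
  expect_equal(f$A, 0.8)
  expect_error(fit_restitution(c(40, 60, 80), c(0.5, 0.6, 0.7)), "4 captured")
})

test_that("AERP is the longest non-capturing interval, with range bounds", {
  ints <- seq(150, 30, by = -10)
  cap <- ints >= 70
  r <- aerp_from_s1s2(ints, cap)
  expect_equal(r$aerp, 60)
  expect_equal(r$status, "ok")
  all_cap <- aerp_from_s1s2(ints, rep(TRUE, length(ints)))
  expect_true(is.na(all_cap$aerp))
  expect_equal(all_cap$status, "below_range")
  expect_match(all_cap$bound, "30")
})

test_that("movie-level AERP error is bounded by the S2 step", {
  sim <- quick_sim(grid = 10, beats = 3, aerp = 55,
                   mode = "S1S2_extrastimulus",
                   s2_intervals = seq(70, 40, by = -5))
  mv <- spatial_gaussian3(sim$voltage)
  wins <- segment_beats(mv)
  amp <- beat_amplitudes(mv, wins)
  sched <- sim$truth$schedule
  wos <- match(round(sched$time_ms, 6), round(wins$ref_time_ms, 6))
  cap <- detect_capture(amp, ref_beats = wos[sched$type == "S1" &
                                             sched$train == 1])
  s2 <- which(sched$type == "S2")
  r <- aerp_from_s1s2(sched$interval[s2], cap[wos[s2]])
  expect_equal(r$status, "ok")
  expect_lte(abs(r$aerp - 55), 5)
})

test_that("SNRT definitions: raw minus baseline gives corrected", {
  r <- snrt(c(350, 550), last_stim = 0, baseline_cl = 200)
  expect_equal(r$snrt_raw, 350)
  expect_equal(r$snrt_corrected, 150)
  r0 <- snrt(c(200), 0, 200)
  expect_equal(r0$snrt_corrected, 0)
  miss <- snrt(c(100), last_stim = 100, baseline_cl = 200)
  expect_true(is.na(miss$snrt_raw))
  expect_equal(miss$flag, "no_spontaneous_beat")
})

test_that("episode detector ignores regular rhythm and short runs", {
  reg <- seq(0, 4000, by = 200)
  rep0 <- detect_episodes(reg, 200)
  expect_equal(nrow(rep0$episodes), 0)
  expect_false(rep0$induced)
  # 3 rapid irregular cycles only: below the 5-cycle minimum
  t3 <- c(seq(0, 2000, by = 200), 2090, 2160, 2255,
          seq(2455, 4000, by = 200))
  expect_equal(nrow(detect_episodes(t3, 200)$episodes), 0)
})

test_that("episode boundaries are recovered within two cycle lengths", {
  tr <- simulate_af_trace(200, list(list(start = 3000, end = 8000,
                                         mean_cl = 80, cl_jitter = 12)),
                          duration = 15000, seed = 31)
  rep1 <- detect_episodes(tr$activation_times, 200)
  expect_equal(nrow(rep1$episodes), 1)
  expect_lt(abs(rep1$episodes$onset - 3000), 2 * 200)
  expect_lt(abs(rep1$episodes$offset - 8000), 2 * 200)
  expect_equal(rep1$total_duration_s, 5, tolerance = 0.1)
})

test_that("episode detector is sensitive and specific over seeded runs", {
  hits <- 0; false_runs <- 0
  for (s in 1:40) {
    tr <- simulate_af_trace(200, list(list(start = 2000, end = 7000,
                                           mean_cl = 80, cl_jitter = 12)),
                            duration = 12000, seed = s)
    det <- detect_episodes(tr$activation_times, 200)
    if (det$induced) hits <- hits + 1
    quiet <- simulate_af_trace(200, list(), duration = 12000,
                               seed = 1000 + s)
    if (detect_episodes(quiet$activation_times, 200)$induced) {
      false_runs <- false_runs + 1
    }
  }
  expect_gte(hits / 40, 0.95)
  expect_lte(false_runs / 40, 0.05)
})

test_that("flux rates recover constructed release and reuptake constants", {
  # linear upstroke 0 -> 1 over 0.02 s: derivative 50/s
  caff <- data.frame(time = seq(0, 0.1, by = 0.001))
  caff$value <- pmin(caff$time / 0.02, 1)
  rec <- data.frame(time = seq(0.5, 20, length.out = 12))
  rec$amplitude <- 1 - exp(-rec$time / 4)
  fx <- flux_rates(caff, rec)
  expect_lt(abs(fx$ryr2_rate - 50) / 50, 0.05)
  expect_lt(abs(fx$serca_rate_inv - 4) / 4, 0.02)
  expect_length(fx$flags, 0)
})

test_that("flat caffeine responses are flagged", {
  caff <- data.frame(time = seq(0, 0.1, by = 0.001), value = 0.01)
  rec <- data.frame(time = seq(0.5, 20, length.out = 12))
  rec$amplitude <- 1 - exp(-rec$time / 4)
  fx <- flux_rates(caff, rec)
  expect_true(any(grepl("flat", fx$flags)))
  expect_true(is.na(fx$ryr2_rate))
})
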