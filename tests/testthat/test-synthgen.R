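# Synthetic generator: waveform families, restitution map, movie and
# trace simulators, dose-response tables.

test_that("AP waveform makes the operational APD90 definition exact", {
  for (prm in list(c(50, 10, 1), c(85.42, 26.21, FP900),
                   c(36.53, 12.51, FP900))) {
    b <- make_ap_waveform(prm[1], prm[2], prm[3])
    w <- full_window(b$trace)
    at <- activation_time(b$trace, w, prm[3])
    expect_lt(abs(as.numeric(at) - b$activation_ms), 0.5 * prm[3])
    apd <- duration_at_level(b$trace, w, at, 0.9, prm[3])
    expect_lt(abs(apd - prm[1]), prm[3])  # within one frame
  }
})

test_that("AP duration is invariant to amplitude scaling", {
  b <- make_ap_waveform(50, 10, 1)
  w <- full_window(b$trace)
  apd1 <- duration_at_level(b$trace, w, activation_time(b$trace, w, 1),
                            0.9, 1)
  tr3 <- 3 * b$trace
  apd3 <- duration_at_level(tr3, w, activation_time(tr3, w, 1), 0.9, 1)
  expect_equal(apd1, apd3)
})

test_that("AP waveform rejects invalid parameter orderings", {
  expect_error(make_ap_waveform(50, 60, 1), "invalid")
  expect_error(make_ap_waveform(50, 10, 6), "invalid")
  expect_error(make_ap_waveform(-5, 10, 1), "positive")
})

test_that("CaT waveform decay constant is recovered by the tau estimator", {
  for (tau in c(0.08, 0.01)) {
    cb <- make_cat_waveform(60 + 1000 * tau * log(10), 10, tau, FP900)
    tt <- decay_tau(cb$trace, full_window(cb$trace), FP900)
    expect_lt(abs(as.numeric(tt) - tau) / tau, 0.02)
    expect_true(attr(tt, "reliable"))
  }
})

test_that("CaT waveform errors when 90% recovery is unreachable", {
  # cat90 shorter than rise/2 + tau*ln(10) cannot reach 90% recovery
  expect_error(make_cat_waveform(50, 10, 0.08, 1), "unreachable")
})

test_that("restitution map is flat when tau_rest is tiny", {
  p <- restitution_params(apd_max = 100, tau_rest = 1e-6)
  s <- iterate_restitution(p, 200, 20, apd_init = 30)
  expect_equal(s, rep(100, 20), tolerance = 1e-9)
})

test_that("perturbations decay geometrically at map slope 0.5", {
  # pick CL so that the fixed-point slope is 0.5, then inject a small
  # perturbation and compare with the closed-form linear prediction
  p <- restitution_params(apd_max = 100, tau_rest = 50)
  # slope(DI) = 2 exp(-DI/50) = 0.5 at DI = 50*log(4)
  di_star <- 50 * log(4)
  apd_star <- 100 * (1 - exp(-di_star / 50))
  cl <- di_star + apd_star
  fx <- restitution_slope(p, cl)
  expect_equal(fx$slope, 0.5, tolerance = 1e-6)
  eps <- 0.01
  s <- iterate_restitution(p, cl, 6, apd_init = apd_star + eps)
  dev <- abs(s - apd_star)
  # deviation shrinks by the slope each beat (alternating sign)
  for (i in 1:5) {
    expect_equal(dev[i + 1] / dev[i], 0.5, tolerance = 0.02)
  }
})

test_that("period-2 orbit matches brute-force iteration", {
  p <- restitution_params(apd_max = 120, tau_rest = 40)
  expect_gt(restitution_slope(p, 80)$slope, 1)
  # independent brute-force oracle
  f <- function(a) 120 * (1 - exp(-max(80 - a, 5) / 40))
  x <- 60
  for (i in 1:10000) x <- f(x)
  orbit_oracle <- sort(c(x, f(x)))
  s <- iterate_restitution(p, 80, 10000, apd_init = 60)
  orbit <- sort(tail(s, 2))
  expect_equal(orbit, orbit_oracle, tolerance = 1e-9)
  expect_gt(diff(orbit_oracle), 10)  # genuine alternans amplitude
})

test_that("restitution map stability matches linear theory", {
  p <- restitution_params(apd_max = 120, tau_rest = 40)
  for (cl in seq(60, 160, by = 10)) {
    sl <- restitution_slope(p, cl)$slope
    if (abs(sl - 1) < 0.05) next  # skip the bifurcation neighbourhood
    s <- tail(iterate_restitution(p, cl, 500), 10)
    amp <- max(s) - min(s)
    if (sl < 1) expect_lt(amp, 1e-3) else expect_gt(amp, 1)
  }
})

test_that("iterate_restitution rejects degenerate requests", {
  expect_error(iterate_restitution(restitution_params(), 100, 1), "n_beats")
})

test_that("movie geometry: far-corner activation delay matches distance/CV", {
  sim <- quick_sim(grid = 16, cv = 0.5, beats = 4)
  mv <- spatial_gaussian3(sim$voltage)
  wins <- segment_beats(mv)
  fs <- measure_beats(mv, wins)
  act <- feature_map(fs, "activation", 2)
  expected <- sqrt(2) * 15 * 0.1 / 0.5
  expect_lt(abs((act[16, 16] - act[1, 1]) - expected), FP900)
})

test_that("noiseless movies reproduce their truth maps within one frame", {
  sim <- quick_sim(grid = 12, beats = 5)
  for (ch in c("voltage", "calcium")) {
    m <- spatial_gaussian3(sim[[ch]])
    wins <- segment_beats(m)
    fs <- measure_beats(m, wins)
    truth <- if (ch == "voltage") sim$truth$apd90_ms else sim$truth$cat90_ms
    for (b in 2:4) {
      expect_lt(max(abs(feature_map(fs, "d90", b) - truth[b, , ])), FP900)
      expect_lt(max(abs(feature_map(fs, "activation", b) -
                          sim$truth$activation_ms[b, , ])), FP900)
    }
  }
})

test_that("movies are bit-identical under one seed, different across seeds", {
  s1 <- quick_sim(grid = 8, beats = 3, sigma = 0.05, seed = 42)
  s2 <- quick_sim(grid = 8, beats = 3, sigma = 0.05, seed = 42)
  s3 <- quick_sim(grid = 8, beats = 3, sigma = 0.05, seed = 43)
  expect_identical(s1$voltage$frames, s2$voltage$frames)
  expect_false(identical(s1$voltage$frames, s3$voltage$frames))
})

test_that("premature stimuli below AERP are omitted and flagged", {
  sim <- quick_sim(grid = 8, beats = 3, aerp = 55,
                   mode = "S1S2_extrastimulus",
                   s2_intervals = c(80, 40))
  sched <- sim$truth$schedule
  s2 <- sched[sched$type == "S2", ]
  expect_equal(s2$captured, c(TRUE, FALSE))
  expect_equal(nrow(sim$truth$emitted), nrow(sched) - 1L)
})

test_that("S2 calcium amplitude recovers monotonically with coupling", {
  sim <- quick_sim(grid = 8, beats = 3, aerp = 30,
                   params = restitution_params(cat_amp_tau_refr = 60),
                   mode = "S1S2_extrastimulus",
                   s2_intervals = c(150, 90, 60, 40))
  em <- sim$truth$emitted
  amps <- sim$truth$region_beats[[1]]$amp_cat[em$type == "S2"]
  ints <- em$interval[em$type == "S2"]
  o <- order(ints)
  expect_true(all(diff(amps[o]) >= 0))
  expect_equal(amps, 1 - exp(-ints / 60), tolerance = 1e-9)
})

test_that("four-region phase layout yields opposite-phase truth labels", {
  regs <- quadrant_regions(12, 12, restitution_params(apd_max = 120,
                                                      tau_rest = 40),
                           offset_quadrants = 4L)
  tis <- tissue_spec(12, 12, regions = regs)
  sim <- simulate_movie(tis, protocol_spec("fixed_rate",
                                           s1_cycle_length = 80,
                                           s1_count = 10))
  ph <- vapply(sim$truth$region_alternans, `[[`, 0L, "apd_phase")
  expect_equal(length(unique(ph)), 2L)
  expect_equal(ph[4], -ph[1])
})

test_that("tissue and protocol specifications validate their invariants", {
  expect_error(tissue_spec(4, 4), "8 x 8")
  expect_error(tissue_spec(12, 12, conduction_velocity = -1), "positive")
  bad <- quadrant_regions(12, 12)
  bad[[1]]$mask[1, 1] <- FALSE  # pixel uncovered -> not a partition
  expect_error(tissue_spec(12, 12, regions = bad), "partition")
  expect_error(protocol_spec("S1S2_extrastimulus", s2_intervals = NULL),
               "s2_intervals")
  expect_error(protocol_spec("S1S1_decremental",
                             cl_sequence = c(80, 100)), "decreasing")
  expect_error(noise_spec(-0.1), ">= 0")
})

test_that("AF trace: regular outside episodes, reproducible, validated", {
  tr <- simulate_af_trace(200, list(), duration = 5000, seed = 1)
  expect_equal(unique(diff(tr$activation_times)), 200)
  a <- simulate_af_trace(200, list(list(start = 1000, end = 4000,
                                        mean_cl = 80, cl_jitter = 12)),
                         duration = 10000, seed = 5)
  b <- simulate_af_trace(200, list(list(start = 1000, end = 4000,
                                        mean_cl = 80, cl_jitter = 12)),
                         duration = 10000, seed = 5)
  expect_identical(a$activation_times, b$activation_times)
  expect_error(
    simulate_af_trace(200, list(list(start = 0, end = 3000, mean_cl = 80,
                                     cl_jitter = 10),
                                list(start = 2000, end = 5000,
                                     mean_cl = 80, cl_jitter = 10)),
                      duration = 8000),
    "disjoint")
  expect_error(
    simulate_af_trace(200, list(list(start = 0, end = 3000,
                                     mean_cl = 150, cl_jitter = 10)),
                      duration = 8000),
    "0.6")
})

test_that("dose-response generator obeys the 4PL and its limits", {
  d <- make_dose_response(10, 1, concs = 10)
  expect_equal(d$response, 50)
  dstep <- make_dose_response(10, 200, concs = c(5, 9.9, 10.1, 20))
  expect_lt(dstep$response[1], 1e-6)
  expect_gt(dstep$response[4], 100 - 1e-6)
  d4 <- make_dose_response(8.666, 1.3, concs = c(1, 3, 10, 30))
  fit <- fit_hill(d4$concentration, d4$response, n_boot = 0)
  expect_lt(abs(fit$ic50 - 8.666) / 8.666, 0.01)
})
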