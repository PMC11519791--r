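# Per-beat feature estimators, conduction velocity, heterogeneity.

test_that("activation time is shift-equivariant and tie-flagged", {
  b <- make_ap_waveform(50, 10, 1)
  w <- full_window(b$trace)
  at0 <- activation_time(b$trace, w, 1)
  shifted <- c(rep(0, 7), b$trace)
  at7 <- activation_time(shifted, full_window(shifted), 1)
  expect_equal(as.numeric(at7) - as.numeric(at0), 7)
  # linear ramp upstroke: every frame has the same derivative
  ramp <- c(rep(0, 5), seq(0, 1, length.out = 11), rep(1, 5))
  atr <- activation_time(ramp, full_window(ramp), 1)
  expect_true(attr(atr, "tie"))
  expect_equal(as.numeric(atr), 5, tolerance = 1)  # earliest taken
})

test_that("durations are monotone across levels over random beats", {
  set.seed(10)
  for (i in 1:20) {
    apd <- runif(1, 30, 110); rise <- runif(1, 5, min(25, apd - 5))
    b <- make_ap_waveform(apd, rise, FP900)
    tr <- b$trace + rnorm(length(b$trace), sd = 0.005)
    w <- full_window(tr)
    at <- activation_time(tr, w, FP900)
    d30 <- duration_at_level(tr, w, at, 0.3, FP900)
    d80 <- duration_at_level(tr, w, at, 0.8, FP900)
    d90 <- duration_at_level(tr, w, at, 0.9, FP900)
    expect_true(d30 <= d80 && d80 <= d90)
    expect_lt(abs(d90 - apd), 3 * FP900)
  }
})

test_that("a cut-off beat yields a flagged missing duration", {
  b <- make_ap_waveform(50, 10, 1)
  cut <- b$trace[seq_len(45)]  # truncated before 90% recovery
  w <- full_window(cut)
  at <- activation_time(cut, w, 1)
  d <- duration_at_level(cut, w, at, 0.9, 1)
  expect_true(is.na(d))
  expect_equal(attr(d, "flag"), "not_reached")
  expect_error(duration_at_level(cut, w, at, 1.2, 1), "level")
})

test_that("rise time follows the 10-90% convention", {
  # linear upstroke of 10 ms -> 10-90% spans 8 ms
  tr <- c(rep(0, 5), seq(0, 1, length.out = 11), rep(1, 10),
          seq(1, 0, length.out = 30))
  expect_equal(as.numeric(rise_time(tr, full_window(tr), 1)), 8,
               tolerance = 0.01)
  # one-frame step upstroke: at most one frame
  st <- c(rep(0, 5), rep(1, 10), seq(1, 0, length.out = 20))
  expect_lt(as.numeric(rise_time(st, full_window(st), 1)), 1 + 1e-9)
  # half-cosine upstroke: calibration constant of the waveform family
  b <- make_ap_waveform(80, 20, 0.5)
  cal <- (acos(-0.8) - acos(0.8)) / pi  # 10-90% fraction of the upstroke
  expect_equal(as.numeric(rise_time(b$trace, full_window(b$trace), 0.5)),
               20 * cal, tolerance = 0.5)
})

test_that("decay fitting flags non-exponential decays", {
  tr <- c(rep(0, 4), seq(0, 1, length.out = 8), seq(1, 0, length.out = 60))
  tt <- decay_tau(tr, full_window(tr), 1)
  expect_false(attr(tt, "reliable"))
})

test_that("transition points match construction and shift together", {
  cb <- make_cat_waveform(120, 12, 0.02, FP900)
  w <- full_window(cb$trace)
  tp <- transition_points(cb$trace, w, FP900)
  p <- 120 - 6 - 20 * log(10)
  expect_equal(tp$t_on, 12, tolerance = FP900)
  expect_equal(tp$t30_off, 12 + p + 20 * log(1 / 0.7), tolerance = FP900)
  expect_equal(tp$t_off, 12 + p + 20 * log(10), tolerance = FP900)
  expect_equal(tp$recovery_time, tp$t_off - tp$t_on)
  sh <- c(rep(0, 9), cb$trace)
  tp2 <- transition_points(sh, full_window(sh), FP900)
  for (f in c("t0", "t_on", "t30_off", "t_off")) {
    expect_equal(as.numeric(tp2[[f]]) - as.numeric(tp[[f]]), 9 * FP900,
                 tolerance = 1e-6)
  }
  # monotone trace with no recovery
  mono <- c(seq(0, 1, length.out = 20), rep(1, 20))
  tp3 <- transition_points(mono, full_window(mono), 1)
  expect_true(is.na(tp3$t30_off) && is.na(tp3$t_off))
})

test_that("all time-based features are amplitude-invariant", {
  sim <- quick_sim(grid = 8, beats = 4)
  tr <- sim$voltage$frames[, 4, 4]
  wins <- segment_beats(sim$voltage)
  w <- wins[2, ]
  for (fn in list(
    function(x) as.numeric(activation_time(x, w, FP900)),
    function(x) as.numeric(rise_time(x, w, FP900)),
    function(x) duration_at_level(x, w, activation_time(x, w, FP900),
                                  0.9, FP900))) {
    expect_equal(fn(tr), fn(tr * 7.3), tolerance = 1e-9)
  }
})

test_that("plane-wave conduction velocity is recovered within 5%", {
  for (v in c(0.3, 0.5, 1.0)) {
    m <- plane_wave_movie(grid = 16, speed = v)
    wins <- segment_beats(m)
    fs <- measure_beats(m, wins)
    act <- feature_map(fs, "activation", 1)
    cv <- conduction_velocity(act, 0.1)
    expect_lt(abs(cv$mean_speed - v) / v, 0.05)
    expect_gt(cv$direction_coherence, 0.95)
  }
})

test_that("velocity scales with pixel pitch and is radial for point sources", {
  m <- plane_wave_movie(grid = 16, speed = 0.5)
  fs <- measure_beats(m, segment_beats(m))
  act <- feature_map(fs, "activation", 1)
  cv1 <- conduction_velocity(act, 0.1)
  cv2 <- conduction_velocity(act, 0.2)
  expect_equal(cv2$mean_speed / cv1$mean_speed, 2, tolerance = 1e-9)
  # target wave from a corner source: speed recovered away from the source
  sim <- quick_sim(grid = 16, cv = 0.5, beats = 3)
  fsv <- measure_beats(spatial_gaussian3(sim$voltage),
                       segment_beats(sim$voltage))
  cvr <- conduction_velocity(feature_map(fsv, "activation", 2), 0.1)
  far <- cvr$speed[8:14, 8:14]
  expect_lt(abs(mean(far, na.rm = TRUE) - 0.5) / 0.5, 0.05)
  # radial direction at the far diagonal
  expect_equal(cvr$vx[12, 12], cvr$vy[12, 12], tolerance = 0.1)
})

test_that("IQR heterogeneity follows the type-7 quantile convention", {
  m <- matrix(1:100, 10, 10)
  expect_equal(heterogeneity_iqr(m),
               unname(diff(quantile(1:100, c(0.25, 0.75), type = 7))))
  expect_equal(heterogeneity_iqr(m), 49.5)
  expect_equal(heterogeneity_iqr(matrix(5, 4, 4)), 0)
  expect_equal(heterogeneity_iqr(m + 17.3), heterogeneity_iqr(m))
  expect_error(heterogeneity_iqr(matrix(1, 1, 3)), "4 valid")
})

test_that("map means stay within 2% of truth at noise sigma 0.05", {
  sim <- quick_sim(grid = 12, beats = 5, sigma = 0.05, seed = 11)
  mv <- spatial_gaussian3(sim$voltage)
  fs <- measure_beats(mv, segment_beats(mv))
  d90 <- feature_map(fs, "d90", 3)
  expect_lt(abs(mean(d90) - mean(sim$truth$apd90_ms[3, , ])) /
              mean(sim$truth$apd90_ms[3, , ]), 0.02)
})
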