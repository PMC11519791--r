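# Alternans magnitude, spectral detection, phase and discordance.

test_that("magnitude implements 1 - mean(small)/mean(big)", {
  expect_equal(alternans_magnitude(c(1.0, 0.8, 1.0, 0.8)), 0.2)
  expect_equal(alternans_magnitude(rep(0.7, 8)), 0)
  s <- c(1.1, 0.9, 1.05, 0.88, 1.12, 0.91)
  expect_equal(alternans_magnitude(s * 3.7), alternans_magnitude(s))
  expect_error(alternans_magnitude(c(1, 2, 3)), "4 beats")
  expect_error(alternans_magnitude(c(-1, -2, -1, -2)), "positive")
})

test_that("strict alternation puts all spectral mass at 0.5 cycles/beat", {
  x <- 1 + 0.1 * rep(c(1, -1), 8)
  sp <- spectral_alternans(x)
  # FFT oracle: detrended series is pure (-1)^t, so every non-alternans
  # bin is zero and the alternans bin carries the whole variance
  expect_true(sp$significant)
  expect_gt(sp$z, 100)
  expect_lt(max(sp$spectrum[-length(sp$spectrum)]), 1e-20)
  expect_equal(unname(sp$power), sum(sp$spectrum), tolerance = 1e-12)
})

test_that("period-3 patterns carry no alternans power", {
  x <- rep(c(1, 0, 0), 8)
  sp <- spectral_alternans(x)
  expect_false(sp$significant)
  # the alternans bin carries only detrending leakage, orders of
  # magnitude below the period-3 peak
  expect_lt(sp$power / max(sp$spectrum), 1e-2)
})

test_that("fewer than 8 beats directs the user to the time-domain path", {
  expect_error(spectral_alternans(c(1, 0.8, 1, 0.8)), "alternans_magnitude")
})

test_that("spectral flag and time-domain magnitude agree when noiseless", {
  alt <- 1 + 0.05 * rep(c(1, -1), 6)
  expect_true(spectral_alternans(alt)$significant)
  expect_gt(alternans_magnitude(alt), 0)
  flat <- rep(1, 12)
  expect_false(spectral_alternans(flat)$significant)
  expect_equal(alternans_magnitude(flat), 0)
})

test_that("phase map labels long-short as positive, offset regions negative", {
  n_beats <- 10
  long_short <- 1 + 0.1 * rep(c(1, -1), n_beats / 2)
  mat <- matrix(rep(long_short, 6), nrow = 6, byrow = TRUE)
  expect_equal(phase_map(mat), rep(1L, 6))
  mixed <- rbind(mat[1:4, ],
                 matrix(rep(1 - 0.1 * rep(c(1, -1), n_beats / 2), 2),
                        nrow = 2, byrow = TRUE) + 0.1)
  ph <- phase_map(mixed)
  expect_equal(ph, c(1L, 1L, 1L, 1L, -1L, -1L))
  # nothing significant -> all zero
  set.seed(12)
  noise <- matrix(rnorm(6 * n_beats, mean = 10, sd = 0.001), nrow = 6)
  expect_true(all(phase_map(noise, k_threshold = 50) == 0L))
  bad <- mat; bad[2, 3] <- NA
  expect_error(phase_map(bad), "misaligned")
})

test_that("discordance index spans concordant to balanced", {
  expect_equal(discordance_index(rep(1L, 20)), 0)
  expect_equal(discordance_index(rep(c(1L, -1L), 10)), 1)
  expect_equal(discordance_index(c(rep(1L, 30), rep(-1L, 10))), 0.5)
  expect_true(is.na(discordance_index(rep(0L, 5))))
})

test_that("generator four-region layout gives discordance 1/2", {
  regs <- quadrant_regions(12, 12, restitution_params(),
                           offset_quadrants = 4L, amp_alternans = 0.3)
  tis <- tissue_spec(12, 12, regions = regs)
  sim <- simulate_movie(tis, protocol_spec("fixed_rate",
                                           s1_cycle_length = 120,
                                           s1_count = 14),
                        noise_spec(0.02, 21))
  mc <- spatial_gaussian3(sim$calcium)
  wins <- segment_beats(mc)
  amps <- beat_amplitudes(mc, wins)[5:14, , , drop = FALSE]
  alt <- alternans_analysis(amps, cycle_length = 120)
  expect_true(all(alt$significant))
  expect_equal(alt$discordance, 0.5)
  expect_setequal(unique(as.vector(alt$phase)), c(-1L, 1L))
})

test_that("measured magnitude grows as the cycle length shortens", {
  # steep-restitution tissue whose alternans onset sits inside the swept
  # range: quiescent at CL 100, mild at 80, deep at 60
  p <- restitution_params(apd_max = 100, tau_rest = 50,
                          cat_decay_tau = 0.008, cat90_scale = 1)
  tis <- tissue_spec(12, 12, regions = list(list(
    mask = matrix(TRUE, 12, 12), params = p, phase_offset = 0,
    amp_alternans = NULL)))
  mags <- vapply(c(100, 80, 60), function(cl) {
    sim <- simulate_movie(tis, protocol_spec("fixed_rate",
                                             s1_cycle_length = cl,
                                             s1_count = 14),
                          noise_spec(0.02, 100 + cl))
    mc <- spatial_gaussian3(sim$calcium)
    amps <- beat_amplitudes(mc, segment_beats(mc))[5:14, , , drop = FALSE]
    alternans_analysis(amps, cycle_length = cl)$mean_magnitude
  }, 0)
  expect_true(all(diff(mags) >= -0.02))  # non-decreasing up to noise
  expect_gt(mags[3], mags[1])
})
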