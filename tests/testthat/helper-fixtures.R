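# Shared fixtures: everything is generated in code at test time.

FP900 <- 1000 / 900  # frame period of the default 900 Hz camera, ms

# window covering a whole single-beat trace
full_window <- function(trace) {
  data.frame(start_frame = 1L, end_frame = length(trace),
             ref_time_ms = 0, beat = 1L)
}

# uniform-tissue movie simulation with sensible defaults
quick_sim <- function(grid = 12, cv = 0.5, cl = 167, beats = 6, sigma = 0,
                      seed = 1, aerp = 50, params = restitution_params(),
                      regions = NULL, mode = "fixed_rate", ...) {
  if (is.null(regions)) {
    regions <- list(list(mask = matrix(TRUE, grid, grid), params = params,
                         phase_offset = 0, amp_alternans = NULL))
  }
  tis <- tissue_spec(grid, grid, pixel_pitch = 0.1,
                     conduction_velocity = cv, pacing_site = c(1, 1),
                     regions = regions, aerp_ms = aerp)
  pr <- protocol_spec(mode, s1_cycle_length = cl, s1_count = beats, ...)
  simulate_movie(tis, pr, noise_spec(sigma, seed))
}

# a movie of a plane wave travelling along columns at `speed` mm/ms,
# assembled directly from the waveform evaluator (not via simulate_movie)
plane_wave_movie <- function(grid = 16, speed = 0.5, pitch = 0.1,
                             apd90 = 50, rise = 10, frame_rate = 900) {
  fp <- 1000 / frame_rate
  f <- atriamap:::ap_wave_fun(apd90, rise)
  t_end <- (grid - 1) * pitch / speed + 20 +
    atriamap:::ap_wave_duration(apd90, rise) + 10
  n <- ceiling(t_end / fp)
  tm <- (seq_len(n) - 1) * fp
  arr <- array(0, c(n, grid, grid))
  for (cc in seq_len(grid)) {
    tr <- f(tm - 20 - (cc - 1) * pitch / speed)
    for (r in seq_len(grid)) arr[, r, cc] <- tr
  }
  movie(arr, frame_rate = frame_rate, pixel_pitch = pitch,
        channel = "voltage", stimulus_times = 20)
}
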