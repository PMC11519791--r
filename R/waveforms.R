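# Single-beat waveform primitives used by the synthetic tissue generator.
#
# The action-potential family is piecewise smooth: a half-cosine upstroke of
# duration `rise_time` followed by a cosine-shoulder repolarization whose
# span is solved so that the 90%-repolarization instant falls exactly
# `apd90` after the maximal-upstroke-velocity instant (which for the
# half-cosine upstroke is at rise_time / 2). This makes the operational
# APD90 definition (dF/dt_max to 90% recovery) exact by construction.

# acos(1 - 2 * level) / pi: fractional position of the `level`-recovery
# instant within a cosine shoulder.
shoulder_frac <- function(level) acos(1 - 2 * level) / pi

ap_wave_fun <- function(apd90, rise_time) {
  r <- rise_time
  D <- (apd90 - r / 2) / shoulder_frac(0.9)
  force(r); force(D)
  function(t) {
    v <- numeric(length(t))
    up <- t >= 0 & t <= r
    v[up] <- 0.5 * (1 - cos(pi * t[up] / r))
    rep_ <- t > r & t <= r + D
    v[rep_] <- 0.5 * (1 + cos(pi * (t[rep_] - r) / D))
    v
  }
}

ap_wave_duration <- function(apd90, rise_time) {
  rise_time + (apd90 - rise_time / 2) / shoulder_frac(0.9)
}

# Duration from dF/dt_max to `level` recovery for the AP family
# (closed form; used as generator ground truth for APD30/80/90).
ap_true_duration <- function(apd90, rise_time, level) {
  D <- (apd90 - rise_time / 2) / shoulder_frac(0.9)
  rise_time / 2 + D * shoulder_frac(level)
}

#' Synthesize a single normalized action-potential beat
#'
#' Builds a normalized (0 to 1) single-beat AP trace from a half-cosine
#' upstroke and a cosine-shoulder repolarization, parameterized directly by
#' the operational APD90: the time from the maximal upstroke velocity
#' (dF/dt max, at `rise_time / 2`) to 90% repolarization equals `apd90`
#' exactly.
#'
#' @param apd90 Action-potential duration at 90% repolarization, ms.
#' @param rise_time Full upstroke duration (0 to 100% of amplitude), ms.
#'   Must satisfy `apd90 > rise_time > 2 * frame_period`.
#' @param frame_period Sampling interval, ms (e.g. 1/0.9 for a 900 Hz
#'   camera).
#' @return An object of class `synthetic_beat`: a list with `time` (ms),
#'   `trace` (normalized), the continuous evaluator `fun(t)`,
#'   `activation_ms` (dF/dt-max instant), `duration_ms` (full waveform
#'   span), and the generating parameters.
#' @examples
#' b <- make_ap_waveform(apd90 = 50, rise_time = 10, frame_period = 1)
#' plot(b$time, b$trace, type = "l")
#' @export
make_ap_waveform <- function(apd90, rise_time, frame_period) {
  check_positive(apd90, "apd90")
  check_positive(rise_time, "rise_time")
  check_positive(frame_period, "frame_period")
  if (!(apd90 > rise_time && rise_time > 2 * frame_period)) {
    stop_invalid("invalid parameters: need apd90 > rise_time > 2 * frame_period")
  }
  dur <- ap_wave_duration(apd90, rise_time)
  f <- ap_wave_fun(apd90, rise_time)
  tm <- seq(0, dur + 2 * frame_period, by = frame_period)
  structure(list(
    time = tm, trace = f(tm), fun = f,
    activation_ms = rise_time / 2, duration_ms = dur,
    apd90 = apd90, rise_time = rise_time, frame_period = frame_period,
    kind = "ap"
  ), class = "synthetic_beat")
}

cat_wave_plateau <- function(cat90, rise_time, decay_tau) {
  tau_ms <- decay_tau * 1000
  cat90 - rise_time / 2 - tau_ms * log(10)
}

cat_wave_fun <- function(cat90, rise_time, decay_tau) {
  r <- rise_time
  tau_ms <- decay_tau * 1000
  p <- cat_wave_plateau(cat90, rise_time, decay_tau)
  function(t) {
    v <- numeric(length(t))
    up <- t >= 0 & t <= r
    v[up] <- 0.5 * (1 - cos(pi * t[up] / r))
    pl <- t > r & t <= r + p
    v[pl] <- 1
    dec <- t > r + p
    v[dec] <- exp(-(t[dec] - r - p) / tau_ms)
    v
  }
}

#' Synthesize a single normalized calcium-transient beat
#'
#' Builds a normalized CaT beat: half-cosine upstroke over `rise_time`, a
#' plateau, then a strictly monoexponential decay with time constant
#' `decay_tau`. The plateau length is solved so that the 90%-recovery
#' instant falls exactly `cat90` after the maximal-upstroke-velocity
#' instant. Because the decay is exactly exponential, refitting it with
#' [decay_tau()] recovers `decay_tau`.
#'
#' @param cat90 CaT duration at 90% recovery, ms. Must be at least
#'   `rise_time / 2 + 1000 * decay_tau * log(10)` (otherwise 90% recovery
#'   cannot be reached with the requested decay constant).
#' @param rise_time Upstroke duration, ms.
#' @param decay_tau Decay time constant, seconds (the field convention for
#'   CaT decay; durations stay in ms).
#' @param frame_period Sampling interval, ms.
#' @return A `synthetic_beat` (see [make_ap_waveform()]); `peak_ms` marks
#'   the first instant at full amplitude.
#' @export
make_cat_waveform <- function(cat90, rise_time, decay_tau, frame_period) {
  check_positive(cat90, "cat90")
  check_positive(rise_time, "rise_time")
  check_positive(decay_tau, "decay_tau")
  check_positive(frame_period, "frame_period")
  if (rise_time <= 2 * frame_period) {
    stop_invalid("invalid parameters: need rise_time > 2 * frame_period")
  }
  p <- cat_wave_plateau(cat90, rise_time, decay_tau)
  if (p < 0) {
    stop_invalid(
      "invalid parameters: 90% recovery unreachable; cat90 must be >= ",
      "rise_time / 2 + 1000 * decay_tau * log(10) = ",
      round(rise_time / 2 + 1000 * decay_tau * log(10), 2), " ms"
    )
  }
  tau_ms <- decay_tau * 1000
  dur <- rise_time + p + tau_ms * log(1000)
  f <- cat_wave_fun(cat90, rise_time, decay_tau)
  tm <- seq(0, dur + 2 * frame_period, by = frame_period)
  structure(list(
    time = tm, trace = f(tm), fun = f,
    activation_ms = rise_time / 2, duration_ms = dur,
    peak_ms = rise_time,
    cat90 = cat90, rise_time = rise_time, decay_tau = decay_tau,
    frame_period = frame_period, kind = "cat"
  ), class = "synthetic_beat")
}

#' @export
print.synthetic_beat <- function(x, ...) {
  cat("<synthetic_beat>", x$kind, "waveform;",
      length(x$trace), "samples @", round(x$frame_period, 4), "ms\n")
  if (x$kind == "ap") cat("  apd90:", x$apd90, "ms  rise:", x$rise_time, "ms\n")
  else cat("  cat90:", x$cat90, "ms  rise:", x$rise_time,
           "ms  tau:", x$decay_tau, "s\n")
  invisible(x)
}
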