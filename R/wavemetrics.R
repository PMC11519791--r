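# Per-beat AP/CaT feature extraction, feature maps, conduction velocity
# and spatial-heterogeneity statistics.

beat_segment <- function(trace, window) {
  trace[window$start_frame:window$end_frame]
}

#' Activation time of a beat
#'
#' The activation instant is the time of the maximal first derivative of
#' the (normalized) upstroke (dF/dt max), refined to sub-frame precision by
#' parabolic interpolation around the discrete argmax. When the discrete
#' maximum is tied (e.g. a perfectly linear ramp) the earliest frame is
#' taken and the result carries attribute `tie = TRUE`.
#'
#' @param trace Numeric pixel trace for the whole recording.
#' @param window One row of [segment_beats()] output.
#' @param frame_period Sampling interval, ms.
#' @return Activation time in ms from the start of the recording. Shifting
#'   the beat by k frames shifts the result by exactly `k * frame_period`.
#' @export
activation_time <- function(trace, window, frame_period) {
  seg <- normalize_beat(trace, window)
  d <- diff(seg)
  i <- which.max(d)
  tie <- sum(abs(d - d[i]) < 1e-9 * max(abs(d), 1e-12)) > 1L
  if (tie) i <- which(abs(d - d[i]) < 1e-9 * max(abs(d), 1e-12))[1]
  off <- if (i > 1 && i < length(d)) parabolic_offset(d[i - 1], d[i], d[i + 1]) else 0
  # d[i] sits between samples i and i+1 -> derivative time i - 0.5 (0-based)
  t_ms <- (window$start_frame - 1 + (i - 0.5) + off) * frame_period
  structure(t_ms, tie = tie)
}

# Noise-robust amplitude reference for level crossings. The diastolic
# baseline is the mean of the pre-activation samples whose local slope
# is small compared with the upstroke (|diff| <= 15% of the maximal
# derivative) — selecting on slope rather than value keeps the estimate
# unbiased under symmetric noise, unlike the window minimum. Windows
# that start on the upstroke itself (single-beat traces) have no flat
# samples and fall back to the first frame. Exact for noiseless beats.
beat_reference <- function(seg) {
  d <- diff(seg)
  i_act <- which.max(d)
  flat <- which(abs(d[seq_len(i_act)]) <= 0.15 * d[i_act])
  base <- if (length(flat)) mean(seg[flat]) else seg[1]
  list(base = base, amp = max(seg) - base)
}

#' Duration from activation to a fractional repolarization level
#'
#' Operational APD/CaT duration: the time from the activation instant
#' (dF/dt max) to the linearly interpolated downward crossing of the
#' `level` recovery point (level 0.9 = 90% repolarization = the trace
#' falling to 10% of the beat amplitude above the diastolic baseline).
#' The baseline is estimated from the pre-upstroke frames, which keeps
#' the crossing level unbiased in the presence of sensor noise.
#'
#' @inheritParams activation_time
#' @param activation Activation time in ms (from [activation_time()]).
#' @param level Recovery fraction in (0, 1): 0.3, 0.8, 0.9 give APD30/80/90.
#' @return Duration in ms, or `NA` with attribute `flag = "not_reached"`
#'   when the beat is cut off before recovering to the level.
#' @export
duration_at_level <- function(trace, window, activation, level,
                              frame_period) {
  if (!(level > 0 && level < 1)) stop_invalid("level must be in (0, 1)")
  seg <- beat_segment(trace, window)
  ref <- beat_reference(seg)
  if (ref$amp <= 1e-12) return(structure(NA_real_, flag = "degenerate"))
  pk <- which.max(seg)
  ci <- crossing_index(seg, ref$base + (1 - level) * ref$amp,
                       from = pk, direction = "down")
  if (is.na(ci)) {
    return(structure(NA_real_, flag = "not_reached"))
  }
  t_cross <- (window$start_frame - 1 + ci - 1) * frame_period
  t_cross - as.numeric(activation)
}

#' Upstroke rise time (10-90%)
#'
#' Time from the 10% to the 90% point of the upstroke amplitude, linearly
#' interpolated — the standard optical-mapping convention. The
#' onset-to-peak interval is also returned as an attribute
#' (`onset_to_peak`) for comparison.
#'
#' @inheritParams activation_time
#' @param min_amplitude Raw-amplitude floor below which `NA` is returned.
#' @return Rise time in ms.
#' @export
rise_time <- function(trace, window, frame_period, min_amplitude = 1e-9) {
  seg_raw <- beat_segment(trace, window)
  if (diff(range(seg_raw)) <= min_amplitude) {
    return(structure(NA_real_, flag = "low_amplitude"))
  }
  seg <- normalize_beat(trace, window)
  pk <- which.max(seg)
  i90 <- crossing_index(seg[seq_len(pk)], 0.9, from = 1L, direction = "up")
  if (is.na(i90)) i90 <- pk
  i10 <- NA_real_
  for (i in seq_len(max(1L, floor(i90))) ) {
    if (seg[i] <= 0.1 && seg[i + 1] > 0.1) {
      i10 <- i + (0.1 - seg[i]) / (seg[i + 1] - seg[i])
    }
  }
  if (is.na(i10)) i10 <- 1
  i05 <- crossing_index(seg[seq_len(pk)], 0.05, from = 1L, direction = "up")
  structure(max(i90 - i10, 0) * frame_period,
            onset_to_peak = if (is.na(i05)) NA_real_
                            else (pk - i05) * frame_period)
}

#' Decay time constant of a calcium transient
#'
#' Fits a monoexponential to the decay segment between 30% below the peak
#' and 90% recovery (normalized values 0.7 down to 0.1): a log-linear
#' least-squares fit provides the start, refined by nonlinear least
#' squares of `A * exp(-t / tau)`. A fit is flagged unreliable when its
#' R-squared (original scale) falls below `r2_min` or when a straight
#' line explains the decay segment at least as well as the exponential
#' (e.g. a linear decay, for which the time constant is meaningless).
#'
#' @inheritParams activation_time
#' @param r2_min Reliability threshold on R-squared.
#' @return Decay constant tau in seconds, with attributes `r2` and
#'   `reliable`.
#' @export
decay_tau <- function(trace, window, frame_period, r2_min = 0.9) {
  seg <- normalize_beat(trace, window)
  pk <- which.max(seg)
  i0 <- crossing_index(seg, 0.7, from = pk, direction = "down")
  i1 <- crossing_index(seg, 0.1, from = pk, direction = "down")
  if (is.na(i0) || is.na(i1)) {
    return(structure(NA_real_, r2 = NA_real_, reliable = FALSE,
                     flag = "no_decay"))
  }
  idx <- seq(ceiling(i0), floor(i1))
  idx <- idx[seg[idx] > 0]
  if (length(idx) < 4) {
    return(structure(NA_real_, r2 = NA_real_, reliable = FALSE,
                     flag = "too_short"))
  }
  t_ms <- (idx - idx[1]) * frame_period
  y <- seg[idx]
  lf <- lm(log(y) ~ t_ms)
  tau_ms <- -1 / coef(lf)[[2]]
  a0 <- exp(coef(lf)[[1]])
  if (is.finite(tau_ms) && tau_ms > 0) {
    fit <- try(nlsLM(y ~ A * exp(-t_ms / tau),
                     start = list(A = a0, tau = tau_ms),
                     control = minpack.lm::nls.lm.control(maxiter = 200)),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      a0 <- coef(fit)[["A"]]; tau_ms <- coef(fit)[["tau"]]
    }
  }
  pred <- a0 * exp(-t_ms / tau_ms)
  rss_exp <- sum((y - pred)^2)
  rss_line <- sum(stats::residuals(lm(y ~ t_ms))^2)
  r2 <- 1 - rss_exp / sum((y - mean(y))^2)
  structure(tau_ms / 1000, r2 = r2,
            reliable = is.finite(r2) && r2 >= r2_min &&
              rss_exp < rss_line)
}

#' Calcium-transient transition points
#'
#' Returns the four canonical transition instants of a CaT beat: `t0`
#' (activation onset, 5% upstroke crossing), `t_on` (first peak instant),
#' `t30_off` (30% recovery) and `t_off` (90% recovery), all in absolute ms,
#' plus `recovery_time = t_off - t_on`. Time-shifting the beat shifts all
#' four points equally.
#'
#' @inheritParams activation_time
#' @return Named list; `t30_off`/`t_off` are `NA` (flagged) when the trace
#'   never recovers.
#' @export
transition_points <- function(trace, window, frame_period) {
  seg <- beat_segment(trace, window)
  ref <- beat_reference(seg)
  if (ref$amp <= 1e-12) stop_invalid("degenerate signal: flat beat window")
  lev <- function(f) ref$base + f * ref$amp
  base_ms <- (window$start_frame - 1) * frame_period
  pk <- which.max(seg)
  i0 <- crossing_index(seg[seq_len(pk)], lev(0.05), from = 1L,
                       direction = "up")
  t0 <- if (is.na(i0)) base_ms else base_ms + (i0 - 1) * frame_period
  t_on <- base_ms + (pk - 1) * frame_period
  c30 <- crossing_index(seg, lev(0.7), from = pk, direction = "down")
  c90 <- crossing_index(seg, lev(0.1), from = pk, direction = "down")
  t30 <- if (is.na(c30)) structure(NA_real_, flag = "not_reached")
         else base_ms + (c30 - 1) * frame_period
  t90 <- if (is.na(c90)) structure(NA_real_, flag = "not_reached")
         else base_ms + (c90 - 1) * frame_period
  list(t0 = t0, t_on = t_on, t30_off = t30, t_off = t90,
       recovery_time = if (is.na(c90)) NA_real_ else as.numeric(t90) - t_on)
}

#' Measure per-pixel per-beat features of a movie
#'
#' Runs the per-beat estimators over every masked pixel and every beat
#' window and assembles feature arrays (`beat x row x col`): activation
#' time, durations at the requested repolarization levels, 10-90% rise
#' time and raw amplitude; optionally the CaT decay constant tau.
#' Windows whose raw amplitude falls below `min_amplitude` times the
#' movie-wide beat amplitude (e.g. non-captured premature stimuli) yield
#' `NA` features but keep their measured amplitude.
#'
#' @param m An [movie()] (typically after [spatial_gaussian3()]).
#' @param windows [segment_beats()] output.
#' @param mask Optional logical pixel mask.
#' @param levels Recovery levels to measure (defaults 0.3, 0.8, 0.9).
#' @param fit_tau Also fit [decay_tau()] per pixel-beat (slower).
#' @param min_amplitude Fraction of the global amplitude below which a
#'   window is treated as not captured.
#' @return A `beat_feature_set`: list of arrays `activation`,
#'   `duration` (named list per level), `rise`, `amplitude`, optionally
#'   `tau`, plus `windows`, `mask` and acquisition metadata.
#' @export
measure_beats <- function(m, windows, mask = NULL,
                          levels = c(0.3, 0.8, 0.9), fit_tau = FALSE,
                          min_amplitude = 0.2) {
  stopifnot(inherits(m, "om_movie"))
  fp <- frame_period_ms(m)
  d <- dim(m$frames)
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  nb <- nrow(windows)
  mk_arr <- function() array(NA_real_, c(nb, d[2], d[3]))
  act <- mk_arr(); rise <- mk_arr(); amp <- mk_arr()
  tau <- if (fit_tau) mk_arr() else NULL
  dur <- lapply(levels, function(l) mk_arr())
  names(dur) <- paste0("d", round(levels * 100))
  global_amp <- diff(range(m$frames))
  for (r in seq_len(d[2])) {
    for (cc in seq_len(d[3])) {
      if (!mask[r, cc]) next
      trace <- m$frames[, r, cc]
      for (b in seq_len(nb)) {
        w <- windows[b, ]
        seg <- trace[w$start_frame:w$end_frame]
        a <- diff(range(seg))
        amp[b, r, cc] <- a
        if (a < min_amplitude * global_amp) next
        at <- activation_time(trace, w, fp)
        act[b, r, cc] <- at
        for (li in seq_along(levels)) {
          dur[[li]][b, r, cc] <- duration_at_level(trace, w, at,
                                                   levels[li], fp)
        }
        rise[b, r, cc] <- rise_time(trace, w, fp)
        if (fit_tau) tau[b, r, cc] <- decay_tau(trace, w, fp)
      }
    }
  }
  structure(list(activation = act, duration = dur, rise = rise,
                 amplitude = amp, tau = tau, windows = windows,
                 mask = mask, frame_rate = m$frame_rate,
                 pixel_pitch = m$pixel_pitch, channel = m$channel),
            class = "beat_feature_set")
}

#' Extract one beat's map from a feature set
#'
#' @param fs A [measure_beats()] result.
#' @param feature One of `"activation"`, `"rise"`, `"amplitude"`, `"tau"`
#'   or a duration name such as `"d90"`.
#' @param beat Beat index.
#' @return Numeric matrix (`NA` outside the mask), class `feature_map`
#'   with attributes `feature` and `beat`.
#' @export
feature_map <- function(fs, feature, beat) {
  stopifnot(inherits(fs, "beat_feature_set"))
  arr <- if (feature %in% names(fs$duration)) fs$duration[[feature]]
         else fs[[feature]]
  if (is.null(arr)) stop_invalid("feature `", feature, "` not measured")
  mp <- arr[beat, , ]
  mp[!fs$mask] <- NA_real_
  structure(mp, class = c("feature_map", "matrix"),
            feature = feature, beat = beat)
}

#' Conduction velocity from an activation map
#'
#' Bayly-style local conduction estimation: a second-order polynomial
#' surface `T(x, y)` is least-squares fitted to the activation times in
#' each interior 5x5 pixel neighbourhood; the local velocity is the
#' inverse-gradient vector of the fitted surface (`mm/ms`). Pixels whose
#' neighbourhood is incomplete, whose fit is singular, or whose gradient
#' is degenerate are excluded.
#'
#' @param act_map Activation-time matrix, ms (e.g.
#'   `feature_map(fs, "activation", beat)`).
#' @param pixel_pitch Pixel size, mm.
#' @param mask Optional logical mask.
#' @return List of class `conduction_result`: `speed` (matrix, mm/ms),
#'   `vx`, `vy` (unit direction components), `mean_speed`,
#'   `direction_coherence` (length of the mean unit direction vector,
#'   in `[0, 1]`) and `n_pixels`.
#' @export
conduction_velocity <- function(act_map, pixel_pitch, mask = NULL) {
  nr <- nrow(act_map); nc <- ncol(act_map)
  if (nr < 5 || nc < 5) stop_invalid("activation map must be at least 5 x 5")
  if (is.null(mask)) mask <- !is.na(act_map)
  # design for the 5x5 neighbourhood in physical units (mm); as.vector()
  # is column-major, so row offsets vary fastest
  off <- (-2:2) * pixel_pitch
  ro <- rep(off, times = 5)  # row offsets
  co <- rep(off, each = 5)   # column offsets
  X <- cbind(1, ro, co, ro^2, ro * co, co^2)
  P <- solve(crossprod(X), t(X))  # coefficients = P %*% T
  speed <- matrix(NA_real_, nr, nc)
  vx <- matrix(NA_real_, nr, nc); vy <- matrix(NA_real_, nr, nc)
  for (r in 3:(nr - 2)) {
    for (cc in 3:(nc - 2)) {
      nb <- act_map[(r - 2):(r + 2), (cc - 2):(cc + 2)]
      mb <- mask[(r - 2):(r + 2), (cc - 2):(cc + 2)]
      if (!all(mb) || anyNA(nb)) next
      beta <- P %*% as.vector(nb)
      g_row <- beta[2]; g_col <- beta[3]
      g2 <- g_row^2 + g_col^2
      if (!is.finite(g2) || g2 < 1e-12) next
      speed[r, cc] <- 1 / sqrt(g2)
      vy[r, cc] <- g_row / sqrt(g2)
      vx[r, cc] <- g_col / sqrt(g2)
    }
  }
  ok <- is.finite(speed)
  coher <- if (any(ok)) {
    sqrt(mean(vx[ok])^2 + mean(vy[ok])^2)
  } else NA_real_
  structure(list(speed = speed, vx = vx, vy = vy,
                 mean_speed = if (any(ok)) mean(speed[ok]) else NA_real_,
                 direction_coherence = coher, n_pixels = sum(ok)),
            class = "conduction_result")
}

#' Spatial heterogeneity as the interquartile range of a map
#'
#' The 75th minus 25th percentile over valid (masked) pixels, using the
#' linear-interpolation quantile convention (type 7).
#'
#' @param map Numeric matrix (NA allowed).
#' @param mask Optional logical mask.
#' @return Scalar IQR in the map's units.
#' @export
heterogeneity_iqr <- function(map, mask = NULL) {
  x <- if (is.null(mask)) as.vector(map) else map[mask]
  x <- x[is.finite(x)]
  if (length(x) < 4) stop_invalid("need at least 4 valid pixels")
  unname(diff(quantile(x, c(0.25, 0.75), type = 7)))
}

#' @export
print.conduction_result <- function(x, ...) {
  cat("<conduction_result> mean speed:", signif(x$mean_speed, 4),
      "mm/ms over", x$n_pixels, "pixels; direction coherence:",
      signif(x$direction_coherence, 3), "\n")
  invisible(x)
}

#' Plot a feature map as a heat map
#'
#' @param x A [feature_map()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.feature_map <- function(x, ...) {
  z <- t(unclass(x))[, rev(seq_len(nrow(x))), drop = FALSE]
  image(z, col = hcl.colors(64, "viridis"), axes = FALSE,
        main = paste0(attr(x, "feature"), " (beat ", attr(x, "beat"), ")"),
        ...)
  invisible(x)
}
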