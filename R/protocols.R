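# Stimulation-protocol analysis: S2/S1 calcium-release restitution,
# effective refractory period, sinus-node recovery, tachyarrhythmia
# episode detection, and RyR2/SERCA rate constants.

#' Per-pixel per-beat amplitudes of a movie
#'
#' Beat amplitude per window: the peak value minus the pre-peak minimum
#' (the diastolic level immediately before the upstroke). Referencing the
#' peak to the preceding minimum, rather than the window-wide range,
#' means a window that only contains the decaying tail of the previous
#' transient (e.g. a premature stimulus that failed to capture) measures
#' near zero instead of the tail height.
#'
#' @param m An [movie()].
#' @param windows [segment_beats()] output.
#' @param mask Optional logical mask.
#' @return Numeric array `beat x row x col`.
#' @export
beat_amplitudes <- function(m, windows, mask = NULL) {
  d <- dim(m$frames)
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  nb <- nrow(windows)
  amp <- array(NA_real_, c(nb, d[2], d[3]))
  for (b in seq_len(nb)) {
    seg <- m$frames[windows$start_frame[b]:windows$end_frame[b], , ,
                    drop = FALSE]
    a <- apply(seg, c(2, 3), function(x) {
      pk <- which.max(x)
      x[pk] - min(x[seq_len(pk)])
    })
    a[!mask] <- NA_real_
    amp[b, , ] <- a
  }
  amp
}

#' Detect capture of each beat window
#'
#' A stimulus is called captured when at least `pixel_frac` of the masked
#' pixels show a beat amplitude of at least `amp_frac` of their own
#' steady-state (S1 reference) amplitude — a propagated response rather
#' than local noise.
#'
#' @param amp Amplitude array from [beat_amplitudes()].
#' @param ref_beats Indices of steady drive-train beats defining the
#'   per-pixel reference amplitude (mean over these beats).
#' @param amp_frac Fraction of the reference amplitude required.
#' @param pixel_frac Fraction of masked pixels required.
#' @return Logical vector, one element per beat window.
#' @export
detect_capture <- function(amp, ref_beats, amp_frac = 0.5,
                           pixel_frac = 0.5) {
  nb <- dim(amp)[1]
  ref <- apply(amp[ref_beats, , , drop = FALSE], c(2, 3), mean)
  ok <- is.finite(ref) & ref > 0
  vapply(seq_len(nb), function(b) {
    frac <- mean(amp[b, , ][ok] >= amp_frac * ref[ok], na.rm = TRUE)
    is.finite(frac) && frac >= pixel_frac
  }, logical(1))
}

#' S2/S1 calcium-transient amplitude ratio
#'
#' For each S1S2 train, the premature-beat (S2) CaT amplitude is expressed
#' relative to the steady drive-train amplitude, per pixel (a ratio map),
#' at four configured analysis sites (3x3 means around each site), and as
#' the masked-field mean. The S1 reference is the per-pixel mean amplitude
#' of the last three S1 beats of the train. S2 windows with a field-mean
#' ratio below `min_ratio` are marked non-captured and their ratio is
#' missing.
#'
#' @param amp Amplitude array (`beat x row x col`) from
#'   [beat_amplitudes()] on the calcium channel.
#' @param labels data.frame aligned with the beat windows, columns `type`
#'   (`"S1"`/`"S2"`), `train` and `interval` (S2 coupling interval, ms) —
#'   e.g. the emitted schedule of [simulate_movie()] truth.
#' @param sites Optional list/matrix of four `(row, col)` site
#'   coordinates.
#' @param mask Optional logical mask.
#' @param min_ratio Field-mean ratio below which the S2 is non-captured.
#' @return data.frame of class `s2s1_result` with one row per S1S2 train:
#'   `interval`, `ratio` (field mean), `site1..site4` (when sites given)
#'   and `captured`; the per-train ratio maps are in
#'   `attr(, "ratio_maps")`.
#' @export
s2s1_ratio <- function(amp, labels, sites = NULL, mask = NULL,
                       min_ratio = 0.05) {
  if (nrow(labels) != dim(amp)[1]) {
    stop_invalid("labels must have one row per beat window")
  }
  nr <- dim(amp)[2]; nc <- dim(amp)[3]
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  trains <- unique(labels$train[labels$type == "S2"])
  rows <- list(); maps <- list()
  site_mean <- function(mp, s) {
    r <- max(2, min(nr - 1, s[1])); cc <- max(2, min(nc - 1, s[2]))
    mean(mp[(r - 1):(r + 1), (cc - 1):(cc + 1)], na.rm = TRUE)
  }
  for (tr in trains) {
    s1_idx <- which(labels$type == "S1" & labels$train == tr)
    s2_idx <- which(labels$type == "S2" & labels$train == tr)
    if (length(s1_idx) < 1 || length(s2_idx) != 1) next
    ref_idx <- tail(s1_idx, 3)
    ref <- apply(amp[ref_idx, , , drop = FALSE], c(2, 3), mean)
    rmap <- amp[s2_idx, , ] / ref
    rmap[!mask] <- NA_real_
    fm <- mean(rmap[mask], na.rm = TRUE)
    captured <- is.finite(fm) && fm >= min_ratio
    row <- data.frame(interval = labels$interval[s2_idx],
                      ratio = if (captured) fm else NA_real_,
                      captured = captured)
    if (!is.null(sites)) {
      sv <- vapply(seq_along(sites), function(i)
        if (captured) site_mean(rmap, sites[[i]]) else NA_real_, 0)
      row[paste0("site", seq_along(sites))] <- as.list(sv)
    }
    rows[[length(rows) + 1L]] <- row
    maps[[length(maps) + 1L]] <- if (captured) rmap else NULL
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$interval), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ratio_maps") <- maps
  class(out) <- c("s2s1_result", class(out))
  out
}

#' Fit a monoexponential calcium-release restitution curve
#'
#' Fits `ratio(d) = A * (1 - exp(-(d - d0) / tau_r))` to S2/S1 ratios
#' against the coupling interval by nonlinear least squares over a
#' multi-start grid; the latency offset `d0` accounts for ratios being
#' undefined below the refractory period. Steepness is the maximal fitted
#' derivative over the tested interval range, times 100 (percent of the
#' asymptote per ms).
#'
#' @param intervals Coupling intervals, ms (at least 4 captured points).
#' @param ratios S2/S1 amplitude ratios.
#' @return List of class `restitution_fit`: `A`, `tau_r`, `d0`,
#'   `steepness`, `fitted`, `r2`, `converged` (FALSE and `flag` when the
#'   curve is degenerate or no start converged).
#' @export
fit_restitution <- function(intervals, ratios) {
  keep <- is.finite(intervals) & is.finite(ratios)
  d <- intervals[keep]; y <- ratios[keep]
  if (length(d) < 4) stop_invalid("need at least 4 captured intervals")
  o <- order(d); d <- d[o]; y <- y[o]
  out <- list(A = NA_real_, tau_r = NA_real_, d0 = NA_real_,
              steepness = NA_real_, fitted = rep(NA_real_, length(d)),
              intervals = d, ratios = y, r2 = NA_real_,
              converged = FALSE, flag = NULL)
  if (sd(y) < 1e-10) {
    out$A <- mean(y); out$flag <- "degenerate: tau_r unidentifiable"
    class(out) <- "restitution_fit"
    return(out)
  }
  best <- NULL
  for (tau0 in c(diff(range(d)) / 4, diff(range(d)) / 2, diff(range(d)))) {
    for (d00 in c(0, min(d) / 2, min(d) - 1)) {
      fit <- try(nlsLM(y ~ A * (1 - exp(-(d - d0) / tau)),
                       start = list(A = max(y), tau = tau0, d0 = d00),
                       lower = c(A = 0, tau = 1e-3,
                                 d0 = min(d) - 5 * diff(range(d))),
                       upper = c(A = 2, tau = 20 * diff(range(d)),
                                 d0 = min(d)),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    out$flag <- "fit did not converge; raw curve returned"
    class(out) <- "restitution_fit"
    return(out)
  }
  cf <- coef(best$fit)
  out$A <- cf[["A"]]; out$tau_r <- cf[["tau"]]; out$d0 <- cf[["d0"]]
  out$fitted <- as.numeric(predict(best$fit))
  out$r2 <- 1 - best$rss / sum((y - mean(y))^2)
  # derivative A/tau * exp(-(d - d0)/tau) is maximal at the shortest interval
  out$steepness <- 100 * out$A / out$tau_r *
    exp(-(min(d) - out$d0) / out$tau_r)
  out$converged <- TRUE
  class(out) <- "restitution_fit"
  out
}

#' @export
print.restitution_fit <- function(x, ...) {
  cat("<restitution_fit> A =", signif(x$A, 4), " tau_r =",
      signif(x$tau_r, 4), "ms  d0 =", signif(x$d0, 4),
      "ms  steepness =", signif(x$steepness, 4), "%/ms\n")
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Atrial effective refractory period from S1S2 capture outcomes
#'
#' AERP is the longest tested premature-stimulus coupling interval that
#' fails to elicit a propagated response. When every tested interval
#' captures (or none does) the AERP lies outside the tested range and is
#' reported as a bound.
#'
#' @param intervals Tested S2 coupling intervals, ms.
#' @param captured Logical capture outcome per interval (e.g. from
#'   [detect_capture()]).
#' @return List of class `refractory_result` with `aerp` (ms, `NA` when
#'   out of range), `status` (`"ok"`, `"below_range"`, `"above_range"`)
#'   and `bound` (a human-readable bound string when out of range).
#' @export
aerp_from_s1s2 <- function(intervals, captured) {
  if (length(intervals) != length(captured)) {
    stop_invalid("intervals and captured must have equal length")
  }
  o <- order(intervals)
  intervals <- intervals[o]; captured <- captured[o]
  if (all(captured)) {
    out <- list(aerp = NA_real_, status = "below_range",
                bound = paste0("< ", min(intervals), " ms"))
  } else if (!any(captured)) {
    out <- list(aerp = NA_real_, status = "above_range",
                bound = paste0(">= ", max(intervals), " ms"))
  } else {
    out <- list(aerp = max(intervals[!captured]), status = "ok",
                bound = NULL)
  }
  class(out) <- "refractory_result"
  out
}

#' Sinus-node recovery time after overdrive pacing
#'
#' `snrt_raw` is the delay from the last paced stimulus to the first
#' spontaneous activation; `snrt_corrected` subtracts the baseline cycle
#' length (the pause in excess of one intrinsic cycle).
#'
#' @param activation_times Activation times, ms.
#' @param last_stim Time of the last paced stimulus, ms.
#' @param baseline_cl Intrinsic (baseline) cycle length, ms.
#' @param window_ms Search window after the last stimulus.
#' @return List with `snrt_raw` and `snrt_corrected` (both `NA`, flagged,
#'   when no spontaneous beat occurs in the window).
#' @export
snrt <- function(activation_times, last_stim, baseline_cl,
                 window_ms = 10 * baseline_cl) {
  post <- activation_times[activation_times > last_stim + 1e-9 &
                           activation_times <= last_stim + window_ms]
  if (!length(post)) {
    return(list(snrt_raw = NA_real_, snrt_corrected = NA_real_,
                flag = "no_spontaneous_beat"))
  }
  raw <- min(post) - last_stim
  list(snrt_raw = raw, snrt_corrected = raw - baseline_cl)
}

#' Detect tachyarrhythmia (AT/AF-like) episodes
#'
#' An episode is a run of at least `min_cycles` consecutive cycles that
#' are individually fast (cycle length below
#' `candidate_frac * baseline_cl`), with run mean cycle length below
#' `mean_frac * baseline_cl` and coefficient of variation above `cv_min`
#' (rapid and irregular). All thresholds are exposed because the
#' criterion is algorithmic, not physiological.
#'
#' @param activation_times Activation-time series, ms (at least 11 beats
#'   = 10 intervals).
#' @param baseline_cl Baseline cycle length, ms.
#' @param min_cycles Minimum run length in cycles.
#' @param mean_frac Run-mean cycle-length threshold (fraction of
#'   baseline).
#' @param cv_min Minimum coefficient of variation of the run.
#' @param candidate_frac Per-cycle fast threshold (fraction of baseline).
#' @return List of class `ectopy_report`: `episodes` data.frame
#'   (`onset`, `offset`, `duration_ms`, `n_cycles`, `mean_cl`, `cv`),
#'   `total_duration_s` and `induced`.
#' @export
detect_episodes <- function(activation_times, baseline_cl, min_cycles = 5,
                            mean_frac = 0.6, cv_min = 0.1,
                            candidate_frac = 0.75) {
  at <- sort(as.numeric(activation_times))
  cl <- diff(at)
  if (length(cl) < 10) stop_invalid("need at least 10 intervals")
  fast <- cl < candidate_frac * baseline_cl
  runs <- rle(fast)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rows <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i] || runs$lengths[i] < min_cycles) next
    idx <- starts[i]:ends[i]
    m <- mean(cl[idx]); cv <- sd(cl[idx]) / m
    if (m < mean_frac * baseline_cl && cv > cv_min) {
      rows[[length(rows) + 1L]] <- data.frame(
        onset = at[idx[1]], offset = at[idx[length(idx)] + 1L],
        duration_ms = at[idx[length(idx)] + 1L] - at[idx[1]],
        n_cycles = length(idx), mean_cl = m, cv = cv)
    }
  }
  eps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset = numeric(0), offset = numeric(0),
               duration_ms = numeric(0), n_cycles = integer(0),
               mean_cl = numeric(0), cv = numeric(0))
  structure(list(episodes = eps,
                 total_duration_s = sum(eps$duration_ms) / 1000,
                 induced = nrow(eps) > 0),
            class = "ectopy_report")
}

#' @export
print.ectopy_report <- function(x, ...) {
  cat("<ectopy_report>", nrow(x$episodes), "episode(s), total",
      signif(x$total_duration_s, 4), "s; induced:", x$induced, "\n")
  invisible(x)
}

#' RyR2 and SERCA rate constants from single-cell calcium protocols
#'
#' The RyR2 release rate is the maximal first derivative of a third-order
#' polynomial fitted to the upstroke of a caffeine-evoked calcium
#' transient (normalized amplitude per second). SERCA function is
#' summarized by the time constant of an exponential fit
#' `A * (1 - exp(-t / tau))` to the recovery of transient amplitude with
#' release blocked (tetracaine protocol); the polynomial-derivative
#' estimate of the recovery is attached as a diagnostic.
#'
#' @param caffeine data.frame with columns `time` (s) and `value`
#'   (normalized fluorescence) covering a caffeine-evoked transient with
#'   a rising phase of at least 5 samples.
#' @param recovery data.frame with columns `time` (s) and `amplitude`
#'   (normalized) — the amplitude-recovery series (at least 5 points).
#' @param min_amplitude Caffeine-transient amplitude floor.
#' @return List of class `flux_rates`: `ryr2_rate` (1/s),
#'   `serca_rate_inv` (s), `diagnostics` (including the polynomial
#'   recovery-rate estimate), and `flags`.
#' @export
flux_rates <- function(caffeine, recovery, min_amplitude = 0.1) {
  flags <- character(0)
  ryr2 <- NA_real_
  tv <- caffeine$time; y <- caffeine$value
  amp <- diff(range(y))
  pk <- which.max(y)
  if (amp < min_amplitude) {
    flags <- c(flags, "caffeine response flat")
  } else if (pk < 5) {
    flags <- c(flags, "caffeine upstroke too short")
  } else {
    ui <- seq_len(pk)
    yn <- (y[ui] - min(y[ui])) / amp
    drops <- diff(yn)
    if (any(drops < -0.1)) flags <- c(flags, "non-monotone caffeine upstroke")
    tt <- tv[ui]
    pf <- lm(yn ~ tt + I(tt^2) + I(tt^3))
    cf <- coef(pf)
    grid <- seq(min(tt), max(tt), length.out = 200)
    deriv <- cf[2] + 2 * cf[3] * grid + 3 * cf[4] * grid^2
    ryr2 <- max(deriv)
  }
  serca <- NA_real_; poly_rate <- NA_real_
  if (nrow(recovery) < 5) {
    flags <- c(flags, "recovery series too short")
  } else {
    tr <- recovery$time; ar <- recovery$amplitude
    fit <- try(nlsLM(ar ~ A * (1 - exp(-tr / tau)),
                     start = list(A = max(ar), tau = max(tr) / 3),
                     control = minpack.lm::nls.lm.control(maxiter = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      flags <- c(flags, "recovery fit failed")
    } else {
      serca <- coef(fit)[["tau"]]
    }
    pr <- lm(ar ~ tr + I(tr^2) + I(tr^3))
    cfr <- coef(pr)
    gr <- seq(min(tr), max(tr), length.out = 200)
    poly_rate <- max(cfr[2] + 2 * cfr[3] * gr + 3 * cfr[4] * gr^2)
  }
  structure(list(ryr2_rate = ryr2, serca_rate_inv = serca,
                 diagnostics = list(recovery_poly_rate = poly_rate),
                 flags = flags),
            class = "flux_rates")
}
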