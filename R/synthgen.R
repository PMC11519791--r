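# Synthetic tissue generator: specifications, the restitution iterated map,
# and the dual-channel movie simulator with exact ground-truth labels.

#' Restitution parameters for one tissue region
#'
#' @param apd_max Plateau (maximal) action-potential duration of the
#'   restitution curve `APD(DI) = apd_max * (1 - exp(-DI / tau_rest))`, ms.
#' @param tau_rest Restitution time constant, ms. Steeper restitution
#'   (larger `apd_max / tau_rest`) promotes alternans at short cycle
#'   lengths.
#' @param cat_decay_tau Calcium-transient decay time constant, seconds.
#' @param cat_amp_tau_refr Recovery time constant of premature-beat (S2)
#'   CaT amplitude, ms: an S2 delivered at coupling interval d elicits a
#'   transient scaled by `1 - exp(-d / cat_amp_tau_refr)`.
#' @param rise_time Upstroke duration of both channels, ms.
#' @param cat90_scale Ratio of CaT90 to APD90 for beats in this region.
#' @return A `restitution_params` list.
#' @export
restitution_params <- function(apd_max = 60, tau_rest = 120,
                               cat_decay_tau = 0.012,
                               cat_amp_tau_refr = 60,
                               rise_time = 12, cat90_scale = 1.4) {
  check_positive(apd_max, "apd_max")
  check_positive(tau_rest, "tau_rest")
  check_positive(cat_decay_tau, "cat_decay_tau")
  check_positive(cat_amp_tau_refr, "cat_amp_tau_refr")
  check_positive(rise_time, "rise_time")
  check_positive(cat90_scale, "cat90_scale")
  structure(list(apd_max = apd_max, tau_rest = tau_rest,
                 cat_decay_tau = cat_decay_tau,
                 cat_amp_tau_refr = cat_amp_tau_refr,
                 rise_time = rise_time, cat90_scale = cat90_scale),
            class = "restitution_params")
}

#' Define a synthetic 2-D tissue
#'
#' The tissue is a rectangular pixel grid paced from `pacing_site`;
#' excitation spreads as a target (circular) wave at a uniform conduction
#' velocity. The grid is partitioned into regions, each with its own
#' restitution parameters and an alternans phase offset (0 or 1 beat), so
#' spatially discordant alternans can be imposed by construction. The
#' canonical phenotype layout is four quadrants with one quadrant offset
#' by one beat (see [quadrant_regions()]).
#'
#' @param grid_rows,grid_cols Pixel counts (each at least 8).
#' @param pixel_pitch Pixel size, mm per pixel.
#' @param conduction_velocity Wavefront speed, mm/ms.
#' @param pacing_site `(row, col)` of the stimulating electrode.
#' @param regions List of regions, each a list with elements `mask`
#'   (logical `grid_rows x grid_cols` matrix), `params`
#'   (a [restitution_params()]), `phase_offset` (0 or 1 beat) and
#'   optionally `amp_alternans` (an imposed CaT-amplitude alternans
#'   fraction in `[0, 1)`; when `NULL` the amplitude alternans is coupled
#'   to the restitution-map APD orbit). Region masks must partition the
#'   grid. `NULL` means one homogeneous region with default parameters.
#' @param aerp_ms The tissue's true atrial effective refractory period, ms:
#'   premature stimuli with coupling interval below this fail to capture.
#' @return A `tissue_spec` list.
#' @export
tissue_spec <- function(grid_rows = 16, grid_cols = 16, pixel_pitch = 0.1,
                        conduction_velocity = 0.5, pacing_site = c(1, 1),
                        regions = NULL, aerp_ms = 50) {
  if (grid_rows < 8 || grid_cols < 8) {
    stop_invalid("grid must be at least 8 x 8")
  }
  check_positive(pixel_pitch, "pixel_pitch")
  check_positive(conduction_velocity, "conduction_velocity")
  check_positive(aerp_ms, "aerp_ms")
  if (length(pacing_site) != 2L || any(pacing_site < 1) ||
      pacing_site[1] > grid_rows || pacing_site[2] > grid_cols) {
    stop_invalid("pacing_site must be a (row, col) pair inside the grid")
  }
  if (is.null(regions)) {
    regions <- list(list(mask = matrix(TRUE, grid_rows, grid_cols),
                         params = restitution_params(), phase_offset = 0,
                         amp_alternans = NULL))
  }
  cover <- matrix(0L, grid_rows, grid_cols)
  for (rg in regions) {
    if (!is.matrix(rg$mask) ||
        !all(dim(rg$mask) == c(grid_rows, grid_cols))) {
      stop_invalid("each region mask must be a grid_rows x grid_cols matrix")
    }
    if (!inherits(rg$params, "restitution_params")) {
      stop_invalid("each region needs restitution_params")
    }
    if (!rg$phase_offset %in% c(0, 1)) {
      stop_invalid("phase_offset must be 0 or 1")
    }
    cover <- cover + rg$mask
  }
  if (any(cover != 1L)) {
    stop_invalid("region masks must partition the grid (each pixel in ",
                 "exactly one region)")
  }
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 pixel_pitch = pixel_pitch,
                 conduction_velocity = conduction_velocity,
                 pacing_site = as.integer(pacing_site),
                 regions = regions, aerp_ms = aerp_ms),
            class = "tissue_spec")
}

#' Four-quadrant region layout with one phase-offset quadrant
#'
#' Convenience constructor for the canonical discordant-alternans layout:
#' the grid is split into four quadrants sharing (or varying) restitution
#' parameters, with the quadrants listed in `offset_quadrants` shifted by
#' one beat so they alternate in the opposite phase.
#'
#' @param grid_rows,grid_cols Grid size.
#' @param params A single [restitution_params()] (recycled) or a list of 4.
#' @param offset_quadrants Integer indices (1 = top-left, 2 = top-right,
#'   3 = bottom-left, 4 = bottom-right) given a one-beat phase offset.
#' @param amp_alternans Optional imposed CaT-amplitude alternans fraction,
#'   recycled across quadrants.
#' @return A list of 4 regions suitable for [tissue_spec()].
#' @export
quadrant_regions <- function(grid_rows, grid_cols,
                             params = restitution_params(),
                             offset_quadrants = 4L,
                             amp_alternans = NULL) {
  if (inherits(params, "restitution_params")) params <- rep(list(params), 4)
  if (!is.null(amp_alternans) && length(amp_alternans) == 1L) {
    amp_alternans <- rep(list(amp_alternans), 4)
  }
  rh <- floor(grid_rows / 2); ch <- floor(grid_cols / 2)
  rows_top <- seq_len(rh); cols_left <- seq_len(ch)
  qmask <- function(rows, cols) {
    m <- matrix(FALSE, grid_rows, grid_cols); m[rows, cols] <- TRUE; m
  }
  masks <- list(qmask(rows_top, cols_left),
                qmask(rows_top, (ch + 1):grid_cols),
                qmask((rh + 1):grid_rows, cols_left),
                qmask((rh + 1):grid_rows, (ch + 1):grid_cols))
  lapply(1:4, function(i) list(
    mask = masks[[i]], params = params[[i]],
    phase_offset = as.integer(i %in% offset_quadrants),
    amp_alternans = if (is.null(amp_alternans)) NULL else amp_alternans[[i]]
  ))
}

#' Pacing-protocol specification
#'
#' @param mode One of `"sinus"` (intrinsic-like rhythm, stimulus times not
#'   recorded in the movie metadata), `"fixed_rate"`, `"S1S1_decremental"`
#'   (drive trains at progressively shorter cycle lengths) or
#'   `"S1S2_extrastimulus"` (drive train plus one premature beat per tested
#'   coupling interval).
#' @param s1_cycle_length Drive-train cycle length, ms (167 ms is 6 Hz).
#' @param s1_count Beats per drive train.
#' @param s2_intervals Premature-beat coupling intervals, ms (S1S2 mode).
#' @param cl_sequence Strictly decreasing cycle lengths, ms (decremental
#'   mode).
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(mode = c("fixed_rate", "sinus",
                                   "S1S1_decremental", "S1S2_extrastimulus"),
                          s1_cycle_length = 167, s1_count = 8,
                          s2_intervals = NULL, cl_sequence = NULL) {
  mode <- match.arg(mode)
  check_positive(s1_cycle_length, "s1_cycle_length")
  if (mode == "S1S2_extrastimulus") {
    if (s1_count < 1 || length(s2_intervals) == 0) {
      stop_invalid("S1S2 mode requires s1_count >= 1 and s2_intervals")
    }
  }
  if (mode == "S1S1_decremental") {
    if (length(cl_sequence) < 1 || any(diff(cl_sequence) >= 0)) {
      stop_invalid("cl_sequence must be non-empty and strictly decreasing")
    }
  }
  structure(list(mode = mode, s1_cycle_length = s1_cycle_length,
                 s1_count = as.integer(s1_count),
                 s2_intervals = s2_intervals, cl_sequence = cl_sequence),
            class = "protocol_spec")
}

#' Sensor-noise specification
#'
#' @param sigma Standard deviation of additive i.i.d. Gaussian noise, in
#'   fractional units of the unit beat amplitude.
#' @param seed Integer seed for the noise stream.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(sigma = 0, seed = 1L) {
  if (!is.numeric(sigma) || sigma < 0) stop_invalid("sigma must be >= 0")
  structure(list(sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Iterate the APD restitution map
#'
#' Standard restitution dynamics: `APD[n+1] = f(CL - APD[n])` with
#' `f(DI) = apd_max * (1 - exp(-DI / tau_rest))` and the diastolic interval
#' clipped below at `di_floor` so the map is total at aggressive cycle
#' lengths. The fixed point is stable (period-1, no alternans) when
#' `|f'(DI*)| < 1` and bifurcates to a period-2 alternans orbit when
#' `|f'(DI*)| > 1`; see [restitution_slope()].
#'
#' @param params A [restitution_params()].
#' @param cycle_length Pacing cycle length, ms.
#' @param n_beats Number of iterates to return (at least 2).
#' @param apd_init Initial APD, ms (default `apd_max / 2`).
#' @param di_floor Diastolic-interval floor, ms.
#' @return Numeric vector of `n_beats` successive APD values (the iterates
#'   after `apd_init`).
#' @export
iterate_restitution <- function(params, cycle_length, n_beats,
                                apd_init = params$apd_max / 2,
                                di_floor = 5) {
  stopifnot(inherits(params, "restitution_params"))
  check_positive(cycle_length, "cycle_length")
  if (n_beats < 2) stop_invalid("n_beats must be at least 2")
  f <- function(apd) {
    di <- max(cycle_length - apd, di_floor)
    params$apd_max * (1 - exp(-di / params$tau_rest))
  }
  out <- numeric(n_beats)
  cur <- apd_init
  for (i in seq_len(n_beats)) {
    cur <- f(cur)
    out[i] <- cur
  }
  out
}

#' Fixed point and slope of the restitution map
#'
#' Solves `APD* = f(CL - APD*)` and returns the map slope
#' `f'(DI*) = (apd_max / tau_rest) * exp(-DI* / tau_rest)` at the fixed
#' point, the linear-stability criterion for alternans onset.
#'
#' @inheritParams iterate_restitution
#' @return List with `apd_star`, `di_star` and `slope`.
#' @export
restitution_slope <- function(params, cycle_length, di_floor = 5) {
  f <- function(apd) {
    di <- pmax(cycle_length - apd, di_floor)
    params$apd_max * (1 - exp(-di / params$tau_rest))
  }
  g <- function(x) f(x) - x
  root <- uniroot(g, c(0, params$apd_max + 1), tol = 1e-10)
  apd_star <- root$root
  di_star <- max(cycle_length - apd_star, di_floor)
  slope <- params$apd_max / params$tau_rest * exp(-di_star / params$tau_rest)
  list(apd_star = apd_star, di_star = di_star, slope = slope)
}

# Build the stimulus/beat schedule for a protocol. Returns a data.frame:
# time_ms (stimulus time), type ("S1"/"S2"), train (index), interval
# (coupling interval for S2, else NA), captured (FALSE when an S2 falls
# below the generator AERP).
build_schedule <- function(tissue, protocol, t_pre = 20) {
  p <- protocol
  rows <- list()
  add <- function(time, type, train, interval = NA_real_, captured = TRUE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      time_ms = time, type = type, train = train,
      interval = interval, captured = captured)
  }
  t <- t_pre
  if (p$mode %in% c("sinus", "fixed_rate")) {
    for (i in seq_len(p$s1_count)) {
      add(t, "S1", 1L); t <- t + p$s1_cycle_length
    }
  } else if (p$mode == "S1S1_decremental") {
    for (k in seq_along(p$cl_sequence)) {
      cl <- p$cl_sequence[k]
      for (i in seq_len(p$s1_count)) {
        add(t, "S1", k); t <- t + cl
      }
    }
  } else { # S1S2_extrastimulus
    for (k in seq_along(p$s2_intervals)) {
      s2 <- p$s2_intervals[k]
      for (i in seq_len(p$s1_count)) {
        add(t, "S1", k)
        t <- t + if (i < p$s1_count) p$s1_cycle_length else 0
      }
      captured <- s2 >= tissue$aerp_ms
      add(t + s2, "S2", k, interval = s2, captured = captured)
      t <- t + s2 + 2 * p$s1_cycle_length
    }
  }
  do.call(rbind, rows)
}

# Per-region per-beat APD/CaT/amplitude sequences consistent with the
# restitution map. Burn-in at the first inter-beat interval reaches the
# steady orbit; a one-beat phase offset is realized by one extra burn-in
# iterate, which flips the parity of a period-2 orbit.
region_beat_params <- function(region, schedule, protocol, di_floor = 5) {
  par <- region$params
  f <- function(apd, interval) {
    par$apd_max * (1 - exp(-max(interval - apd, di_floor) / par$tau_rest))
  }
  n <- nrow(schedule)
  first_int <- if (n >= 2) schedule$time_ms[2] - schedule$time_ms[1]
               else protocol$s1_cycle_length
  cur <- par$apd_max / 2
  for (i in seq_len(200 + region$phase_offset)) cur <- f(cur, first_int)
  apd <- numeric(n)
  prev_time <- schedule$time_ms[1] - first_int
  for (i in seq_len(n)) {
    interval <- schedule$time_ms[i] - prev_time
    cur <- f(cur, interval)
    apd[i] <- cur
    prev_time <- schedule$time_ms[i]
  }
  # CaT amplitude: S2 beats recover with the refractoriness constant;
  # S1-beat alternans either imposed explicitly or coupled to the APD orbit.
  amp_cat <- rep(1, n)
  s1 <- schedule$type == "S1"
  if (!is.null(region$amp_alternans) && region$amp_alternans > 0) {
    parity <- (seq_len(n) + region$phase_offset) %% 2
    amp_cat[s1] <- ifelse(parity[s1] == 1, 1, 1 - region$amp_alternans)
  } else if (any(s1)) {
    amp_cat[s1] <- apd[s1] / max(apd[s1])
  }
  is_s2 <- schedule$type == "S2"
  amp_cat[is_s2] <- 1 - exp(-schedule$interval[is_s2] / par$cat_amp_tau_refr)
  amp_v <- rep(1, n)
  list(apd = apd, amp_cat = amp_cat, amp_v = amp_v)
}

#' Simulate a dual-channel optical-mapping movie with ground truth
#'
#' Emits a voltage-channel and a calcium-channel [movie()] of a paced 2-D
#' tissue together with exact ground-truth labels. A target wave spreads
#' from the pacing site at the tissue's conduction velocity; each pixel
#' plays the single-beat waveforms of its region ([make_ap_waveform()],
#' [make_cat_waveform()]) with per-beat APDs from the restitution map
#' ([iterate_restitution()]), regional alternans phase offsets, premature
#' (S2) calcium transients scaled by
#' `1 - exp(-interval / cat_amp_tau_refr)`, and additive Gaussian sensor
#' noise. Premature stimuli below the tissue AERP elicit no beat and are
#' flagged non-captured in the ground truth. Repolarization is truncated
#' when the next stimulus arrives before it completes (the emitted
#' duration, recorded in the truth maps, is capped at 85% of the interval
#' to the next beat).
#'
#' @param tissue A [tissue_spec()].
#' @param protocol A [protocol_spec()].
#' @param noise A [noise_spec()].
#' @param frame_rate Camera sampling rate, Hz (default 900).
#' @return List with elements `voltage` and `calcium` (class `om_movie`)
#'   and `truth`, a list carrying the schedule (with capture flags),
#'   per-beat per-pixel activation-time / APD90 / CaT90 arrays
#'   (`beat x row x col`), per-region beat parameter sequences, regional
#'   alternans magnitude and phase, the region index map, and the true
#'   AERP.
#' @export
simulate_movie <- function(tissue, protocol, noise = noise_spec(),
                           frame_rate = 900) {
  stopifnot(inherits(tissue, "tissue_spec"),
            inherits(protocol, "protocol_spec"),
            inherits(noise, "noise_spec"))
  fp <- 1000 / frame_rate
  nr <- tissue$grid_rows; nc <- tissue$grid_cols
  sched <- build_schedule(tissue, protocol)
  emitted <- sched[sched$captured, , drop = FALSE]
  nb <- nrow(emitted)

  # conduction delay map (target wave from the pacing site)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dist_mm <- sqrt((rr - tissue$pacing_site[1])^2 +
                  (cc - tissue$pacing_site[2])^2) * tissue$pixel_pitch
  delay <- dist_mm / tissue$conduction_velocity

  region_map <- matrix(0L, nr, nc)
  for (k in seq_along(tissue$regions)) {
    region_map[tissue$regions[[k]]$mask] <- k
  }

  # per-region per-beat waveform parameters (with truncation caps)
  next_gap <- c(diff(emitted$time_ms), Inf)
  reg_seq <- lapply(tissue$regions, region_beat_params, schedule = emitted,
                    protocol = protocol)
  reg_beats <- vector("list", length(tissue$regions))
  for (k in seq_along(tissue$regions)) {
    par <- tissue$regions[[k]]$params
    s <- reg_seq[[k]]
    apd_eff <- pmin(s$apd, 0.85 * next_gap)
    tau_ms <- par$cat_decay_tau * 1000
    cat_min <- par$rise_time / 2 + tau_ms * log(10) + 1e-6
    cat_eff <- pmax(pmin(par$cat90_scale * s$apd, 0.85 * next_gap), cat_min)
    reg_beats[[k]] <- list(
      apd90 = apd_eff, cat90 = cat_eff,
      amp_v = s$amp_v, amp_cat = s$amp_cat,
      ap_fun = lapply(apd_eff, ap_wave_fun, rise_time = par$rise_time),
      ap_dur = ap_wave_duration(apd_eff, par$rise_time),
      cat_fun = lapply(cat_eff, cat_wave_fun, rise_time = par$rise_time,
                       decay_tau = par$cat_decay_tau),
      cat_dur = par$rise_time +
        pmax(cat_eff - par$rise_time / 2 - tau_ms * log(10), 0) +
        tau_ms * log(1000),
      rise_time = par$rise_time
    )
  }

  t_end <- max(emitted$time_ms) + max(delay) +
    max(vapply(reg_beats, function(b) max(b$ap_dur, b$cat_dur), 0)) + 30
  n_frames <- ceiling(t_end / fp) + 1L
  t_frames <- (seq_len(n_frames) - 1) * fp

  v_arr <- array(0, c(n_frames, nr, nc))
  c_arr <- array(0, c(n_frames, nr, nc))
  act_truth <- array(NA_real_, c(nb, nr, nc))
  apd_truth <- array(NA_real_, c(nb, nr, nc))
  cat_truth <- array(NA_real_, c(nb, nr, nc))

  for (px_r in seq_len(nr)) {
    for (px_c in seq_len(nc)) {
      k <- region_map[px_r, px_c]
      b <- reg_beats[[k]]
      rise <- b$rise_time
      vtr <- numeric(n_frames); ctr <- numeric(n_frames)
      for (i in seq_len(nb)) {
        t0 <- emitted$time_ms[i] + delay[px_r, px_c]
        act_truth[i, px_r, px_c] <- t0 + rise / 2
        apd_truth[i, px_r, px_c] <- b$apd90[i]
        cat_truth[i, px_r, px_c] <- b$cat90[i]
        i0 <- max(1L, floor(t0 / fp) + 1L)
        i1 <- min(n_frames, ceiling((t0 + max(b$ap_dur[i], b$cat_dur[i])) / fp) + 1L)
        if (i1 < i0) next
        idx <- i0:i1
        tt <- t_frames[idx] - t0
        vtr[idx] <- vtr[idx] + b$amp_v[i] * b$ap_fun[[i]](tt)
        ctr[idx] <- ctr[idx] + b$amp_cat[i] * b$cat_fun[[i]](tt)
      }
      v_arr[, px_r, px_c] <- vtr
      c_arr[, px_r, px_c] <- ctr
    }
  }

  if (noise$sigma > 0) {
    with_seed(noise$seed, {
      v_arr <- v_arr + rnorm(length(v_arr), sd = noise$sigma)
      c_arr <- c_arr + rnorm(length(c_arr), sd = noise$sigma)
    })
  }

  stim <- if (protocol$mode == "sinus") numeric(0) else sched$time_ms
  mv <- movie(v_arr, frame_rate = frame_rate,
              pixel_pitch = tissue$pixel_pitch, channel = "voltage",
              stimulus_times = stim)
  mc <- movie(c_arr, frame_rate = frame_rate,
              pixel_pitch = tissue$pixel_pitch, channel = "calcium",
              stimulus_times = stim)

  # regional alternans truth from the emitted S1 sequences
  s1_idx <- which(emitted$type == "S1")
  region_alt <- lapply(seq_along(tissue$regions), function(k) {
    amp <- reg_beats[[k]]$amp_cat[s1_idx]
    apd <- reg_beats[[k]]$apd90[s1_idx]
    two_group <- function(x) {
      odd <- mean(x[seq_along(x) %% 2 == 1])
      even <- mean(x[seq_along(x) %% 2 == 0])
      list(magnitude = 1 - min(odd, even) / max(odd, even),
           phase = if (odd >= even) 1L else -1L)
    }
    a <- two_group(amp); d <- two_group(apd)
    list(amp_magnitude = a$magnitude, amp_phase = a$phase,
         apd_magnitude = d$magnitude, apd_phase = d$phase)
  })

  truth <- list(
    schedule = sched, emitted = emitted,
    activation_ms = act_truth, apd90_ms = apd_truth, cat90_ms = cat_truth,
    delay_ms = delay, region_map = region_map,
    region_beats = lapply(reg_beats, function(b)
      b[c("apd90", "cat90", "amp_v", "amp_cat")]),
    region_alternans = region_alt,
    aerp_ms = tissue$aerp_ms,
    rise_time_ms = vapply(tissue$regions, function(r) r$params$rise_time, 0)
  )
  list(voltage = mv, calcium = mc, truth = truth)
}

#' Simulate an activation-time series with fibrillation-like episodes
#'
#' Generates a beat (activation) time series at a regular baseline cycle
#' length, interrupted by labelled episodes of rapid irregular cycles
#' (cycle lengths drawn from a truncated Gaussian), emulating induced
#' atrial tachycardia / fibrillation runs.
#'
#' @param baseline_cl Baseline cycle length, ms.
#' @param episodes List of episodes, each a list/vector with `start`, `end`
#'   (ms, disjoint, inside the recording) and `mean_cl`, `cl_jitter` (ms);
#'   `mean_cl` must be below `0.6 * baseline_cl`.
#' @param duration Recording length, ms.
#' @param seed Integer seed.
#' @return List of class `af_trace` with `activation_times` (ms),
#'   `episodes` (the truth labels as a data.frame) and `baseline_cl`.
#' @export
simulate_af_trace <- function(baseline_cl, episodes = list(), duration,
                              seed = 1L) {
  check_positive(baseline_cl, "baseline_cl")
  check_positive(duration, "duration")
  ep <- if (length(episodes)) {
    do.call(rbind, lapply(episodes, function(e) {
      data.frame(start = e$start, end = e$end, mean_cl = e$mean_cl,
                 cl_jitter = e$cl_jitter)
    }))
  } else {
    data.frame(start = numeric(0), end = numeric(0),
               mean_cl = numeric(0), cl_jitter = numeric(0))
  }
  if (nrow(ep)) {
    ep <- ep[order(ep$start), , drop = FALSE]
    if (any(ep$start < 0 | ep$end > duration | ep$end <= ep$start)) {
      stop_invalid("episodes must lie inside the recording")
    }
    if (nrow(ep) > 1 && any(ep$start[-1] < ep$end[-nrow(ep)])) {
      stop_invalid("episodes must be disjoint")
    }
    if (any(ep$mean_cl >= 0.6 * baseline_cl)) {
      stop_invalid("episode mean_cl must be < 0.6 * baseline_cl")
    }
  }
  times <- with_seed(seed, {
    t <- 0; out <- numeric(0)
    while (t <= duration) {
      out <- c(out, t)
      k <- if (nrow(ep)) which(t >= ep$start & t < ep$end) else integer(0)
      cl <- if (length(k)) {
        max(rnorm(1, ep$mean_cl[k[1]], ep$cl_jitter[k[1]]),
            0.3 * ep$mean_cl[k[1]])
      } else baseline_cl
      t <- t + cl
    }
    out
  })
  structure(list(activation_times = times, episodes = ep,
                 baseline_cl = baseline_cl, duration = duration,
                 seed = as.integer(seed)),
            class = "af_trace")
}

#' Generate a synthetic concentration-inhibition table
#'
#' Draws percent-inhibition values from a four-parameter logistic
#' `bottom + (top - bottom) / (1 + (ic50 / conc)^hill)` plus Gaussian
#' noise, for validating [fit_hill()].
#'
#' @param ic50 Half-maximal inhibitory concentration (same units as
#'   `concs`).
#' @param hill Hill slope.
#' @param concs Positive concentrations.
#' @param top,bottom Upper and lower plateaus (percent).
#' @param noise Gaussian noise SD (percent).
#' @param seed Integer seed.
#' @return data.frame with columns `concentration` and `response`.
#' @export
make_dose_response <- function(ic50, hill, concs, top = 100, bottom = 0,
                               noise = 0, seed = 1L) {
  check_positive(ic50, "ic50")
  if (any(concs <= 0)) stop_invalid("concentrations must be positive")
  y <- bottom + (top - bottom) / (1 + (ic50 / concs)^hill)
  if (noise > 0) {
    y <- with_seed(seed, y + rnorm(length(y), sd = noise))
  }
  data.frame(concentration = concs, response = y)
}
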