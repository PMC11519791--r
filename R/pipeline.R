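# Configured, seeded end-to-end pipeline: simulate -> preprocess ->
# analyze -> report.

#' Group parameter set for the synthetic pipeline
#'
#' Bundles the generator parameters describing one experimental "group"
#' (one heart phenotype). [sham_like_group()] and [model_like_group()]
#' provide the two canonical phenotypes: the diseased phenotype has
#' longer APD/CaT, a steeper effective restitution (alternans at longer
#' cycle lengths), more spatial heterogeneity, slower conduction, slower
#' CaT decay, a smaller refractory-period-to-APD ratio and inducible
#' fibrillation-like episodes.
#'
#' @param apd_max,tau_rest,cat_decay_tau,cat_amp_tau_refr,rise_time See
#'   [restitution_params()].
#' @param apd_heterogeneity Fractional spread of `apd_max` across the four
#'   quadrants.
#' @param conduction_velocity mm/ms.
#' @param aerp_ms True refractory period, ms.
#' @param offset_quadrants Quadrants alternating in opposite phase.
#' @param af_episodes Episode list for [simulate_af_trace()] (may be
#'   empty).
#' @param snrt_excess_ms Pause in excess of the baseline cycle after
#'   overdrive pacing.
#' @param caffeine_rise_s Upstroke duration of the caffeine-evoked
#'   transient, s.
#' @param serca_tau_s Amplitude-recovery time constant, s.
#' @param calcium Emit/analyze the calcium channel.
#' @return A `pipeline_group` list.
#' @export
pipeline_group <- function(apd_max = 60, tau_rest = 40,
                           cat_decay_tau = 0.012, cat_amp_tau_refr = 60,
                           rise_time = 12, apd_heterogeneity = 0.05,
                           conduction_velocity = 0.5, aerp_ms = 60,
                           offset_quadrants = 4L,
                           af_episodes = list(), snrt_excess_ms = 150,
                           caffeine_rise_s = 0.021, serca_tau_s = 4,
                           calcium = TRUE) {
  structure(as.list(environment()), class = "pipeline_group")
}

#' @rdname pipeline_group
#' @export
sham_like_group <- function() {
  pipeline_group(apd_max = 45, tau_rest = 40, cat_decay_tau = 0.01,
                 cat_amp_tau_refr = 40, rise_time = 12,
                 apd_heterogeneity = 0.02, conduction_velocity = 0.8,
                 aerp_ms = 60, af_episodes = list(),
                 snrt_excess_ms = 60, caffeine_rise_s = 0.021,
                 serca_tau_s = 2)
}

#' @rdname pipeline_group
#' @export
model_like_group <- function() {
  pipeline_group(apd_max = 120, tau_rest = 40, cat_decay_tau = 0.02,
                 cat_amp_tau_refr = 80, rise_time = 25,
                 apd_heterogeneity = 0.12, conduction_velocity = 0.3,
                 aerp_ms = 70,
                 af_episodes = list(
                   list(start = 2000, end = 7000, mean_cl = 80,
                        cl_jitter = 12),
                   list(start = 12000, end = 15000, mean_cl = 80,
                        cl_jitter = 12)),
                 snrt_excess_ms = 250, caffeine_rise_s = 0.035,
                 serca_tau_s = 6)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis pipeline in one
#' validated object. Configurations round-trip losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param groups Named list of [pipeline_group()]s.
#' @param seed Master seed; every random stage derives its own stream
#'   from it.
#' @param grid_rows,grid_cols Tissue grid.
#' @param frame_rate Hz.
#' @param pixel_pitch mm.
#' @param noise_sigma Sensor-noise SD (fraction of beat amplitude).
#' @param levels Repolarization levels measured.
#' @param k_threshold Spectral alternans significance threshold.
#' @param fixed_rate_cl,fixed_rate_beats Fixed-rate mapping stage.
#' @param alternans_cls Cycle lengths of the alternans sweep, ms.
#' @param alternans_beats Beats per alternans run (first
#'   `alternans_skip` discarded as pre-steady-state).
#' @param alternans_skip Beats discarded before alternans analysis.
#' @param s2_intervals S1S2 coupling intervals, ms.
#' @param s1_count Drive beats per S1S2 train.
#' @param sites Four `(row, col)` analysis sites (`NULL` = quadrant
#'   centres).
#' @param af_baseline_cl,af_duration AF-simulation stage, ms.
#' @param af_criteria List of [detect_episodes()] thresholds.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(groups = list(sham = sham_like_group(),
                                          model = model_like_group()),
                            seed = 1L, grid_rows = 12, grid_cols = 12,
                            frame_rate = 900, pixel_pitch = 0.1,
                            noise_sigma = 0.02,
                            levels = c(0.3, 0.8, 0.9), k_threshold = 3,
                            fixed_rate_cl = 167, fixed_rate_beats = 6,
                            alternans_cls = c(100, 70),
                            alternans_beats = 14, alternans_skip = 4,
                            s2_intervals = c(150, 120, 90, 70, 50, 40, 30),
                            s1_count = 4, sites = NULL,
                            af_baseline_cl = 200, af_duration = 20000,
                            af_criteria = list(min_cycles = 5,
                                               mean_frac = 0.6,
                                               cv_min = 0.1,
                                               candidate_frac = 0.75)) {
  cfg <- as.list(environment())
  validate_pipeline_config(cfg)
  if (is.null(cfg$sites)) {
    qr <- round(grid_rows * c(0.25, 0.25, 0.75, 0.75))
    qc <- round(grid_cols * c(0.25, 0.75, 0.25, 0.75))
    cfg$sites <- lapply(1:4, function(i) c(qr[i], qc[i]))
  }
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  fail <- function(...) stop_invalid("config schema error: ", ...)
  if (!length(cfg$groups) || is.null(names(cfg$groups)) ||
      any(names(cfg$groups) == "")) fail("groups must be a named list")
  for (g in cfg$groups) {
    if (!inherits(g, "pipeline_group")) fail("each group must be a pipeline_group")
  }
  if (cfg$grid_rows < 8 || cfg$grid_cols < 8) fail("grid must be >= 8 x 8")
  if (cfg$noise_sigma < 0 || cfg$noise_sigma > 0.5) {
    fail("noise_sigma must be in [0, 0.5]")
  }
  if (any(cfg$levels <= 0 | cfg$levels >= 1)) fail("levels must be in (0, 1)")
  if (cfg$k_threshold < 1 || cfg$k_threshold > 10) {
    fail("k_threshold must be in [1, 10]")
  }
  if (cfg$alternans_beats - cfg$alternans_skip < 8) {
    fail("need >= 8 analyzed alternans beats")
  }
  if (cfg$s1_count < 3) fail("s1_count must be >= 3 (S1 reference uses 3 beats)")
  invisible(TRUE)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns the reconstructed, validated
#'   `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  plain <- unclass(cfg)
  plain$groups <- lapply(plain$groups, unclass)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  plain <- yaml::read_yaml(path)
  plain$groups <- lapply(plain$groups, function(g) {
    if (length(g$af_episodes)) {
      g$af_episodes <- lapply(g$af_episodes, as.list)
    }
    do.call(pipeline_group, g)
  })
  do.call(pipeline_config, plain)
}

group_tissue <- function(cfg, grp) {
  scales <- 1 + grp$apd_heterogeneity * c(-1, -1 / 3, 1 / 3, 1)
  params <- lapply(scales, function(s) {
    restitution_params(apd_max = grp$apd_max * s, tau_rest = grp$tau_rest,
                       cat_decay_tau = grp$cat_decay_tau,
                       cat_amp_tau_refr = grp$cat_amp_tau_refr,
                       rise_time = grp$rise_time)
  })
  tissue_spec(grid_rows = cfg$grid_rows, grid_cols = cfg$grid_cols,
              pixel_pitch = cfg$pixel_pitch,
              conduction_velocity = grp$conduction_velocity,
              pacing_site = c(1, 1),
              regions = quadrant_regions(cfg$grid_rows, cfg$grid_cols,
                                         params = params,
                                         offset_quadrants = grp$offset_quadrants),
              aerp_ms = grp$aerp_ms)
}

map_summary <- function(fs, beat, feature) {
  mp <- feature_map(fs, feature, beat)
  mean(mp[is.finite(mp)])
}

analyze_group <- function(cfg, grp, gname, gseed) {
  rows <- list()
  emit <- function(stage, metric, value, cl = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      group = gname, stage = stage, metric = metric,
      cycle_length = cl, value = as.numeric(value))
  }
  tissue <- group_tissue(cfg, grp)
  mid_beat <- function(fs) max(2L, nrow(fs$windows) - 1L)

  ## stage 1: fixed-rate mapping
  sim <- simulate_movie(tissue,
                        protocol_spec("fixed_rate",
                                      s1_cycle_length = cfg$fixed_rate_cl,
                                      s1_count = cfg$fixed_rate_beats),
                        noise_spec(cfg$noise_sigma, gseed),
                        frame_rate = cfg$frame_rate)
  mv <- spatial_gaussian3(sim$voltage)
  wins <- segment_beats(mv)
  fsv <- measure_beats(mv, wins, levels = cfg$levels)
  b <- mid_beat(fsv)
  apd90 <- map_summary(fsv, b, "d90")
  emit("fixed_rate", "apd90", apd90, cfg$fixed_rate_cl)
  emit("fixed_rate", "apd30_80",
       map_summary(fsv, b, "d30") / map_summary(fsv, b, "d80"),
       cfg$fixed_rate_cl)
  emit("fixed_rate", "ap_rise_time", map_summary(fsv, b, "rise"),
       cfg$fixed_rate_cl)
  emit("fixed_rate", "apd90_iqr",
       heterogeneity_iqr(feature_map(fsv, "d90", b)), cfg$fixed_rate_cl)
  cv <- conduction_velocity(feature_map(fsv, "activation", b),
                            cfg$pixel_pitch)
  emit("fixed_rate", "velocity", cv$mean_speed, cfg$fixed_rate_cl)
  if (grp$calcium) {
    mc <- spatial_gaussian3(sim$calcium)
    fsc <- measure_beats(mc, wins, levels = cfg$levels)
    emit("fixed_rate", "cat90", map_summary(fsc, b, "d90"),
         cfg$fixed_rate_cl)
    emit("fixed_rate", "cat_rise_time", map_summary(fsc, b, "rise"),
         cfg$fixed_rate_cl)
    emit("fixed_rate", "cat90_iqr",
         heterogeneity_iqr(feature_map(fsc, "d90", b)), cfg$fixed_rate_cl)
    mean_ca <- apply(mc$frames, 1, mean)
    emit("fixed_rate", "tau",
         decay_tau(mean_ca, wins[b, ], frame_period_ms(mc)),
         cfg$fixed_rate_cl)
  } else {
    for (mtr in c("cat90", "cat_rise_time", "cat90_iqr", "tau")) {
      emit("fixed_rate", mtr, NA_real_, cfg$fixed_rate_cl)
    }
  }

  ## stage 2: alternans sweep
  for (cl in cfg$alternans_cls) {
    if (!grp$calcium) { emit("alternans", "cat_alternans", NA_real_, cl); next }
    sa <- simulate_movie(tissue,
                         protocol_spec("fixed_rate", s1_cycle_length = cl,
                                       s1_count = cfg$alternans_beats),
                         noise_spec(cfg$noise_sigma, gseed + 7L + cl),
                         frame_rate = cfg$frame_rate)
    mca <- spatial_gaussian3(sa$calcium)
    winsa <- segment_beats(mca)
    keep <- (cfg$alternans_skip + 1L):nrow(winsa)
    amps <- beat_amplitudes(mca, winsa)[keep, , , drop = FALSE]
    alt <- alternans_analysis(amps, cycle_length = cl,
                              k_threshold = cfg$k_threshold)
    emit("alternans", "cat_alternans", alt$mean_magnitude, cl)
    emit("alternans", "discordance", alt$discordance, cl)
  }

  ## stage 3: S1S2 restitution and refractoriness
  ss <- simulate_movie(tissue,
                       protocol_spec("S1S2_extrastimulus",
                                     s1_cycle_length = cfg$fixed_rate_cl,
                                     s1_count = cfg$s1_count,
                                     s2_intervals = cfg$s2_intervals),
                       noise_spec(cfg$noise_sigma, gseed + 101L),
                       frame_rate = cfg$frame_rate)
  mvs <- spatial_gaussian3(ss$voltage)
  winss <- segment_beats(mvs)
  sched <- ss$truth$schedule
  ampv <- beat_amplitudes(mvs, winss)
  emitted <- ss$truth$emitted
  # capture per scheduled S2: non-emitted stimuli have no matching window
  # only when the generator suppressed them, so align on the schedule
  win_of_sched <- match(round(sched$time_ms, 6),
                        round(winss$ref_time_ms, 6))
  ref_beats <- win_of_sched[sched$type == "S1" & sched$train == 1]
  cap_all <- detect_capture(ampv, ref_beats[!is.na(ref_beats)])
  s2_rows <- which(sched$type == "S2")
  s2_cap <- cap_all[win_of_sched[s2_rows]]
  aerp <- aerp_from_s1s2(sched$interval[s2_rows], s2_cap)
  emit("s1s2", "aerp", if (aerp$status == "ok") aerp$aerp else NA_real_)
  emit("s1s2", "aerp_apd", if (aerp$status == "ok") aerp$aerp / apd90
                           else NA_real_)
  if (grp$calcium) {
    mcs <- spatial_gaussian3(ss$calcium)
    ampc <- beat_amplitudes(mcs, winss)
    labels <- sched
    labels$win <- win_of_sched
    labels <- labels[!is.na(labels$win), ]
    lab <- data.frame(type = labels$type, train = labels$train,
                      interval = labels$interval)[order(labels$win), ]
    ratios <- s2s1_ratio(ampc, lab, sites = cfg$sites)
    for (i in seq_len(nrow(ratios))) {
      emit("s1s2", "s2s1_ratio", ratios$ratio[i], cl = ratios$interval[i])
    }
    ok <- ratios$captured
    if (sum(ok) >= 4) {
      rf <- fit_restitution(ratios$interval[ok], ratios$ratio[ok])
      emit("s1s2", "restitution_tau", rf$tau_r)
      emit("s1s2", "restitution_steepness", rf$steepness)
    }
  }

  ## stage 4: AF inducibility
  af <- simulate_af_trace(cfg$af_baseline_cl, grp$af_episodes,
                          cfg$af_duration, seed = gseed + 211L)
  rep_af <- detect_episodes(af$activation_times, cfg$af_baseline_cl,
                            min_cycles = cfg$af_criteria$min_cycles,
                            mean_frac = cfg$af_criteria$mean_frac,
                            cv_min = cfg$af_criteria$cv_min,
                            candidate_frac = cfg$af_criteria$candidate_frac)
  emit("af", "af_duration_s", rep_af$total_duration_s)
  emit("af", "af_induced", as.numeric(rep_af$induced))

  ## stage 5: sinus-node recovery
  n_paced <- 10
  paced <- seq(0, by = 100, length.out = n_paced)
  first_spont <- paced[n_paced] + cfg$af_baseline_cl + grp$snrt_excess_ms
  spont <- seq(first_spont, by = cfg$af_baseline_cl, length.out = 5)
  sn <- snrt(c(paced, spont), paced[n_paced], cfg$af_baseline_cl)
  emit("snrt", "snrt_raw", sn$snrt_raw)
  emit("snrt", "snrt_corrected", sn$snrt_corrected)

  ## stage 6: single-cell flux rates
  if (grp$calcium) {
    tcaf <- seq(0, 1.2, by = 0.002)
    caff <- data.frame(
      time = tcaf,
      value = cat_wave_fun(900, grp$caffeine_rise_s * 1000, 0.2)(tcaf * 1000))
    trec <- seq(0.5, 5 * grp$serca_tau_s, length.out = 12)
    rec <- data.frame(time = trec,
                      amplitude = 1 - exp(-trec / grp$serca_tau_s))
    fx <- flux_rates(caff, rec)
    emit("flux", "ryr2_rate", fx$ryr2_rate)
    emit("flux", "serca_rate_inv", fx$serca_rate_inv)
  }

  do.call(rbind, rows)
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes, per configured group: fixed-rate dual-channel mapping
#' (duration/rise/velocity/heterogeneity metrics), an alternans
#' cycle-length sweep (magnitude and discordance), an S1S2 stage
#' (capture, AERP, AERP/APD, S2/S1 calcium restitution with
#' monoexponential fit), fibrillation-episode simulation and detection,
#' sinus-node recovery, and single-cell RyR2/SERCA rate constants. Fully
#' deterministic given `config$seed`; failures in one group are isolated
#' (reported as a warning, other groups unaffected).
#'
#' @param config A [pipeline_config()] or a YAML path.
#' @return A `run_report`: `metrics` (long data.frame: group, stage,
#'   metric, cycle_length, value) and `provenance` (config hash, seed,
#'   package version).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  metrics <- list()
  for (gi in seq_along(config$groups)) {
    gname <- names(config$groups)[gi]
    res <- tryCatch(
      analyze_group(config, config$groups[[gi]], gname,
                    gseed = config$seed * 1000L + gi * 17L),
      error = function(e) {
        warning("group `", gname, "` failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(res)) metrics[[length(metrics) + 1L]] <- res
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  structure(list(
    metrics = metrics,
    provenance = list(config_hash = rlang::hash(unclass(config)),
                      seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("atriamap")))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$provenance$seed, " config",
      substr(x$provenance$config_hash, 1, 8), "\n")
  print(utils::head(x$metrics, 20))
  if (nrow(x$metrics) > 20) cat("...", nrow(x$metrics), "rows\n")
  invisible(x)
}

#' Extract one metric from a run report
#'
#' @param report A [run_pipeline()] result.
#' @param metric Metric name.
#' @param group Optional group filter.
#' @return data.frame subset.
#' @export
report_metric <- function(report, metric, group = NULL) {
  m <- report$metrics
  m <- m[m$metric == metric, , drop = FALSE]
  if (!is.null(group)) m <- m[m$group == group, , drop = FALSE]
  m
}
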