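# Concentration-response (Hill/4PL), Boltzmann gating and I-V summary
# fits for patch-clamp summary tables.

#' Fit a four-parameter logistic concentration-inhibition curve
#'
#' Fits `I(c) = bottom + (top - bottom) / (1 + (IC50 / c)^h)` by least
#' squares on log-concentration (the IC50 is parameterized as its
#' logarithm), with `bottom` and `top` fixed by default at 0 and 100
#' percent — sparse designs (four concentrations) cannot support four free
#' parameters. A multi-start grid over IC50 (the concentration quantiles
#' and the geometric mean) and the Hill slope avoids local minima.
#' Confidence intervals come from a seeded residual-resampling bootstrap
#' (residuals inflated by the degrees-of-freedom factor, normal-theory
#' interval on the log-IC50 scale).
#'
#' @param conc Positive concentrations (any unit; the fitted IC50 scales
#'   with the unit).
#' @param inhibition Percent inhibition at each concentration.
#' @param fix_bottom,fix_top Plateau constraints; set to `NULL` to free a
#'   plateau (requires enough data).
#' @param n_boot Bootstrap replicates for the CI (0 to skip).
#' @param boot_seed Seed for the bootstrap resampling.
#' @param conf_level CI coverage.
#' @return List of class `hill_fit`: `ic50`, `hill`, `top`, `bottom`,
#'   `fitted`, `r2`, `ci` (percentile bootstrap for `ic50` and `hill`).
#' @examples
#' d <- make_dose_response(ic50 = 10, hill = 1, concs = c(1, 3, 10, 30, 100))
#' fit_hill(d$concentration, d$response, n_boot = 0)
#' @export
fit_hill <- function(conc, inhibition, fix_bottom = 0, fix_top = 100,
                     n_boot = 1000, boot_seed = 0, conf_level = 0.95) {
  if (any(conc <= 0)) stop_invalid("concentrations must be positive")
  if (length(unique(conc)) < 3) {
    stop_invalid("need at least 3 distinct positive concentrations")
  }
  if (length(conc) != length(inhibition)) {
    stop_invalid("conc and inhibition must have equal length")
  }
  free_bottom <- is.null(fix_bottom)
  free_top <- is.null(fix_top)
  n_par <- 2L + free_bottom + free_top
  if (length(conc) <= n_par) {
    stop_invalid("not enough points for ", n_par, " free parameters")
  }
  model_fn <- function(p, cc) {
    bot <- if (free_bottom) p[3L] else fix_bottom
    top <- if (free_top) p[3L + free_bottom] else fix_top
    bot + (top - bot) / (1 + exp(p[2L] * (p[1L] - log(cc))))
  }
  fit_once <- function(y, starts) {
    best <- NULL
    for (s in starts) {
      r <- try(nls.lm(par = s, fn = function(p) model_fn(p, conc) - y,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
               silent = TRUE)
      if (inherits(r, "try-error") || !is.finite(r$deviance)) next
      if (is.null(best) || r$deviance < best$deviance) best <- r
    }
    best
  }
  ic_starts <- log(unique(c(quantile(conc, c(0.25, 0.5, 0.75)),
                            exp(mean(log(conc))))))
  h_starts <- c(0.5, 1, 1.3, 2, 3)
  starts <- list()
  for (ic in ic_starts) for (h in h_starts) {
    s <- c(ic, h)
    if (free_bottom) s <- c(s, min(inhibition))
    if (free_top) s <- c(s, max(inhibition))
    starts[[length(starts) + 1L]] <- s
  }
  best <- fit_once(inhibition, starts)
  if (is.null(best)) {
    stop_invalid("Hill fit failed to converge from any start; ",
                 "check that the data span the transition")
  }
  p <- best$par
  fitted <- model_fn(p, conc)
  resid <- inhibition - fitted
  r2 <- 1 - sum(resid^2) / sum((inhibition - mean(inhibition))^2)
  ci <- NULL
  if (n_boot > 0) {
    # residual resampling with a degrees-of-freedom inflation: raw
    # residuals underestimate the error scale at sparse designs
    infl <- sqrt(length(conc) / max(length(conc) - n_par, 1))
    boots <- with_seed(boot_seed, {
      t(vapply(seq_len(n_boot), function(i) {
        yb <- fitted + infl * sample(resid, replace = TRUE)
        bb <- fit_once(yb, list(p))
        if (is.null(bb)) c(NA_real_, NA_real_)
        else c(bb$par[1L], bb$par[2L])  # log IC50, hill
      }, numeric(2)))
    })
    # normal-theory bootstrap interval, on the log scale for the IC50
    # (a positive, right-skewed parameter)
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- list(
      ic50 = exp(p[1L] + c(-1, 1) * zq * sd(boots[, 1], na.rm = TRUE)),
      hill = p[2L] + c(-1, 1) * zq * sd(boots[, 2], na.rm = TRUE))
  }
  structure(list(
    ic50 = exp(p[1L]), hill = p[2L],
    bottom = if (free_bottom) p[3L] else fix_bottom,
    top = if (free_top) p[3L + free_bottom] else fix_top,
    conc = conc, inhibition = inhibition, fitted = fitted,
    r2 = r2, ci = ci, n_boot = n_boot
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit> IC50 =", signif(x$ic50, 5), " hill =",
      signif(x$hill, 4), " R2 =", signif(x$r2, 4), "\n")
  if (!is.null(x$ci)) {
    cat("  IC50 CI: [", signif(x$ci$ic50[1], 5), ",",
        signif(x$ci$ic50[2], 5), "] (", x$n_boot, "bootstraps )\n")
  }
  invisible(x)
}

#' Fit a Boltzmann steady-state gating curve
#'
#' Activation: `G/Gmax(V) = 1 / (1 + exp((V0.5 - V) / k))` (monotone
#' increasing in V); inactivation flips the sign of the argument (monotone
#' decreasing). Slope factor `k` is reported positive; the direction
#' carries the sign convention. Fits whose data do not span the 0.2-0.8
#' portion of the transition are flagged extrapolated.
#'
#' @param voltages Test potentials, mV (at least 5).
#' @param response Normalized conductance/availability in `[0, 1]`-ish.
#' @param direction `"activation"` or `"inactivation"`.
#' @return List of class `gating_fit`: `v_half` (mV), `k` (mV),
#'   `direction`, `r2`, `extrapolated`.
#' @export
fit_boltzmann <- function(voltages, response,
                          direction = c("activation", "inactivation")) {
  direction <- match.arg(direction)
  if (length(voltages) < 5) stop_invalid("need at least 5 voltages")
  if (sd(response) < 1e-9) {
    stop_invalid("response has no transition (constant)")
  }
  sgn <- if (direction == "activation") 1 else -1
  v0 <- voltages[which.min(abs(response - 0.5))]
  k0 <- diff(range(voltages)) / 6
  best <- NULL
  for (ks in c(k0 / 2, k0, 2 * k0)) {
    fit <- try(nlsLM(response ~ 1 / (1 + exp(sgn * (vh - voltages) / k)),
                     start = list(vh = v0, k = ks),
                     control = minpack.lm::nls.lm.control(maxiter = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop_invalid("Boltzmann fit failed to converge")
  cf <- coef(best$fit)
  r2 <- 1 - best$rss / sum((response - mean(response))^2)
  extrap <- !(min(response) <= 0.2 && max(response) >= 0.8)
  structure(list(v_half = cf[["vh"]], k = abs(cf[["k"]]),
                 direction = direction, r2 = r2, extrapolated = extrap,
                 voltages = voltages, response = response,
                 fitted = as.numeric(predict(best$fit))),
            class = "gating_fit")
}

#' @export
print.gating_fit <- function(x, ...) {
  cat("<gating_fit>", x$direction, ": V1/2 =", signif(x$v_half, 5),
      "mV  k =", signif(x$k, 4), "mV  R2 =", signif(x$r2, 4),
      if (x$extrapolated) " [extrapolated]" else "", "\n")
  invisible(x)
}

#' Summarize a current-voltage (I-V) relation
#'
#' With inward currents negative: the peak potential is the argmin of the
#' current density, refined by a quadratic through the neighbouring test
#' potentials; the reversal potential is the linearly interpolated zero
#' crossing above the peak (reported as a bound when the densities never
#' cross zero); the activation threshold is the first test potential at
#' which the density reaches 5% of the peak density.
#'
#' @param voltages Strictly increasing test potentials, mV (at least 5).
#' @param density Current densities, pA/pF (inward negative).
#' @return List of class `iv_summary`: `peak_potential`,
#'   `reversal_potential` (or `reversal_bound`), `activation_threshold`,
#'   `peak_density`.
#' @export
iv_summary <- function(voltages, density) {
  if (length(voltages) < 5) stop_invalid("need at least 5 potentials")
  if (any(diff(voltages) <= 0)) {
    stop_invalid("potentials must be strictly increasing")
  }
  i <- which.min(density)
  pk <- voltages[i]
  if (i > 1 && i < length(voltages)) {
    # quadratic vertex through the three points around the minimum
    x <- voltages[(i - 1):(i + 1)]; y <- density[(i - 1):(i + 1)]
    qf <- lm(y ~ x + I(x^2))
    a <- coef(qf)[[3]]; b <- coef(qf)[[2]]
    if (is.finite(a) && a > 0) pk <- -b / (2 * a)
  }
  rev_pot <- NA_real_; rev_bound <- NULL
  above <- seq_along(voltages) > i
  cross <- which(density[above][-sum(above)] < 0 &
                 density[above][-1] >= 0)
  if (length(cross)) {
    j <- which(above)[cross[1]]
    rev_pot <- voltages[j] + (0 - density[j]) /
      (density[j + 1] - density[j]) * (voltages[j + 1] - voltages[j])
  } else {
    rev_bound <- paste0("> ", max(voltages), " mV")
  }
  thr_idx <- which(density <= 0.05 * min(density))
  thr <- if (length(thr_idx)) voltages[min(thr_idx)] else NA_real_
  structure(list(peak_potential = pk, reversal_potential = rev_pot,
                 reversal_bound = rev_bound, activation_threshold = thr,
                 peak_density = min(density)),
            class = "iv_summary")
}

#' @export
print.iv_summary <- function(x, ...) {
  cat("<iv_summary> peak:", signif(x$peak_potential, 4), "mV  reversal:",
      if (is.na(x$reversal_potential)) x$reversal_bound
      else paste(signif(x$reversal_potential, 4), "mV"),
      " threshold:", signif(x$activation_threshold, 4), "mV\n")
  invisible(x)
}

#' Printed concentration-inhibition reference tables
#'
#' Mean percent inhibition of the L-type calcium current at each tested
#' concentration for the two study compounds (the aqueous herbal extract,
#' in mg/mL, and its active saponin dioscin, in umol/L), shipped as small
#' CSV tables in `inst/extdata/`.
#'
#' @param compound `"wk"` or `"dioscin"`.
#' @return data.frame with columns `concentration` and `response`.
#' @export
ical_inhibition_table <- function(compound = c("wk", "dioscin")) {
  compound <- match.arg(compound)
  f <- system.file("extdata",
                   paste0(compound, "_ical_inhibition.csv"),
                   package = "atriamap", mustWork = TRUE)
  read.csv(f, comment.char = "#")
}
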