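---
title: "Models, conventions and validation in atriamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and validation in atriamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriamap)
```

`atriamap` quantifies action-potential (AP) and calcium-transient (CaT)
dynamics from dual-channel cardiac optical-mapping movies and fits
patch-clamp summary curves. Because the quantities it reports — APD90,
rise time, conduction velocity, alternans magnitude, spatial discordance,
refractory periods — are all *operational* (defined by a measurement
convention rather than by physics), the package is built around a
synthetic tissue generator whose output carries exact per-pixel, per-beat
ground truth. Every estimator is validated against construction. This
vignette records the models, the conventions chosen where the field
leaves them open, the numerical choices, and what the validation does and
does not establish.

## The synthetic tissue generator

### Waveform families

The AP beat is piecewise smooth: a half-cosine upstroke of duration
$r$ (`rise_time`) followed by a cosine shoulder of span $D$,

$$V(t) = \tfrac12\bigl(1-\cos(\pi t/r)\bigr)\ (0\le t\le r), \qquad
V(t) = \tfrac12\bigl(1+\cos(\pi (t-r)/D)\bigr)\ (r< t\le r+D).$$

The maximal upstroke velocity sits exactly at $t=r/2$ (the activation
instant), and $D$ is solved so that the 90%-repolarization crossing falls
exactly `apd90` later. The operational definition of APD90 — time from
dF/dt max to 90% recovery — is therefore exact by construction, without
solving ionic models (an explicit non-goal: no Hodgkin–Huxley or
FitzHugh-type membranes, no reentry simulation).

The CaT beat uses the same upstroke, a plateau, and a strictly
monoexponential decay with time constant `decay_tau` (seconds — the
conventional unit for Tau, while all durations are milliseconds; the
printed magnitudes of the two differ by three orders). The plateau length
is solved from `cat90`; if `cat90` is shorter than
$r/2 + \tau\ln 10$ the 90% recovery point is unreachable and the
constructor refuses the parameters.

### Beat-to-beat dynamics

Per-beat APDs follow the standard restitution iterated map

$$\mathrm{APD}_{n+1} = \mathrm{APD_{max}}\bigl(1 -
  e^{-\mathrm{DI}_n/\tau_{rest}}\bigr),\qquad
  \mathrm{DI}_n = \max(\mathrm{CL}-\mathrm{APD}_n,\ 5\ \mathrm{ms}).$$

The 5 ms diastolic-interval floor keeps the map total at the aggressive
cycle lengths the protocols reach (down to tens of ms). The fixed point
is stable when $|f'(\mathrm{DI}^*)|<1$ and bifurcates into a period-2
(alternans) orbit when $|f'|>1$; `restitution_slope()` exposes this
criterion and the test suite verifies that simulated alternans onset
coincides with it.

The tissue is partitioned into regions (canonically four quadrants), each
with its own restitution parameters and an *alternans phase offset* of 0
or 1 beat. Spatial discordance is therefore imposed by construction — an
offset region plays the opposite phase of the same period-2 orbit —
rather than emerging from conduction-velocity restitution. This is a
deliberate design choice: imposed discordance gives exact truth labels
for the discordance index, which an emergent mechanism could not.

CaT amplitudes of drive-train beats either follow the APD orbit
(amplitude ratio = orbit ratio) or an explicitly imposed alternans
fraction; premature (S2) beats are scaled by
$1 - e^{-\Delta/\tau_{refr}}$ where $\Delta$ is the S1S2 coupling
interval — the closed form against which the S2/S1 analysis is checked.
Stimuli below the tissue's refractory period `aerp_ms` elicit no beat and
are flagged non-captured in the truth.

### Acquisition model and its limits

Movies default to 900 Hz sampling and 0.1 mm pixel pitch (both
configurable). Excitation spreads as a target wave at a uniform velocity
from the pacing site; repolarization is truncated at 85% of the interval
to the next beat (as in real tissue, where the next wavefront interrupts
it), and the truth maps record the truncated values. Noise is additive
i.i.d. Gaussian per pixel-frame — the simplest model consistent with
shot-noise-dominated fluorescence at this scale.

The generator deliberately omits: motion artifacts (experiments uncouple
contraction pharmacologically), photobleaching drift, spatially
correlated noise, dye-specific kinetics, curvature of the 3-D atrial
surface, and any emergent reentry. Passing the validation suite therefore
shows the estimators are correct *given the assumed signal model*; it
does not certify performance on real movies with these additional
artifacts.

## Analysis conventions

* **Activation time** — maximal first derivative of the beat window,
  refined by parabolic interpolation of the discrete derivative
  (sub-frame precision at 900 Hz). Ties (perfectly linear ramps) resolve
  to the earliest frame and are flagged.
* **Durations** — time from activation to the linearly interpolated
  downward crossing of the fractional recovery level. The crossing level
  is referenced to the diastolic baseline estimated from pre-upstroke
  frames selected by *slope* (|diff| ≤ 15% of the maximal derivative);
  a value-based reference (the window minimum) is biased low by about
  two noise standard deviations and would shift every duration. With
  this convention, map means stay within 2% of truth at noise σ = 0.05.
* **Rise time** — the 10–90% upstroke interval (the common
  optical-mapping convention; onset-to-peak is also computed and attached
  as an attribute, since the field sometimes reports it instead). For
  the half-cosine upstroke family the 10–90% interval is
  $[\arccos(-0.8)-\arccos(0.8)]/\pi \approx 0.59$ of the full upstroke —
  the calibration constant used in the tests.
* **Tau** — log-linear least squares on the 0.7 → 0.1 decay segment,
  refined by nonlinear least squares of $Ae^{-t/\tau}$. A fit is flagged
  unreliable when R² < 0.9 **or** when a straight line explains the
  segment at least as well as the exponential (a pure linear decay passes
  the R² rule alone, so the model comparison is what actually catches
  it).
* **Conduction velocity** — local second-order polynomial surface fit of
  activation time over 5×5 neighbourhoods (Bayly-style); velocity is the
  inverse gradient of the fitted surface. Noiseless plane waves at
  0.3–1.0 mm/ms are recovered within 5%; under activation-time noise the
  speed is biased *down* (noise inflates $|\nabla T|$), visible in the
  README example. Velocities are reported in mm/ms; the published
  whole-atrium values this emulates carry no printed unit, and mm/ms is
  the assumption documented here.
* **Heterogeneity** — IQR with the type-7 (linear interpolation)
  quantile convention, stated explicitly because IQR is a headline
  metric and quantile conventions differ across software.

## Alternans

The time-domain magnitude follows the published formula exactly: beats
split into odd/even groups, magnitude
$= 1 - \overline{\text{small}}/\overline{\text{big}}$. Even/odd grouping
(rather than local pairing) is robust to residual drift after
detrending. Phase is +1 when the odd-indexed beats (parity anchored to
the shared stimulus train, so phases are comparable across pixels) are
the long/high group; for unpaced data phase is meaningful only up to a
global sign.

Spectral detection evaluates the periodogram at 0.5 cycles/beat. The
linear trend is estimated *jointly* with the alternating component and
only the trend is removed, so detrending leaks no power into or out of
the alternans bin. The noise reference band is 0.33–0.48 cycles/beat (the
spectral-method convention, excluding the alternans bin), widened down to
0.2 cycles/beat when fewer than four periodogram bins fall inside (short
desk-scale series). Two statistics are reported:

* the conventional power k-score
  $(P_{0.5} - \mu_{band})/\sigma_{band}$, for comparability;
* the amplitude signal-to-noise ratio $z = \sqrt{P_{0.5}/\mu_{band}}$,
  which drives the significance flag at the default threshold 3.

The calibration reason: periodogram bins have exponential tails and the
band SD is estimated from few bins, so the *power* k-score at 3
false-alarms at several percent even for 128-beat series — far from the
sub-1% a normal-theory reading suggests. At the alternans frequency the
spectral coefficient is real, so $z$ behaves like the absolute value of a
Student statistic with roughly twice as many degrees of freedom as noise
bins; at the conventional 128-beat sequence length its measured null
false-positive rate at $z \ge 3$ is about 0.5%. Shorter series inflate
it (about 1.5% at 16 beats); movie analyses at 10–14 beats rely on the
alternans being strong, not on marginal significance.

The discordance index $2\min(N_+,N_-)/(N_++N_-)$ maps concordant tissue
to 0 and balanced opposition to 1; the published work reports discordance
qualitatively, so the formula is the package's own, chosen for its [0,1]
range. It is defined only over significant pixels — with very few
significant (noise-flagged) pixels it is reported but unstable, which is
visible in quiescent-tissue runs.

## Protocol analysis

* **Beat amplitude** is the window peak minus the pre-peak minimum, so a
  window containing only the decaying tail of the previous transient
  (a non-captured premature stimulus) measures near zero rather than the
  tail height.
* **S2/S1 ratio** — the S1 reference is the mean amplitude of the last
  three drive beats (steady state); ratios are produced per pixel (maps),
  at four configurable sites (3×3 means), and as the field mean. The
  restitution fit $A(1-e^{-(\Delta-\Delta_0)/\tau_r})$ includes a latency
  offset $\Delta_0$ because ratios are undefined below the refractory
  period; steepness is the maximal fitted derivative × 100 (percent per
  ms). Parameters are box-bounded (A ≤ 2, τ within 20× the tested range)
  to keep degenerate curves from wandering; flat curves are flagged
  unidentifiable.
* **Capture / AERP** — a stimulus is captured when ≥ 50% of masked
  pixels show a propagated upstroke of ≥ 50% of their steady amplitude
  (the published protocols leave capture undefined). AERP is the longest
  failing interval; out-of-range outcomes are reported as bounds. The
  estimate error is bounded by the S2 step by construction.
* **SNRT** — both the raw delay (last stimulus to first spontaneous
  beat) and the corrected value (minus one baseline cycle) are reported,
  because the published 10–70 ms values suggest a corrected measure but
  the definition is not stated.
* **AT/AF episodes** — a run of ≥ 5 consecutive cycles each below 75% of
  baseline, with run mean below 60% of baseline and coefficient of
  variation above 0.1. All four thresholds are config-exposed: the
  criterion is algorithmic, not physiological, and the published work
  gives no operational definition. At the generator's episode parameters
  (mean cycle 40% of baseline, 15% jitter) sensitivity exceeds 95% with
  a false-episode rate below 5% over seeded runs.
* **Flux rates** — RyR2 release rate is the maximal first derivative of
  a cubic polynomial fitted to the caffeine-transient upstroke
  (normalized amplitude/s); SERCA recovery is the time constant of
  $A(1-e^{-t/\tau})$ fitted to the amplitude-recovery series, with the
  cubic-derivative estimate attached as a diagnostic. The published
  methods say only "fitted by a polynomial"; the cubic order and the
  rate definitions are the package's documented choices, validated by
  synthetic recovery only.

## Pharmacology

Concentration–inhibition tables are fitted with the four-parameter
logistic on log-concentration with bottom and top fixed at 0 and 100 by
default — four-point designs cannot support four free parameters
(releasable by argument). A multi-start grid (IC50 at the concentration
quartiles and geometric mean; Hill slope 0.5–3) guards against local
minima. Confidence intervals use a seeded residual-resampling bootstrap
with residuals inflated by $\sqrt{n/(n-p)}$ and a normal-theory interval
on the log-IC50 scale; with sparse designs percentile intervals
undercover noticeably, and even this construction is validated only to a
loose ≥ ~90% coverage at nominal 95%.

Boltzmann gating fits use $1/(1+e^{(V_{1/2}-V)/k})$ with the sign flipped
for inactivation; data not spanning the 0.2–0.8 portion of the transition
are flagged extrapolated. I–V summaries take the peak potential from a
quadratic refinement around the density minimum, the reversal potential
from the zero crossing above the peak, and the activation threshold as
the first potential reaching 5% of the peak density.

The IC50 values reproducible from the published mean-inhibition tables
are whatever the least-squares fit yields; for one of the two shipped
tables the printed means are internally inconsistent with the printed
IC50 (inhibition is already above half-maximal below the printed IC50),
which is expected when a published value averages per-cell fits rather
than fitting the printed means. The package reports the computed value.

## The pipeline and problem sizes

`run_pipeline()` chains, per configured group: fixed-rate dual-channel
mapping, an alternans cycle-length sweep, an S1S2 stage (capture, AERP,
AERP/APD, calcium-release restitution), fibrillation-episode simulation
and detection, sinus-node recovery, and single-cell flux rates. It is
deterministic given the master seed (each stage derives its own stream),
records a configuration hash and package version in the report, and
isolates per-group failures. Configurations round-trip through YAML with
schema validation before any computation.

Default problem sizes — 10–16 pixel grids, 5–14 beats per run, six or
seven S2 intervals, two or three cycle lengths in the sweep — are chosen
so a full two-group run completes in seconds on one CPU while every
stage still exercises the same code paths as larger maps; all are
configuration fields, and nothing in the methods depends on the grid
being small.

## Known limitations

* Validation is against the generator's signal model; real recordings
  add motion, bleaching, correlated noise and geometry not modelled
  here.
* Discordance is imposed, not emergent; the package cannot say anything
  about the mechanisms that create discordance in tissue.
* Heavy beat overlap at the fastest cycle lengths (CaT decay longer than
  the cycle) degrades amplitude-based measures; the alternans sweep
  interprets magnitudes there as trends, not absolute values.
* The spectral significance call is calibrated for ≥ ~48-beat series;
  10-beat movie series carry a few-percent false-positive rate at the
  default threshold.
* Single-run SNRT and flux-rate stages consume constructed traces; they
  validate definitions, not biology.
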