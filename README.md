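# atriamap

Optical-mapping and patch-clamp analysis of atrial electrophysiology, with
a ground-truth-labelled synthetic tissue generator for end-to-end
validation.

## The problem

Atrial-fibrillation phenotyping in small-animal hearts rests on a chain of
image-analysis steps applied to dual-channel fluorescence movies
(transmembrane voltage and intracellular calcium, typically acquired at
0.9 kHz): per-pixel action-potential and calcium-transient features, maps
of conduction and repolarization, beat-to-beat alternans and its spatial
organization, and pacing-protocol readouts such as the effective
refractory period and calcium-release restitution. Each step involves
conventions (where "activation" is, what "rise time" means, how alternans
significance is called) that are rarely testable on animal data because no
ground truth exists. `atriamap` implements the full chain as a tested R
package and pairs it with a generator that emits movies whose per-pixel,
per-beat truth is known exactly, so every estimator can be validated
against construction rather than convention.

## What is implemented

**Wave metrics.** Activation time is the instant of maximal upstroke
velocity (dF/dt max, parabolic sub-frame refinement); APD30/80/90 and
CaT durations are times from activation to the linearly interpolated
crossing of the fractional recovery level; rise time is the 10–90%
upstroke interval; the CaT decay constant Tau comes from a monoexponential
fit of the 0.7 → 0.1 decay segment. Conduction velocity uses a local
second-order polynomial (Bayly-style) surface fit of activation time over
5×5-pixel neighbourhoods, `v = 1 / |∇T|` in mm/ms. Spatial heterogeneity
is the type-7 interquartile range of a feature map.

**Alternans.** Time-domain magnitude is `1 − mean(small)/mean(big)` over
odd/even beat groups; spectral detection evaluates the periodogram at
0.5 cycles/beat against a 0.33–0.48 cycles/beat noise band; phase is +1
for long–short (high–low) sequences and −1 for the opposite; spatial
discordance is `2·min(N₊, N₋)/(N₊+N₋)` over significant pixels.

**Protocols.** S2/S1 calcium-transient ratios against the S1S2 coupling
interval (calcium-release restitution, fitted by
`A·(1 − exp(−(Δ−Δ₀)/τ_r))`), AERP from capture outcomes, sinus-node
recovery time (raw and corrected), cycle-length-based AT/AF episode
detection, and RyR2/SERCA rate constants from caffeine/tetracaine
protocols.

**Pharmacology.** Constrained four-parameter logistic
`I(c) = bottom + (top − bottom)/(1 + (IC50/c)^h)` for
concentration–inhibition tables, Boltzmann
`1/(1 + exp((V½ − V)/k))` gating fits, and I–V summaries (peak, reversal,
threshold potentials).

**Generator.** Paced 2-D target-wave propagation at a set conduction
velocity; AP/CaT waveforms built so the operational APD90/CaT90
definitions are exact by construction; beat-to-beat dynamics from the
restitution map `APD_{n+1} = APDmax·(1 − exp(−DI_n/τ))` with regional
one-beat phase offsets (imposed spatial discordance); premature-beat CaT
amplitudes scaled by `1 − exp(−Δ/τ_refr)`; fibrillation-like episodes of
rapid irregular cycles; additive Gaussian sensor noise. Every emitted
movie carries per-pixel per-beat truth labels.

## Worked example

```r
library(atriamap)

tis <- tissue_spec(grid_rows = 16, grid_cols = 16, pixel_pitch = 0.1,
                   conduction_velocity = 0.5)
sim <- simulate_movie(tis,
                      protocol_spec("fixed_rate", s1_cycle_length = 167,
                                    s1_count = 6),
                      noise_spec(sigma = 0.02, seed = 1))
mv <- spatial_gaussian3(sim$voltage)
fs <- measure_beats(mv, segment_beats(mv))
apd90 <- feature_map(fs, "d90", 3)
mean(apd90)                                   # 56.09 ms (truth 56.24 ms)
heterogeneity_iqr(apd90)                      # 1.25 ms
conduction_velocity(feature_map(fs, "activation", 3), 0.1)
#> <conduction_result> mean speed: 0.4505 mm/ms over 144 pixels; ...

wk <- ical_inhibition_table("wk")
fit_hill(wk$concentration, wk$response)
#> <hill_fit> IC50 = 24.41  hill = 2.018  R2 = 0.9952
#>   IC50 CI: [ 22.409 , 26.59 ] ( 1000 bootstraps )
```

The measured APD90 map matches the generator truth to a fraction of a
frame; the velocity estimate sits below the generated 0.5 mm/ms because
activation-time noise inflates the fitted gradient (the noiseless
estimate recovers the truth within 2%, see the test suite). The Hill fit
reproduces the half-maximal inhibitory concentration of the published
extract inhibition table.

A two-group end-to-end run (a healthy-like and a diseased-like parameter
set through simulation, preprocessing, mapping, alternans, S1S2 and
episode detection) is one call:

```r
rep <- run_pipeline(pipeline_config(seed = 7))
report_metric(rep, "apd90")
```

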