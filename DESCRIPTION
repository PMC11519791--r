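Package: atriamap
Title: Optical-Mapping and Patch-Clamp Analysis of Atrial Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-channel (transmembrane voltage and
    intracellular calcium) cardiac optical-mapping movies and patch-clamp
    summary tables, aimed at atrial-fibrillation phenotyping in small-animal
    hearts. Provides per-pixel action-potential and calcium-transient feature
    extraction (activation time, APD30/80/90, CaT durations, rise time, decay
    time constant), conduction-velocity estimation from activation maps,
    spectral and time-domain alternans detection with spatial-discordance
    quantification, pacing-protocol analysis (S1S2 calcium-release
    restitution, effective refractory period, sinus-node recovery time,
    tachyarrhythmia episode detection, RyR2/SERCA rate constants), and
    concentration-response (Hill) and gating-curve (Boltzmann) fitting. A
    fully ground-truth-labelled synthetic tissue generator emulates paced 2-D
    wavefront propagation, restitution-driven alternans with regional phase
    structure, premature-beat amplitude suppression and fibrillation-like
    episodes, so every estimator can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
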