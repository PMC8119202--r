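---
title: "Methods behind metaboflux: flux parameters, isotope tracing and morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind metaboflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboflux)
```

# Scope

`metaboflux` implements the quantitative core of a plate-based cellular
metabolism study: extracellular-flux (Seahorse-type) stress-test parameter
extraction, natural-abundance-corrected mass-isotopolog analysis of
[U-13C]-glucose tracing with PDH/PC surrogate ratios, mitochondrial
morphometry from traced outlines, and the replicate/statistics conventions
that tie plate wells to biological inference. Because such studies rarely
deposit raw instrument exports, each analysis module is paired with a seeded
synthetic-data generator whose ground truth is known exactly; the test suite
exercises every analysis path against those generators and against
independent oracles.

# Extracellular flux parameters

A well's trace is a time-ordered series of OCR (pmol O2/min) or ECAR
(mpH/min) measurements segmented into phases by the injection schedule:
each measurement is labeled "baseline" or with the most recent preceding
injection. All rates are first normalized to the well's total protein (BCA),
so parameters are per microgram.

The mitochondrial stress test (oligomycin, FCCP, rotenone/antimycin A)
decomposes respiration as

* nonmitochondrial respiration = OCR after rotenone/antimycin A,
* basal respiration = OCR before oligomycin − nonmitochondrial,
* proton leak = OCR after oligomycin − nonmitochondrial,
* ATP production = basal − leak,
* maximal respiration = maximum OCR after FCCP − nonmitochondrial,
* spare respiratory capacity = 100 × maximal / basal,
* OCR/ECAR = first OCR / first ECAR measurement.

Several of these name a single "measurement after" an injection without
picking one. We adopt a consistent extremal convention: the *minimum* within
an inhibitor phase (oligomycin, rotenone/antimycin A, UK5099, etomoxir) and
the *maximum* within a stimulation phase (FCCP, glucose), and the *last*
measurement before an injection. This matches the cases where the protocol
wording is explicit (maximum after FCCP, minimum after rotenone/antimycin A,
last before glucose) and extends it to the unstated ones; the convention is
recorded in every report manifest. Phase statistics make the difference-based
parameters equivariant under uniform value scaling and invariant under time
shifts, with the two ratio parameters scale-invariant, properties the suite
verifies.

The glycolysis stress test (glucose, oligomycin, 2-deoxyglucose) yields
nonglycolytic acidification (last ECAR before glucose), glycolysis,
glycolytic capacity and reserve (capacity − glycolysis, reported signed).

The glycolytic-rate assay derives the proton efflux rate as
`PER = ECAR × buffer_factor × chamber_volume × volume_scaling` and its
glycolytic component as `glycoPER = PER − ccf × OCR`. The vendor calibration
behind published glycoPER values is not part of the assay description, so all
four constants are configurable (`per_constants()`, defaults 2.6 mmol/L/pH,
2.28 µL, 1.6, ccf 0.61); `neutral_per_constants()` (scale 1, ccf 0) makes
glycoPER coincide with ECAR so unit tests are independent of the vendor
values. Percentage PER from glycolysis (a ratio) is invariant to the buffer
scale, which the suite checks.

Undefined ratios (spare capacity with basal ≤ 0, mitoOCR/glycoPER with zero
basal glycolysis, ATP/ADP with zero net ADP) are returned as `flagged()`
sentinels carrying a reason, never as silent `NaN`.

# The plate simulator

`simulate_plate()` draws each measurement as
`baseline × phase multiplier × (1 + drift·t) + N(0, noise_sd)`, clipped at
zero, with protein drawn once per well. This emulates the dominant structure
of real exports — plateaued phases with injection responses and roughly
Gaussian measurement noise — and deliberately omits instrument drift
artifacts, outlier wells and well-edge effects; passing recovery tests
therefore demonstrate correctness of the arithmetic, not robustness to
machine pathology (raw-level QC is out of scope).

Presets encode study conditions. The acute LPS scenario is anchored to the
one in-text quantitative claim this pipeline can reproduce: a 1.5-fold ECAR
increase after LPS injection relative to resting controls, measured as 3
biological repeats each being the mean of 2 technical wells. Baselines (OCR
100 pmol/min, ECAR 20 mpH/min) and noise (5% of baseline) are typical ARPE-19
scales; other preset magnitudes (poly(I:C) raising OCR, IL-33 knockdown
lowering FCCP-phase maximal respiration and raising glycolysis, IL-33
overexpression raising maximal respiration) are published only as figures, so
the presets encode directions with plausible magnitudes, chosen once and not
tuned.

The per-well response statistic for an acute injection is the mean
post-injection value over the mean pre-injection value; technical wells are
averaged within each experiment before the treated/control ratio, mirroring
the replicate policy below.

# Mass-isotopolog correction and surrogate ratios

Measured isotopolog intensities mix tracer labeling with naturally occurring
13C. The correction matrix's column *j* is the mass-shift distribution of a
species with *j* tracer carbons: the convolution of Binomial(*j*,
`tracer_purity`) and Binomial(*n−j*, `p13_natural`). We deconvolve by
nonnegative least squares (`pracma::lsqnonneg`) and renormalize; NNLS rather
than direct inversion suppresses the small negative fractions inversion
produces on noisy spectra, at the cost of a bias toward zero exactly at the
boundary — acceptable because fractions are physically nonnegative. The
forward model (`apply_natural_abundance()`) uses the same kernel, making
forward-then-correct an exact round trip (verified to 1e−6 over random
MIDs). Defaults `p13_natural = 0.0107` and `tracer_purity = 0.99` are
standard values, configurable because the study's own constants are not
reported. Only carbon isotopes are corrected; H/N/O and derivatization
corrections are a documented limitation since no derivatization formulas are
available.

"Labeled vs unlabeled abundance" is implemented as the M+0-versus-rest split
of the total pool, normalized to protein. (Whether published "relative
abundance" panels are per-isotopolog or M+0-vs-rest is ambiguous; we chose
the latter and note it here.)

From [U-13C]-glucose, M+3 pyruvate entering via pyruvate dehydrogenase (PDH)
loses C1 as CO2 and yields an M+2 acetyl unit, hence M+2 citrate; entry via
pyruvate carboxylase (PC) fixes unlabeled CO2 and yields M+3 oxaloacetate,
hence M+3 citrate. The fraction ratios citrate M+2 / pyruvate M+3 and
citrate M+3 / pyruvate M+3 therefore serve as surrogates of PDH and PC
activity. Both are invariant to uniform intensity scaling of either
spectrum.

# The label-propagation simulator

`simulate_mids()` forward-simulates isotopic steady state through an
atom-mapped glycolysis/TCA network, giving the surrogate-ratio logic a
ground truth. The model:

* pyruvate is M+3 with probability `p = f_glc_labeled × (1 − pyr_dilution)`,
  else M+0; lactate mirrors pyruvate;
* the acetyl-CoA pool receives PDH flux (labeled with probability `p`)
  against unlabeled acetyl influx (β-oxidation and other fuels), so
  P(acetyl M+2) = `phi_pdh × p`;
* fresh oxaloacetate influx mixes PC-derived molecules (weight
  `(1 − u_anaplerotic) × phi_pc`, M+3 with probability `p`, CO2 refixation
  assumed unlabeled) with obligatorily unlabeled anaplerosis;
* the OAA pool is `cycling_weight` recycled malate plus `1 − cycling_weight`
  fresh influx;
* citrate is the acetyl ⊗ OAA joint state; each oxidative decarboxylation
  removes one carbon from the OAA-derived moiety, labeled with probability
  (labeled count)/(moiety size) — the exchangeable-position approximation
  that avoids full positional isotopomer bookkeeping while preserving the
  M+2/M+3 mass logic the surrogate ratios rely on;
* succinate symmetry is automatic at mass resolution; aspartate mirrors OAA;
  glutamate is an `glu_exchange` mixture with α-ketoglutarate.

The flux-fraction coupling deserves a note: routing fractions alone do not
change a per-molecule labeling probability, so for the surrogate ratios to
respond to `phi_pdh` and `phi_pc` the model must dilute each pool with the
unlabeled influx that the remaining flux share represents. Treating the
labeled share of the acetyl pool as `phi_pdh × p` and the PC share of fresh
OAA influx as `(1 − u_anaplerotic) × phi_pc` is the simplest scheme that is
biochemically interpretable, reduces to the expected corner cases (pure PDH
flux with unlabeled OAA gives citrate M+2/pyruvate M+3 = 1 and M+3 ratio 0)
and makes both surrogates monotone in their flux fraction.

The pool distribution is solved by fixed-point iteration on the OAA
labeled-carbon distribution (contraction factor `cycling_weight`; tolerance
1e−10, cap 1000 iterations; with cycling off it converges in one pass and
matches closed-form products of the configuration fractions exactly). An
independent Monte-Carlo oracle samples individual molecules by ancestry: a
Geometric(1 − cycling) number of completed TCA turns (capped at 60, beyond
which the truncated mass is < 1e−12 at the tested cycling weights), applied
forward from a fresh OAA. Solver and oracle share only the atom maps; the
suite requires agreement within 0.01 per isotopolog at 10^6 molecules over a
grid of flux splits. Defaults (`pyr_dilution` 0.1, `u_anaplerotic` 0.5,
`cycling_weight` 0.2, `glu_exchange` 0.8) are free parameters representing
unquantified unlabeled fuel contributions, chosen once as mid-range
plausible values. Kinetic (time-course) labeling and reductive carboxylation
are out of scope: the model is a 2-hour-pulse steady-state approximation.

# Morphometry

Outlines are calibrated polygons (nm). Area is the shoelace formula,
averaged over up to three repeated tracings (mirroring triplicate manual
tracing); the diameter is the Feret (maximum pairwise vertex) distance —
whether a published "diameter" means Feret or width is often unstated, so
the choice is recorded in output metadata. Manual three-class morphology
calls (fragmented / short tubular / long tubular) are made reproducible by
an elongation statistic, `e = diameter / (2√(area/π))`, with cutoffs 1.3 and
2.5 (ties go to the longer class). The cutoffs are conventions, not
published values, and are configurable and reported in every output. The
shape generator draws ellipse polygons with per-class elongation bands kept
clear of the cutoffs plus radial jitter, so generator–classifier agreement
(≥ 95% at moderate jitter) tests the geometry pipeline, not threshold
placement.

# Replicates, statistics, reporting

Technical wells are averaged to one biological value per experiment before
any test or ratio; a sole well passes through. Two groups are compared by an
unpaired two-tailed Student's t test (pooled variance by default — the
study-style reporting does not state the variance assumption; Welch is a
flag); three or more by one-way ANOVA with Dunnett's comparisons against the
control, via the equicorrelated multivariate-t distribution
(`multcomp`), whose randomized quadrature runs under a fixed local seed so
repeated calls are identical. Significance is reported at P < 0.05.
Reports are tidy CSVs plus a JSON manifest listing inputs, seeds and every
convention in force (phase statistics, PER constants, correction constants,
cutoffs, test choices), so a bundle is self-describing and byte-reproducible.

# Problem sizes used in the checks

The package's own verification runs at sizes chosen to make the statistics
sharp while remaining quick: 25 randomized noiseless traces for formula
equivalence (exact), 200 random MIDs for the correction round trip (1e−6),
a 3 × 3 flux-split grid at 10^6 molecules for solver/oracle agreement
(0.01), a 9-point PDH sweep for monotonicity, 10 000 null simulations at
n = 3/group for t-test size ([0.04, 0.06]), and 300 synthetic shapes for
classifier agreement (≥ 95%).

# Known limitations

* No raw-export QC (drift, outlier wells) and no instrument communication.
* Carbon-only isotope correction; no derivatization chemistry.
* The label network is steady-state and mass-resolved only (no positional
  isotopomers, no reductive carboxylation branch).
* Simulator realism is limited to what the tests need: Gaussian noise and
  clean plateaus; conclusions about robustness to real machine artifacts
  cannot be drawn from passing tests.
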