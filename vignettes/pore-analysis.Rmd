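---
title: "Methods: characterizing an oligomeric peptide pore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing an oligomeric peptide pore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porescribe)
```

`porescribe` implements the quantitative chain by which a pore-forming
antimicrobial peptide is characterized: from peptide identity (mass
spectrometry, hydrophobicity) through single-channel electrophysiology
(stepwise insertions, I/V, selectivity) to the physical picture of the pore
(size, β-barrel geometry, permeant exclusion, oligomer stoichiometry). This
vignette documents the models, their assumptions, the parameters that
matter, and the choices made where the design was genuinely open.

## Peptide mass and charge-state deconvolution

A peptide's monoisotopic mass is the sum of its residue masses plus one
water for the chain termini; each intrachain disulfide removes two hydrogen
atoms (2 × 1.0078250319 Da), one per cysteine thiol. For the mature
52-residue peptide with its Cys25–Cys50 disulfide this gives 5839.08 Da,
reported as 5.8 kDa at one-decimal half-up rounding.

Electrospray deconvolution follows the standard protocol: a peak at m/z
with charge *i* implies a neutral mass M<sub>i</sub> = (m/z − m<sub>p</sub>)·*i*; the
reported mass is the arithmetic mean across charge states and the spread is
the sample standard deviation (divisor n − 1, generalized from the
four-charge-state case to any peak set). Two details are deliberate:

- **Proton mass.** The default is the rounded constant 1.007 Da used in the
  published deconvolution protocol, so worked examples reproduce digit for
  digit; `PROTON_MASS["physical"]` (1.00727646677 Da) is available when
  physical accuracy matters. At peptide scale the difference is below a
  millidalton per charge.
- **Single peaks.** With one peak the standard deviation is undefined; it is
  returned as `NA` with an explicit `sd_defined = FALSE` flag rather than 0.

`predict_charge_ladder()` is the exact algebraic inverse of
`deconvolute()`; the round trip is tested to < 10⁻⁹ Da over masses from
500 Da to 50 kDa.

## Hydrophobicity and the transmembrane helix

No universal "hydrophobic residue" classification exists. The package
default is {A, F, G, I, L, M, V, W}, which counts 34 of the 52 mature
residues (65%); the set is an explicit argument everywhere and the result
reports both the unrounded and rounded percentage. A stricter set swapping
glycine for cysteine, {A, C, F, I, L, M, V, W}, gives 61.5% on the same
sequence — the classification, not the arithmetic, carries the difference,
which is why it is never silent.

Hydropathy profiles use the Kyte–Doolittle scale with a sliding window of
odd length, default 19 residues — the classical span of a membrane-crossing
α-helix — and the transmembrane call (`max_hydrophobic_span()`) uses the
classical threshold of 1.6 on the window mean. The span is the longest
contiguous run of passing window centers expanded to full window extent;
run-length ties break toward the N-terminus. On the mature peptide the
maximal window centers inside the N-terminal half, between the two
tryptophans (positions 2 and 24) that flank the predicted helix.
Amphipathicity is quantified by the Eisenberg hydrophobic moment
µ_H = |Σ h_k e^{ikδ}|/N at δ = 100° (helix) or 180° (strand).

## Synthetic recordings: what is emulated, and what is not

The generators produce every input the pipeline consumes, with ground
truth. `simulate_trace()` emulates a voltage-clamped planar-bilayer
recording during pore insertion:

- **Insertions are a homogeneous Poisson process** and each pore is
  *persistent* — once inserted its conductance never gates, flickers, or
  closes. This mirrors the stable, stepwise-increasing total conductance
  that distinguishes discrete oligomeric pores from transient
  membrane-perturbing peptides.
- **Single-pore conductances are lognormal**, median 10.8 nS, log-sd 0.5 —
  a broad right-tailed distribution matching the observed conductance
  histogram's character; the distribution family is a package choice, as no
  parametric form is implied by the data.
- **Noise is white Gaussian** (default sd 20 pA). Recording-chain 1/f
  noise, capacitance transients, and gating kinetics are *not* modeled, so
  passing tests show the detector handles the idealized insertion process,
  not every artifact of real amplifiers.
- Defaults (5 kHz sampling, 60 s, +50 mV, insertion rate 1/3 s⁻¹ ≈ 20
  events per trace) keep the step signal-to-noise ratio ΔI/σ ≥ 5, the
  regime in which the detector's acceptance properties are defined: the
  smallest plausible amplitude (≈2.4 nS at 3 log-sd below the median) still
  yields ΔI ≈ 120 pA ≈ 6σ.

`simulate_iv()` produces Ohmic points I = G(V − Ψ_rev) + noise;
`simulate_spectrum()` jitters an exact charge ladder;
`simulate_metrics_table()` draws a unimodal (Gaussian-profile) confidence
curve over stoichiometry, clipped to [0, 1]. All generators are pure
functions of (parameters, seed) and bit-reproducible.

## Filtering and step detection

Recordings are conditioned with an order-8 digital Bessel low-pass filter
at 1 kHz. The `signal` package supplies Butterworth/Chebyshev designs but
no Bessel, so the analog prototype is built in-package from the reverse
Bessel polynomial (coefficients (2n−k)!/(2^{n−k} k!(n−k)!)), renormalized
so the −3 dB point sits exactly at the requested cutoff (found by
`uniroot` on the prototype magnitude), and discretized by the bilinear
transform with cutoff pre-warping. The filter runs forward once — so the
single-pass magnitude response is preserved, and filtering twice squares
the transfer function as it should — and the output is shifted back by the
analytically known low-frequency group delay, keeping step edges aligned
to within a couple of samples. A Bessel response is the right choice here
precisely because its near-constant group delay does not ring on steps.
The hardware anti-aliasing filter of the acquisition chain is assumed
already applied upstream and is not re-modeled.

Step detection uses a transparent two-window moving-mean difference: at
each sample, mean(next *w*) − mean(previous *w*) is compared with a
threshold, contiguous passing samples collapse to the local maximum of the
statistic, candidates closer than a dead time (default 20 ms) merge keeping
the larger, and amplitudes are re-estimated from flanking plateau means
offset by a small guard (default 5 samples) to avoid the filter-smeared
edge. Defaults: *w* = 10 ms of samples; threshold = 6 × a robust noise
estimate (MAD of first differences / √2, insensitive to the steps
themselves); insertions only (upward steps), matching persistent pores.
Commercial acquisition software performs this step interactively; this
detector is deliberately simple enough to state and test — recall and
precision ≥ 0.95 against simulated ground truth at SNR ≥ 5 (±2 ms matching
window), under one false positive per minute on pure noise at the default
threshold, and conservation of Σ ΔG against the final plateau conductance
to well under 5% averaged over recordings.

Event statistics use half-open lower-inclusive bins [kw, (k+1)w) and a
lower-interpolation median (for even n, the lower middle order statistic),
so the reported median is always an observed amplitude. The bilayer seal
check regresses mean baseline current on test voltage; its default
threshold retains a printed figure of 0.01 pS verbatim, flagged in the
documentation as far below conventional seal criteria (0.01 nS would be
typical) — it is a configuration value, never a hard constant.

## Reversal potential and ion selectivity

Each conductance level's I/V points are fit by ordinary least squares; the
slope is the level conductance (pA/mV = nS) and the reversal potential is
the voltage-axis intercept −a/G — the voltage at which net current
vanishes, which is what a reversal potential *is*. With 7 voltages spanning
±50 mV and 5% current noise, Ψ_rev is recovered with mean absolute error
below 1 mV over 100 simulations.

Selectivity under a KCl gradient uses the bi-ionic GHK voltage equation

Ψ_rev = (RT/F) ln[(P_K[K]_trans + P_Cl[Cl]_cis) / (P_K[K]_cis + P_Cl[Cl]_trans)],

cis relative to trans. It is strictly increasing in P_K/P_Cl, spans the
open interval between the two Nernst potentials (±40.66 mV at 150/730 mM,
298.15 K), and `permeability_ratio_from_reversal()` inverts it exactly
(x = e^{Ψ F/RT}; P_K/P_Cl = (x·trans − cis)/(trans − x·cis) for a 1:1
salt). Choices: nominal concentrations, no activity coefficients (the
measurements report molarities; an activity option would multiply both
sides similarly at these ionic strengths); temperature default 298.15 K;
gradient default 150 mM cis / 730 mM trans, following the figure-level
statement of the salt conditions over an ambiguous prose variant ("750 mM"
could read as to-750 or +750 — both are expressible through
`salt_condition()`). A pore is classified non-selective when
|Ψ_rev| ≤ 2 mV, an explicit tolerance standing in for "no measurable
selectivity"; zero is unmeasurable, a tolerance is testable.

## Pore geometry

The canonical conductance model for a short, wide pore is a conducting
cylinder in series with the access resistance of the two solution
hemispheres (Hille): G = σ[l/(πr²) + 1/(2r)]⁻¹. Units collapse neatly:
1 S/m = 1 nS/nm. Defaults: l = 5 nm (a typical bilayer span; the true pore
length is not measured) and σ = 1.66 S/m (150 mM KCl at 25 °C); both are
arguments. The inverse is the positive root of a quadratic and is exact.
Two consistency results matter:

- at r = 5 nm, l ∈ [4, 6] nm, σ ∈ [1.5, 1.8] S/m the model predicts
  G ∈ [8.5, 11.9] nS, bracketing the observed 10.8 nS median — a
  consistency check, not a fit;
- inverting G = 10.8 nS at the defaults gives r ≈ 5.2 nm (diameter
  ≈ 10.5 nm), consistent with the ~5 nm pore radius of the structural
  models and with the permeation of macromolecules of Stokes–Einstein
  radius 4.7 nm (margin 0.3 nm) and 3.9 nm.

β-barrel geometry places the backbone of an n_s-stranded barrel on a
regular polygon of side d: circumradius d/(2 sin(π/n_s)), widened by
1/cos(α) for strand tilt α. Defaults d = 4.8 Å (interstrand hydrogen-bond
spacing), α = 0, and a 0.25 nm side-chain wall allowance between backbone
circle and aqueous lumen; a 21-protomer barrel of two-stranded hairpins
(42 strands) has backbone radius 3.21 nm. These formulas are geometric
idealizations — the predicted structures come from a neural predictor, not
from this polygon — which is why every parameter is exposed and the two
routes (conductance-derived and geometry-derived size) are treated as
independent consistency checks rather than one pipeline.

Stokes–Einstein conversions r = k_BT/(6πηD) use water viscosity
8.9 × 10⁻⁴ Pa·s at 298.15 K by default. The permeation predicate is bare
size exclusion (permeant iff r̄_ES ≤ r_pore); partitioning and
hindered-diffusion corrections are out of scope.

## Ranking oligomer models

The package consumes multimer-prediction metric tables — stoichiometry n,
ipTM, pTM, mean pLDDT — and never runs the predictor (GPU-scale, external,
and not the quantity of interest here). The confidence score is the
standard weighted average 0.8·ipTM + 0.2·pTM; ranking is by descending
score with ties broken toward the *lower* stoichiometry (parsimony — the
tie rule is this package's choice). pLDDT bands follow the conventional
cutpoints with the "confident" band as the open interval (70, 90), strict
at both ends, so pLDDT = 70 is moderate and 90 is very-high.

`two_round_selection()` reproduces the broad-scan-then-template logic: a
first-round scan (e.g. n = 2–25) selects a best stoichiometry, a second
template-seeded round (e.g. n = 18–30) rescans around it, the final model
is the round-2 best, and an improvement flag records whether the best score
rose. The validator reports — but does not resolve — declared-range
mismatches, since scan-range inconsistencies are a documentation problem,
not an arithmetic one.

With noiseless synthetic tables the ranking recovers every peak
stoichiometry from 10 to 30 exactly. Under score noise of 0.02, exact
recovery is only attainable when the confidence peak is sharp relative to
the noise (≥ 90% at profile width 1.5); for wide peaks (width 4) adjacent
stoichiometries differ by less than the noise and the honest property is
recovery to within one protomer (≥ 90%), which the tests assert in exactly
those terms.

## Leakage normalization

Liposome dye-leakage fluorescence is affine-rescaled between the
buffer-only (0%) and detergent-lysis (100%) anchors. The normalization is
invariant under any common gain/offset and monotone in the sample reading.
Values outside [0, 100] — quenching, scatter — are returned unchanged with
an `in_range = FALSE` flag rather than clipped: an artifact the user can
see is better than one silently truncated.

## Numerical and testing choices

- All randomness flows through explicit integer seeds; generators are
  bit-reproducible.
- The test suite regenerates every fixture in code; Monte-Carlo checks use
  modest sizes (20 × 60 s traces for detector recovery, 100 seeds for
  reversal recovery, 1000 ladders for the deconvolution round trip) chosen
  as the package's own balance of statistical power against suite runtime.
- Degenerate inputs fail loudly and specifically: unknown residue codes
  report the offending position, non-numeric cells report row and column,
  single-peak deconvolutions and empty event sets flag undefined
  statistics, reversal potentials at or beyond the Nernst limits are
  rejected as unbounded ratios.

## Known limitations

- The step detector targets persistent insertions; gating, flicker,
  sub-conductance states, and dwell-time analysis are out of scope.
- GHK inference is restricted to the K⁺/Cl⁻ bi-ionic case; multi-ion
  mixtures, surface-potential corrections, and voltage-dependent
  permeation are not modeled.
- The cylinder and polygon models are deliberately minimal; they support
  consistency arguments about pore scale, not atomistic lumen profiles.
- Synthetic traces omit 1/f noise, drift, and capacitance transients; real
  recordings may need pre-processing the package does not provide.
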