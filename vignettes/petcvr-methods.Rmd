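---
title: "Models and design of petcvr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of petcvr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petcvr)
```

# Scope

`petcvr` implements the full comparison chain between transcranial
Doppler (TCD) CO₂-reactivity and quantitative oxygen-15 PET haemodynamics
in symptomatic internal carotid artery occlusion: synthetic cohort
generation, tracer-kinetic quantification of CBF/OEF/CBV, reactivity
computation and categorisation, haemodynamic staging, and
method-agreement statistics. Everything runs from seeded simulation, so
each stage is testable without patient data.

# Kinetic models

## Water study (CBF)

Tissue activity after a [¹⁵O]H₂O bolus follows the one-tissue Kety model
for a freely diffusible tracer,

$$C(t) = f \left(C_a \otimes e^{-(f/\lambda)t}\right),$$

where $f$ is perfusion (internally mL blood · s⁻¹ · mL tissue⁻¹, reported
as mL/min/100 mL), $\lambda$ the blood–tissue partition coefficient of
water (mL/mL) and $C_a$ the arterial input. The model assumes flow-limited
exchange (extraction ≈ 1 for water), a well-mixed tissue compartment, and
an input curve free of residual dispersion beyond what the AIF model
carries. Scans are frame-averaged; the fit minimises duration-weighted
squared residuals over $(f, \lambda, \text{arrival delay})$ with
Levenberg–Marquardt (`minpack.lm`), bounded to $f \in [0.1, 200]$,
$\lambda \in [0.5, 1.2]$, delay $\in [-10, 10]$ s. Whether the partition
coefficient should be fitted or fixed is genuinely open (quantification
protocols differ); the default fits it, and `fitLambda = FALSE` fixes it,
because a fitted $\lambda$ absorbs modest tissue heterogeneity at no cost
in identifiability on 25-frame schedules.

## Oxygen study (OEF)

The [¹⁵O]O₂ model is Mintun-type with three components — extracted
oxygen, recirculating metabolic water, and intravascular tracer:

$$C(t) = E f (C_{a,O_2} \otimes e^{-(f/\lambda)t})
       + f (C_{a,w} \otimes e^{-(f/\lambda)t})
       + V_b R_{Hct} C_{a,O_2}(t)\,(1 - 0.835\,E).$$

$E$ is the oxygen extraction fraction, $C_{a,w}$ the recirculating-water
input (constrained to lag the O₂ curve), $V_b$ the blood-volume fraction
and $0.835$ the standard vascular correction for oxygen still bound in
vessels. With $f$ (water study) and $V_b$ (CO study) fixed, the model is
linear in $E$ and solved in closed form by weighted least squares.
Estimates outside $[0, 1.5]$ are flagged rather than truncated.

## Carbon monoxide study (CBV)

CO binds to haemoglobin, so tissue signal is purely vascular and the
equilibrium equation applies per frame:
$\mathrm{CBV} = 100\, C_{tissue} / (R_{Hct} C_{blood})$ with the
small-to-large-vessel haematocrit ratio $R_{Hct} = 0.85$. The 3 × 120 s
frames are all treated as equilibrium frames (duration-weighted).

These three model forms, the 0.835 vascular factor and $R_{Hct} = 0.85$
are the package's documented defaults; they are the standard quantitative
oxygen-15 formulations and every constant is an exposed argument.

## Arterial input functions

AIFs are peak-normalised gamma-variates
$C_a(t) = A u^{\alpha} e^{\alpha(1-u)}$, $u = (t-d)/t_p$, optionally
convolved with an exponential dispersion kernel (time constant $\tau$).
The gamma-variate is a modelling choice — measured inputs from an online
sampler are simply curves — chosen because it is non-negative, zero
before onset, and analytically integrable
($\int C_a = A e^{\alpha} t_p \Gamma(\alpha+1)/\alpha^{\alpha+1}$), which
gives the tests a closed-form oracle. Dispersion preserves that area.

# Numerical choices

* Forward models are evaluated on a uniform 0.05 s grid; convolutions use
  an FFT (zero-padded to a power of two) with a trapezoid endpoint
  correction, making the quadrature second-order accurate. Against an
  independent direct-quadrature oracle the frame values agree to well
  under 0.1 %.
* Frame averages come from linear interpolation of the cumulative
  trapezoid integral; frame boundaries normally sit exactly on the grid.
* Dispersion is applied by the exact exponential-update recursion of the
  first-order kernel on a ≤ 0.02 s grid (implemented with a recursive
  filter), then interpolated.
* Decay handling: synthetic activities are decay-corrected by
  construction; `applyDecay()`/`correctDecay()` apply the exact
  frame-averaged ¹⁵O factor (half-life 122.24 s) and are exact inverses,
  so the correction path is testable.
* Degenerate inputs fail loudly: all-zero tissue curves, zero blood
  activity, non-positive baseline velocity, and non-converged fits return
  flagged results or errors, never silent zeros.
* Mann–Whitney U uses the exact distribution when the pooled sample is
  tie-free and the mid-rank normal approximation otherwise; Spearman uses
  mid-ranks. Two-sided tests throughout, no multiplicity correction.

# The synthetic cohort

The generator draws, per patient, a symptomatic side, an ipsilateral true
stage (default prevalence 9/24, 13/24, 2/24), and per-hemisphere true
values anchored on the printed normal limits being control mean ± 1.96 SD:

* stage 0: CBF ~ N(40, 4.5), CBV ~ N(3.2, 0.35), OEF ~ N(45, 5), all
  truncated into the normal box (CBF ≥ 31.1, CBV ≤ 3.9, OEF ≤ 55.7);
* stage 1: CBF shifted below 31.1 and/or CBV above 3.9 — the subtype mix
  (low CBF, high CBV, both) is configurable with default weights
  (10, 3, 2), exposed as configuration because the printed subtype
  counts do not have a single obvious reading;
* stage 2: OEF ~ N(62, 4) truncated above 55.7, with low-normal CBF and
  raised CBV.

Contralateral hemispheres are near-normal; a configurable fraction
(default 9/24, matching the prevalence of contralateral carotid stenosis)
is drawn mildly abnormal, and their stage label is derived from the drawn
values so labels are always rule-consistent.

True reactivity is stage-dependent: stage-0 hemispheres draw from the
normal-control distribution N(36, 8) — whose mean minus two SD equals the
20 % impairment cut-off — while stage 1 and 2 draw from N(10, 7) and
N(0, 6), overlapping distributions chosen to match the group summaries of
impaired and absent/steal patients. TCD recordings are 50-sample 5-s
envelopes per phase whose means hit baseline velocity and
baseline × (1 + r/100) exactly; measurement noise (default SD 3
percentage points) enters through the measured reactivity, so noiseless
runs recover truth to machine precision. End-tidal CO₂ rises by
N(12, 6) mmHg under carbogene; blood pressures start near 158/86 mmHg
with small stimulus-related changes.

PET frame noise is Gaussian per frame with SD = scale ·
√(mean/duration) (default scale 0.5, giving a few percent at peak frame
values), mimicking count statistics without sinogram simulation; a
Poisson-like variant with the same scaling is available. Infarcted tissue
is represented by a scalar masked fraction per region — manual infarct
delineation is not reproducible, so the mask is an input contract, and
the voxelwise mode (`fitParametricMaps()`) takes an explicit infarct mask
and flags fully-masked regions as unavailable.

What the generator does **not** emulate: scanner resolution and
partial-volume effects, attenuation/scatter, intra-scan motion, real AIF
measurement error, day-to-day physiological drift between the TCD and PET
sessions, and — importantly — genuinely independent disagreement between
modalities: simulated TCD truth is conditioned on the same underlying
stage that PET measures, so cohort-level agreement is typically higher
than in real patients, where the two methods probe different physiology.
Passing tests therefore demonstrate correctness of the computational
chain, not clinical concordance levels.

# Staging and agreement rules

Stage 2 is defined solely by OEF and takes precedence over CBF/CBV
findings (a hemisphere with low CBF and high OEF is stage 2). Values
exactly at a limit are normal for that parameter (the limits are written
with inclusive ≥/≤). `classifyStage()` is checked against an
independently coded brute-force rule table on a dense grid including the
boundary neighbourhoods, and is monotone: lowering CBF or raising OEF
never lowers the stage.

Binary TCD impairment is reactivity ≤ 20 % (absent and steal included);
binary PET compromise is stage ≥ 1. Cohen's kappa is an added summary
beyond the raw agreement count and is reported as undefined when a margin
has no variation. Group contrasts default to the declared variable→test
map (t for CBF, CBF ratio, CBV/CBF and its ratio; U for OEF and its
ratio); correlations default to Pearson for the CBF and CBV/CBF
hemispheric ratios and Spearman for the OEF ratio. Outlier exclusion for
the secondary correlation run is always a caller-supplied patient list,
never auto-detected, and excluding nobody reproduces the primary run
bit-for-bit.

# Problem sizes used by the test suite

The suite exercises determinism and schema round-trips on 2–4 patient
cohorts, prevalence recovery on a 2,000-patient truth-only cohort,
reactivity-distribution calibration on 3,000 patients, kinetic round
trips on the grid CBF ∈ {20, …, 70} mL/min/100 mL and OEF ∈
{0.3, …, 0.7}, noise calibration with 200 replicate fits at the default
noise scale plus 50 replicates at each of three scales, and full
pipeline runs on 3–8 patients. These sizes were chosen to give stable
statistics for each property while keeping a complete run around a
minute.

# Known limitations

* The oxygen model fixes flow and blood volume at their estimated values;
  their estimation error propagates into OEF without being reflected in
  its reported spread.
* Delay is fitted per region but dispersion is taken from AIF metadata;
  residual dispersion mismatch biases CBF slightly at very low flows.
* The generator's stage-conditional reactivity distributions are a
  deliberate simplification; realistic inter-modality discordance would
  need an independent physiological axis (e.g. collateral status), which
  is out of scope.
* Voxel phantoms are small rectangular grids; no spatial correlation or
  resolution modelling is attempted.
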