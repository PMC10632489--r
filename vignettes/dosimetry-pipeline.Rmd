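---
title: "Internal dosimetry from PET time-activity curves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal dosimetry from PET time-activity curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdosim)
```

## The problem

Before a new PET radiotracer is given to trial participants, its internal
radiation burden must be estimated from whole-body dynamic imaging of a few
healthy subjects. The chain is standard: per-organ time-activity curves
(TACs) are integrated into cumulated activities, divided by the injected
dose to give residence times, folded through an S-value matrix into
per-organ absorbed doses, and collapsed into a single risk-weighted
effective dose that is compared against regulatory limits (30 mSv per
administration, 50 mSv per year in US federal regulation). Different
software implementations of the residence-time stage differ in unstated
numerical details; this package implements the chain end to end and makes
those details explicit, configurable switches so their downstream effect
can be quantified.

## The model

**Residence times.** Dosimetry integrates decay-*uncorrected* activity:
the number of decays that actually occur in an organ. For organ $h$ with
measured activity $A_h(t)$ and injected dose $ID$,

$$\tilde A_h = \int_0^\infty A_h(t)\,dt, \qquad \tau_h = \tilde A_h / ID .$$

The observed window is integrated by the composite trapezoid rule over the
frame-midpoint samples; the unobserved tail from the last image to
infinity is $A_\text{last}/\lambda$ under pure physical decay of F-18
($\lambda = \ln 2 / 109.77\,\text{min} = 0.3789\,\text{h}^{-1}$), or
$A_\text{last}/\lambda_\text{fit}$ with a single exponential fitted by
log-linear least squares through the last $k$ samples. Because measured
activity cannot clear more slowly than physical decay, the fitted rate is
floored at $\lambda$; a non-positive fit falls back to the physical tail
with a warning.

**Closure.** In a non-excreting system every decay happens somewhere, so
residence times over all compartments sum to $T_{1/2}/\ln 2 = 2.6394$ h.
The remainder of body is assigned by subtraction,
$\tau_\text{rem} = 2.6394 - \sum_h \tau_h$, per subject; tables of
*averaged* residence times therefore need not close, and the package
applies closure strictly before any averaging. A source-organ sum
exceeding the theoretical total is rejected as unphysical.

**Doses.** The MIRD schema gives the absorbed dose in target $k$ as
$D_k = \sum_h \tau_h\, S(k\!\leftarrow\! h)$ with
$S(k\!\leftarrow\! h) = \sum_i \phi_i \Delta_i / m_k$ — absorbed fractions,
equilibrium dose constants and target mass folded into one dose rate per
unit cumulated activity. Doses are reported as $\mu$Gy per injected MBq.
The effective dose is $E = \sum_T w_T D_T w_R$ with ICRP-103 tissue
weights by default (urinary bladder 0.04, brain 0.01, lung 0.12; the
weights sum to 1) and $w_R = 1$ for photons and positrons, which makes
$\mu$Gy and $\mu$Sv numerically identical. ICRP-60 weights are selectable.
Some published discussions informally assign 0.12 to brain or kidney;
those values conflict with ICRP 103 and are deliberately not encoded.
The remainder-of-body term is treated as a source organ named
`remainder` that must carry its own S column, mirroring what phantom dose
software does internally.

## Pipeline variants and what they probe

Residence-time implementations differ in two places the literature rarely
specifies: how the leading segment before the first frame midpoint is
handled, and how the tail is extrapolated. The package exposes both as a
preset:

* `conventional` — linear ramp from $(0, 0)$ to the first midpoint sample
  (no tracer has reached any organ at the instant of injection), physical
  decay tail;
* `pmod` — integration starts at the first frame midpoint, physical decay
  ("isotope toolbox") tail; an exponential-fit tail is the documented
  alternative.

`compare_tables()` quantifies their disagreement organ by organ:
per-subject percent differences (signed, relative to the first method by
default; a symmetric relative-to-mean convention is available) are
computed first and then averaged within sex — differencing per subject
rather than differencing averaged tables keeps the comparison paired.
Zero-valued organs yield an `NA` marker rather than an error so tables
with empty gallbladders still render.

## The synthetic-data generator

The raw study images behind whole-body dosimetry papers are generally not
deposited, so the package ships a generator whose ground truth is exact.
Each organ handles a fraction $f$ of the injected dose with one of two
closed-form decay-uncorrected shapes:

* washout: $A(t) = ID\,f\,\frac{k_u}{k_u-k_c}\,(e^{-k_c t}-e^{-k_u t})\,e^{-\lambda t}$,
  with $k_c = 0$ modelling trapping (hepatobiliary retention);
* accumulation: $A(t) = ID\,f\,(1-e^{-k_u t})\,e^{-\lambda t}$ (monotone
  bladder filling).

Both integrate analytically (`analytic_tau()`), so every pipeline stage
can be checked against truth. Two presets emulate the classic excretion
phenotypes: a hepatobiliary tracer (dominant liver/gallbladder/intestine
trapping, $\tau_\text{liver} \gg \tau_\text{lungs} > \tau_\text{brain}$)
and a renal tracer (bladder filling dominates, bladder $\gg$ liver, and a
zero-uptake gallbladder that exercises the 0.000-row paths). Noise is
multiplicative lognormal, median-preserving, with a default CV of 5% —
about the reproducibility of large-organ VOI measurements — because
activities must stay positive.

**Choice of rate constants.** The preset constants are fixed, documented
values chosen by an error-budget calculation *of the pipeline itself*,
done before any parameter was frozen. The physical-decay tail is exact
only for organs whose activity beyond the last frame declines at the
physical rate; its relative bias for a washout organ is
$e^{-(k_c+\lambda)T}\bigl[\lambda^{-1} - (k_c+\lambda)^{-1}\bigr]$ relative
to the remaining integral, which for a 2-h scan is a few tenths of a
percent either for trapping organs ($k_c = 0$, any $k_u \gtrsim 2.5$/h) or
for fast-washout organs ($k_c = 4$/h, biological half-time about 10 min,
$k_u = 8$/h), but grows to tens of percent for intermediate clearance
rates around 0.5–2/h. The presets therefore use the two well-conditioned
regimes — which also match the biology they emulate (hepatic trapping;
blood-pool clearance) — and the accuracy invariants the test suite
asserts (within 15% per organ on the sparse 5-frame schedule, within 1%
on a dense 50-frame schedule) hold with margin: measured worst cases are
about 3.8% and 0.35%. Intermediate-clearance kinetics remain available
through `organ_kinetics()` for studying exactly that tail bias, as the
tail-bound property test does.

**What the generator does not emulate:** plasma input functions,
compartmental exchange between organs, bladder voiding (content is
assumed constant, as whole-body protocols usually do), partial-volume and
motion effects, or count-rate-dependent noise. Passing tests on synthetic
subjects therefore validate the *numerics* of the chain, not the
biological fidelity of any real tracer.

## Numerical choices and degenerate inputs

* Frames are reduced to midpoints; frame-duration weighting is not
  applied because point-series integration is what the compared
  implementations do. Midpoint placement means a noiseless curve sampled
  on frames loses the sliver before the first midpoint unless the ramp is
  on; the second-order convergence check is therefore run on point
  samples that include $t = 0$, where the trapezoid error is the only
  error (observed order: error ratio 4.08 when halving the step).
* Negative activities are rejected at parse time, never clamped — a
  negative VOI value is evidence of a segmentation problem that clamping
  would hide.
* Decay-correction state is an explicit flag; converting twice in the
  same direction is an error, and the residence stage refuses corrected
  input outright rather than converting silently.
* A residence organ missing from the S-value sources is an error naming
  the pair; a *weighted tissue* missing from a dose table contributes
  zero with a warning, because partial organ coverage is the norm and the
  result is then a defensible lower bound.
* Compliance uses a strict-exceed rule: a total of exactly 30 mSv passes.
* Synthetic S tables are seeded, strictly positive, and self-dose
  dominant ($S(k\!\leftarrow\!k) \ge 10\,\max_{h\neq k}S(k\!\leftarrow\!h)$);
  their scale puts effective doses in the tens of $\mu$Sv/MBq typical of
  F-18 tracers, but no agreement with any published phantom is claimed.

## Problem sizes

The bundled study simulates 6 subjects per excretion phenotype (3 male,
3 female) on the 7-frame and 5-frame whole-body schedules with study-mean
injected activities; property suites run 100 seeded subjects per preset
and 50–100-frame dense schedules. These sizes keep every check
closed-form-verifiable while exercising all code paths.

## Worked example

```{r example}
sim <- simulate_subject("renal", schedule_mefway(), 226,
                        noise_model(cv = 0, seed = 1))
rt <- residence_table(sim$subject)
rt

S <- synthetic_svalue_table(rt$organ[rt$organ != "remainder"], seed = 1)
doses <- absorbed_doses(rt, S)
e <- suppressWarnings(effective_dose(doses))
compliance_check(e, 226)$total_mSv
```

## Known limitations

Absolute absorbed doses depend entirely on the S-value table supplied;
the package validates and applies user tables but does not bundle phantom
data. Sparse late sampling makes the tail the dominant uncertainty for
slowly clearing organs, and the physical-decay tail is then an upper
bound rather than an estimate. The comparison module is descriptive —
paired inferential statistics are out of scope. Averaged residence-time
tables do not close against 2.6394 h; only per-subject tables do.
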