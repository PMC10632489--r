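# petdosim

Image-based internal dosimetry for PET radiotracers: from per-organ
time-activity curves (TACs) to residence times, MIRD absorbed doses, ICRP
effective dose and regulatory compliance — with a paired comparison of two
residence-time pipeline variants and a synthetic-subject generator whose
ground truth is closed-form.

## Who it is for

Groups evaluating the radiation safety of F-18 (or other single-isotope)
tracers from whole-body dynamic PET on limited-field-of-view scanners:
the standard deliverable is a per-organ residence-time table fed into
phantom dose software, an effective dose in µSv/MBq, and a check against
the 30 mSv/administration and 50 mSv/year limits.

## The computation

For each source organ $h$ with decay-uncorrected activity $A_h(t)$ and
injected dose $ID$:

$$\tilde A_h = \underbrace{\int_0^{T} A_h(t)\,dt}_{\text{trapezoid over frame midpoints}}
  + \underbrace{A_h(T)/\lambda}_{\text{physical-decay tail}},
  \qquad \tau_h = \tilde A_h / ID,$$

with $\lambda = \ln 2/109.77\,\text{min}$ for F-18 and an optional
fitted-exponential tail (rate floored at $\lambda$). The remainder of body
closes the budget per subject: $\tau_\text{rem} = T_{1/2}/\ln 2 - \sum_h \tau_h
= 2.6394 - \sum_h \tau_h$ hours. Doses follow the MIRD schema
$D_k = \sum_h \tau_h\,S(k{\leftarrow}h)$ and the effective dose is
$E = \sum_T w_T D_T w_R$ with ICRP-103 weights (urinary bladder 0.04) by
default. Two pipeline presets — `conventional` (zero-anchored leading ramp)
and `pmod` (integration from the first frame midpoint) — make the usually
unstated implementation choices explicit, and `compare_tables()` reports
their per-organ percent differences, sex-stratified.

## Worked example

A noiseless renal-excretion subject (monotone bladder filling) on the
5-frame whole-body schedule, 226 MBq injected:

```r
library(petdosim)
sim <- simulate_subject("renal", schedule_mefway(), 226,
                        noise_model(cv = 0, seed = 1))
rt <- residence_table(sim$subject)   # conventional preset defaults
rt
#>             organ     tau_h
#> 1 urinary_bladder 0.9025838
#> 2           liver 0.3705124
#> 3         kidneys 0.0125898
#> 4           lungs 0.0083932
#> 5           brain 0.0052458
#> 6           heart 0.0008393
#> 7 small_intestine 0.0157952
#> 8     gallbladder 0.0000000
#> 9       remainder 1.3234511
```

The bladder dominates (0.90 h of the 2.6394 h total), the liver holds
0.37 h, and 1.32 h of decays happen in undelineated tissue — the table
sums to 2.6394 h exactly by closure. Folding through a seeded synthetic
S-value table (self-dose dominant; not a published phantom) and the
ICRP-103 weights:

```r
S <- synthetic_svalue_table(rt$organ[rt$organ != "remainder"], seed = 1)
doses <- absorbed_doses(rt, S)
e <- effective_dose(doses)          # 21.86 uSv/MBq
compliance_check(e, 226)$total_mSv  # 4.94 mSv -> passes both limits
```

So this administration delivers 4.94 mSv effective dose, well under the
30 mSv per-administration limit. Against the generator's closed-form
truth, `sim$tau_true["urinary_bladder"]` is 0.9168 h — the pipeline's
0.9026 h is 1.5% low, the sparse-schedule discretisation error.

## The analysis workflow

Numbered drivers under `analysis/` rerun the full synthetic study
(two excretion phenotypes × 6 subjects, 3 male + 3 female) and write all
tables under `results/`:

```sh
Rscript analysis/01_simulate_subjects.R   # TAC files + analytic ground truth
Rscript analysis/02_residence_times.R     # both pipeline variants, closure-checked
Rscript analysis/03_absorbed_doses.R      # doses, effective doses, compliance
Rscript analysis/04_compare_methods.R     # paired variant comparison
```

The run reproduces the qualitative finding the package is built around:
per-organ residence times can differ by 5–15% between variants while the
whole-body effective dose differs by well under 1%, because the organs
most sensitive to the integration convention carry small tissue weights.

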