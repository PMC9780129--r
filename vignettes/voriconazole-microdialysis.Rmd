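---
title: "Microdialysis pharmacokinetics of voriconazole and its N-oxide: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microdialysis pharmacokinetics of voriconazole and its N-oxide: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vorimd)
```

## The analysis problem

Voriconazole (VRC) is a triazole antifungal with notoriously variable
pharmacokinetics, driven largely by CYP2C19-mediated N-oxidation to
voriconazole N-oxide (NO). Because fungal pathogens reside in extravascular
spaces, the pharmacologically relevant exposure is in the interstitial
space fluid (ISF), which microdialysis samples directly: a perfused
semipermeable catheter collects a *diluted* reflection of the unbound
tissue concentration, because equilibrium across the membrane is never
reached. The analysis chain this package implements is:

1. **Catheter calibration.** During retrodialysis a known drug
   concentration is perfused and its loss across the membrane measured:
   \[ rD\,[\%] = 100 - 100\cdot C_{retrodialysate}/C_{retroperfusate}, \]
   assumed equal to the relative recovery (RR). ISF concentrations are then
   reconstructed from microdialysate concentrations as
   \(C_{ISF} = C_{\mu D}/rD \cdot 100\%\). The metabolite uses the parent's
   calibration as a surrogate, consistent with in-vitro feasibility data
   showing indistinguishable recoveries.
2. **Noncompartmental analysis.** Per subject, analyte, matrix and dosing
   interval: AUC to the last positive concentration by the
   linear-up/log-down trapezoidal rule, Cmax and its (earliest) time, the
   12 h trough, and classification of VRC plasma troughs against the
   therapeutic window of 1–2 µg/mL (2.86–5.73 µmol/L), not to exceed
   4.5–6 µg/mL (12.9–17.2 µmol/L).
3. **Ratio analyses.** Molar NO/VRC concentration ratios per sample, AUC
   ratios NO/VRC (extent of metabolism) and ISF/plasma (tissue
   penetration, optionally divided by the fraction unbound, fu = 0.50 for
   VRC), fold-range summaries of interindividual spread, and a
   ratio-versus-concentration trend statistic that flags saturable
   metabolism.

The raw concentrations of the motivating clinical study are not public, so
the package pairs the pipeline with a synthetic-trial simulator whose
ground truth (exact AUCs, true recoveries, true parameters) exercises every
stage, and with arithmetic cross-checks that recompute the study's printed
summary ratios from its printed AUC tables (`paper_crosscheck()`).

## Numerical choices in the NCA engine

* Rising or flat segments, and segments touching a zero concentration, use
  the arithmetic trapezoid; strictly declining positive segments use the
  logarithmic mean \((C_1-C_2)/\ln(C_1/C_2)\,\Delta t\), which integrates a
  mono-exponential decline exactly. Equal consecutive concentrations fall
  back to the linear branch (the log formula is 0/0 there).
* Integration runs from time 0 (or the first observation) to the last
  positive concentration; no extrapolation to infinity is attempted.
* Microdialysate samples integrate the ISF concentration over their
  collection interval and are placed at the interval midpoint for all
  time-based evaluations.
* Anchoring at \(t=0\): plasma profiles of the first dosing interval start
  at the observed pre-dose sample, whose below-LLOQ value is represented
  as an explicit zero (no half-LLOQ imputation anywhere); plasma profiles
  of later rich intervals start at their observed 0 h sample, which is
  stored as-is and interpreted as the interval's starting trough. ISF
  profiles have no 0 h observation, so the AUC anchor is a policy:
  `zero` for the first interval (no drug can precede the first dose) and,
  by default, `carry_back` — the first midpoint value copied back to
  \(t=0\) — for the steady-state intervals, where the 0–0.25 h segment is
  well approximated by the interval average. The policy is switchable
  (`isf_anchor`) and recorded in every report.
* The trough is the point nearest 12 h within a tolerance of 0.6 h, which
  admits the 11.5 h midpoint of the final collection interval; sparser
  profiles yield a missing-trough signal rather than a guess.
* Trough classification reads the "not to exceed" band permissively:
  `above` only beyond 17.2 µmol/L, with troughs in (12.9, 17.2] flagged
  `borderline_high`. The motivating study treated an observed trough of
  12.0 µmol/L as never exceeding the limit, implying the upper edge
  governs.
* The ratio-versus-concentration trend is a Kendall-type statistic by
  explicit pair counting (ties contribute zero; no p-value — with four
  subjects no formal testing is sensible). Concentration ratios are
  only formed where the parent is quantifiable; points with a BLQ parent
  are excluded and counted.

## Calibration policies

Replicate retrodialysate samples within an occasion are averaged before
the delivery equation by default (`average_within_occasion = TRUE`); each
catheter's calibration is then the unweighted mean over its own occasions,
so a catheter replaced mid-trial keeps only the occasions performed on it.
Records implying a delivery outside (0, 100] — retrodialysate at or above
the perfusate level — are excluded with a warning rather than failing the
run, and a configurable plausibility band (default 20–100%) flags suspect
calibrations in the report.

## What the simulator emulates

`default_trial()` reproduces the trial design the analysis assumes: four
healthy subjects, one per CYP2C19 phenotype (rapid, normal, rapid/poor and
intermediate metabolizer), dosed twice daily with 6 mg/kg 2 h i.v.
infusions on day one, 4 mg/kg 1.3 h infusions on day two and 200 mg oral
doses on days three and four; 16 plasma samples and 16 microdialysate
collection intervals in dosing intervals 1, 5 and 7; sparse sampling
elsewhere; retrodialysis at 200 µg/mL after intervals 3 and 7 with two
replicate samples per occasion; assay LLOQs of 0.005 µg/mL (plasma) and
0.004 µg/mL (microdialysate); multiplicative unit-mean lognormal assay
noise (default CV 10%, seed 42).

The kinetic model is a deliberate stand-in, the simplest structure that
reproduces the qualitative findings the pipeline must detect: a
two-compartment parent with first-order non-oxidative clearance and
saturable (Michaelis–Menten) N-oxidation of *unbound* drug, a
one-compartment metabolite, first-order oral absorption, and first-order
plasma–ISF equilibration toward a partition of the unbound concentration.
An optional auto-inhibition term (off by default) can reduce the oxidation
capacity with cumulative metabolite formation; saturation alone produces
the declining ratio-versus-concentration signature, and the study design
cannot distinguish the two mechanisms.

Default parameters (the "factory") encode the study conditions: oxidation
capacity ordered RM > NM > RM_PM > IM (128/96/69/56 µmol/h at Km = 8
µmol/L unbound), V1 = 70 L, V2 = 250 L, Q = 15 L/h, CL_other = 3 L/h,
ka = 1/h, F = 0.9, fu = 0.5 for both analytes, ISF partitions 0.95 (VRC)
and 0.50 (NO; 0.12 for the IM, echoing that phenotype's distinctly poor
metabolite penetration). Two properties shaped the less obvious choices:

* **Accumulation.** The steady-state 200 mg oral dose is less than half
  the weight-based i.v. loading dose, so interval-5 exposure can only
  exceed interval-1 exposure through carryover. The factory therefore uses
  a large steady-state volume (≈320 L, giving a terminal half-life long
  enough that the i.v. loading days still contribute on day three) plus
  saturation that deepens as concentrations accumulate.
* **Metabolite kinetics.** The metabolite compartment is fast
  (CLm = 3 L/h, Vm = 0.4 L), keeping the NO concentration in
  quasi-equilibrium with its formation rate. This makes the NO/VRC
  concentration ratio genuinely concentration-*independent* when
  metabolism is first-order, so the trend statistic collapses toward zero
  in the linear limit (`vmax_scale` large) and is clearly negative only
  under saturation — the discrimination the analysis relies on. The price
  is that the simulated metabolite peaks shortly after the parent rather
  than 8–10 h after the first dose as reported clinically: with slow
  metabolite elimination the within-interval anticorrelation between the
  ratio and the parent concentration persists even under first-order
  metabolism (we measured trend statistics near −0.8 in that regime),
  destroying the saturation diagnostic. The simulator keeps the lag
  direction (NO never peaks before VRC) but not its clinical magnitude,
  and conclusions about metabolite formation *delay* should not be read
  off synthetic trials.

Integration uses `deSolve::lsoda` at rtol 1e-10 with the integration split
at every infusion start/stop and oral dose, and carries running integrals
of every concentration so that ground-truth AUCs and interval averages are
quadrature-exact rather than re-interpolated. Simulated trials are
bit-reproducible for a fixed seed.

What the simulator does **not** emulate: assay error structure beyond
multiplicative lognormal noise, inter-occasion variability other than the
optional catheter replacement, circadian or food effects, protein-binding
nonlinearity, and metabolite renal-versus-hepatic clearance partitioning
(CLm is a lumped total). Passing the synthetic end-to-end suite therefore
demonstrates that the *pipeline arithmetic* is faithful — recoveries,
ISF reconstruction, AUC, ratios — not that the kinetic model describes
real patients.

## Problem sizes and verification

The test suite verifies, among others: exactness of the log-down rule on
exponential declines (1e-12 relative, arbitrary grids), agreement with a
10^5-point Riemann oracle on irregular profiles (1e-6), segment-split
additivity and the log-mean ≤ arithmetic-mean inequality over 1000
randomized segments, exact recovery of true catheter recoveries from
noise-free retrodialysis, the closed-form two-compartment solution as an
independent oracle for the ODE integration (1e-6), mass balance over the
full trial (1e-6), and — on the noise-free default trial — pipeline AUCs
within 2% of ground truth for all 48 rich subject × analyte × matrix ×
interval cells together with the phenotype orderings, accumulation,
penetration bands and trend properties described above. The default
synthetic trial (4 subjects, 7 dosing intervals, 84 h horizon) integrates
in a few seconds, so the whole suite runs in well under a minute of
compute-heavy work.

## Known limitations

* Two analytes (parent + one metabolite) are fixed in this version.
* No AUC extrapolation to infinity, half-life or clearance estimation —
  the analysis is deliberately restricted to within-interval exposure.
* No formal statistical inference: with one subject per phenotype the
  outputs are descriptive (folds, medians, trend signs), as in the
  motivating study.
* The printed-value cross-checks validate the ratio arithmetic against the
  published tables; they cannot validate concentration-level processing of
  the original trial, whose raw data are unavailable.
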