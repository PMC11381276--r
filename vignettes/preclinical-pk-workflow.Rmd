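---
title: "Methods: preclinical PK characterization and PBPK prediction for Deg-AZM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preclinical PK characterization and PBPK prediction for Deg-AZM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degpk)
```

`degpk` implements the complete preclinical pharmacokinetic
characterization of deglycosylated azithromycin (Deg-AZM), a
small-molecule transgelin agonist developed for slow transit
constipation, as a tested analysis pipeline: non-compartmental analysis
(NCA) of plasma concentration–time data in rats and dogs, equilibrium
dialysis protein binding, microsomal metabolic stability with in
vitro–in vivo extrapolation (IVIVE), excretion mass balance, tissue
distribution ratios, and a minimal whole-body physiologically based
pharmacokinetic (PBPK) model used to check the rat data and predict
human single-ascending-dose exposure. This vignette documents the
models, the parameter choices, and the numerical conventions; it is
the package's record of the decisions that were genuinely open.

## Units and data model

Units are fixed pipeline-wide: time in hours in vivo and minutes in
vitro, concentrations in ng/mL, doses in mg/kg (absolute mg only for
the human dose-escalation scenarios). A profile
(`conc_profile()`) is one subject × matrix series with a dosing event;
the CSV schema (`read_profiles()`/`write_profiles()`) has a mandatory
header, comma separation, decimal points, and a deterministic column
order, so a write–read round trip is exact. Sex is kept explicit on
every profile and never pooled silently; the only sex-pooled quantities
in the pipeline are the PBPK validation inputs, where pooling is a
deliberate, documented choice (below).

Below-LLOQ handling follows the common NCA convention the study report
leaves unstated: pre-peak BLQ values count as zero, post-peak BLQ
samples are dropped from terminal fitting and from the AUC beyond the
last quantifiable point.

## Non-compartmental analysis

`auc_trapezoid()` defaults to the linear-up/log-down rule, the standard
default of commercial NCA software; plain linear trapezoids are
selectable by flag, and at the dense study sampling schedules the two
agree well inside the precision of any quantity anchored to the
reported tables. The first moment (AUMC) uses the exact moment integral
of the interpolant on each segment.

`fit_lambda_z()` regresses ln C on t by ordinary least squares over
candidate terminal windows of at least three quantifiable points,
maximizing adjusted R²; ties prefer more points. The Cmax point is
excluded from candidate windows for extravascular profiles and allowed
for iv boluses. For an iv bolus whose first record is a pre-dose zero,
C0 is back-extrapolated log-linearly from the first two quantifiable
points.

Derived parameters follow the usual definitions: AUC∞ = AUClast +
Clast/λz, CL = dose/AUC∞, Vz = CL/λz, t½ = ln 2/λz, MRT = AUMC/AUC with
oral MRT reported absorption-inclusive (the report's convention is
unstated; this is the uncorrected quantity). Oral CL and Vz are always
flagged apparent (per-F). Bioavailability uses group-mean AUCs over the
common reported windows (0–12 h rat, 0–24 h dog) rather than AUC∞: the
reported F cells reproduce from those windows, and AUC∞ is selectable.
A Welch two-sample t-test between sexes is attached to group summaries
as a plain report field only.

One reported bioavailability cell (rat, 25 mg/kg, male: 82.8%) is not
derivable from the printed mean AUCs, whose quotient gives ≈ 41.9%;
every other F cell reproduces. The reproduction report excludes that
cell and says so rather than matching it. Two further reported ratio
cells (the rat female Cmax dose-proportionality 6.76 and the dog female
AUC dose-proportionality 7.52) disagree in the last digit with the
quotients of the printed means (6.70 and 7.54); they were presumably
computed from unrounded subject-level data and are left flagged in the
report.

## Protein binding and IVIVE

Bound% = 100 (C_total − C_free)/C_total per dialysis pair; replicates
average within each nominal level (1, 4, 20 µg/mL) and the across-level
average is the unweighted mean of level means, matching the reported
layout. fup = 1 − average/100 (rat 0.61, human 0.27).

The microsomal chain is, per species,

* t½ = 0.693/ke, with ke the negated OLS slope of ln(% remaining) on
  incubation time (t = 0 included; exclusion selectable),
* CLint = (ke/C_protein) × SF, C_protein = 1 mg/mL, SF = microsomal
  protein per g liver × liver weight per kg body weight (mouse 3937.5,
  rat 1792, dog 2492.8, monkey 1462.5, human 1254.16 mg/kg),
* CLh = Q·fub·CLint/(Q + fub·CLint), the well-stirred liver with
  hepatic blood flows of 90/55.2/30.9/44/20.7 mL/min/kg,
* ER = CLh/Q,

with microsomal binding fub fixed at 1 (measured as approximately
complete) but exposed as a parameter. The chain deliberately uses the
truncated constant 0.693 rather than full-precision ln 2: the reported
table was computed with 0.693 (ln 2 would shift the rat half-life to
43.1 min at three significant figures), while the NCA module keeps
ln 2 for in vivo half-lives. Comparisons against reported cells round
to three significant figures. Metabolite profiles are semi-quantitative
peak-area normalization (proportions over detected peaks summing to
100%); positive/negative incubation controls are pass/fail QC at <1%
and 90–110% remaining respectively.

Since per-timepoint remaining percentages are not printed, `fit_ke()`
is validated on seeded synthetic decays (500 replicates at 5% CV
recover ke within 2%), and the printed ke row is the trusted input for
the chain.

## Excretion and tissue distribution

Interval amounts are concentration × collected volume (or weight), with
fecal concentrations referred to the 1:5 (g/mL) homogenate so the
back-calculation multiplies by a configurable dilution factor of 5.
Cage-pooled records carry `n_animals`. Cumulative percent-of-dose
curves are non-decreasing by construction; a total recovery above 100%
raises a warning, never silent acceptance. Tissue exposure uses the
same trapezoid engine over the sparse 0.167–8 h design with no
extrapolation (too few points for a terminal fit); kp_obs = tissue
AUC/plasma AUC, ranked descending. The reported tissue-to-plasma
multiples (e.g. stomach 12.8×) cannot be recomputed without the
unpublished tissue concentrations and are treated as reference
annotations that the synthetic tissue generator reproduces by
construction.

## PBPK model

The simulator is a minimal whole-body, perfusion-limited model: 14
tissues (lung, brain, heart, muscle, adipose, skin, bone, gut, spleen,
stomach, liver, kidney, gonads, rest) plus arterial and venous blood,
connected by blood flows, each tissue flow-limited with
dA_T/dt = Q_T(C_art − C_T·BP/Kp_T). Gut, spleen and stomach drain into
the portal inflow of the liver (the stomach wall is part of the
portal-drained viscera; the observed high stomach exposure is not
specially fitted). The liver carries the well-stirred metabolic sink
−CLint_u·fup·C_liver/Kp_liver, the kidney a renal plasma clearance
−CL_R·C_art. Oral doses sit in a gut-lumen depot absorbed first-order
(ka) into the portal stream with bioaccessible fraction fa. Cumulative
eliminations are carried as states, so conservation is checkable at
every output time; the mass-balance error stays below 10⁻⁶ relative
(in practice ~10⁻¹⁴) under the default tolerances (lsoda, rtol 10⁻⁸,
atol 10⁻¹⁰ mg, 0.01 h output grid). Simulated negative amounts beyond
10⁻⁶ of the dose abort with an integration error; smaller excursions
are clamped to zero in the returned trajectory.

Tissue:plasma partition coefficients use the Rodgers–Rowland
tissue-composition method. With a basic center of pKa 9.0, Deg-AZM is
a moderate-to-strong base: ionization at plasma pH 7.4 versus
intracellular pH 7.0, neutral lipid/phospholipid partitioning driven by
logP 1.7, and an acidic-phospholipid association constant derived from
the erythrocyte partitioning implied by the blood:plasma ratio
(default 1, not measured; hematocrit 0.46 rat / 0.45 human). The
neutral-lipid term uses logP for every tissue including adipose (a
vegetable-oil logD was not measured); for a compound of logP 1.7 the
adipose Kp is small and the simplification is immaterial. Limiting
cases are tested: a non-partitioning neutral distributes into tissue
water (plus the 30/70 lipid/water-equivalent split of neutral
phospholipid), and a pure-water tissue gives Kp = 1. The Kp set is
deterministic given (compound, species).

Organ volumes, flows, GFR and hematocrit ship in code from standard
physiological reference compilations (the study delegates them to a
commercial PBPK platform and prints none), with one deliberate
constraint: liver inflow (hepatic artery + portal) equals the hepatic
blood flow the IVIVE chain uses, 55.2 (rat) and 20.7 (human) mL/min/kg,
so the simulator and the well-stirred scaling share one hepatic flow.
Human body weight defaults to 60 kg (healthy Asian adult reference),
configurable.

### Clearances and absorption: the validation configuration

The documented default configuration for the rat validation is:

* **Hepatic**: IVIVE-scaled CLint = 0.016 mL/min/mg × SF(rat) =
  28.67 mL/min/kg, unbound via fup 0.61, fub = 1.
* **Renal**: excretion-informed, CL_R = fe_urine × observed plasma CL,
  both sex-pooled (fe 0.149, CL 3.015 L/h/kg → 7.49 mL/min/kg): parent
  drug appears in urine although the IVIVE hepatic clearance alone
  cannot account for the observed plasma clearance. Human CL_R scales
  the rat value by the GFR ratio (1.8/5.2 mL/min/kg). Sex pooling is
  used because the model is sex-agnostic and no significant sex
  differences were reported.
* **Absorption**: ka fitted by grid search to the observed oral Tmax
  (~0.33 h), giving ka on the order of 4 h⁻¹; fa calibrated once
  against the observed 25 mg/kg (mid-dose) oral AUC(0–12 h). The model
  is linear in fa, so a single noise-free simulation determines it
  (fa ≈ 0.33). `build_pbpk_model()` itself defaults to fa = 1; the
  calibration is a property of the study configuration, justified by
  the compound's low Caco-2 permeability (3 × 10⁻⁷ cm/s) and observed
  oral bioavailability of 24–57%, which are incompatible with complete
  absorption under any defensible clearance. ka and fa carry to the
  human model unchanged (no human absorption data exist).

Validation compares simulated and observed (sex-pooled printed means)
Cmax and AUC(0–12 h) at 10, 25 and 50 mg/kg oral by fold ratio against
the 0.5–2.0 band. Because the observed exposure is supra-proportional
(dose-normalized AUC rises ~1.7× from 10 to 50 mg/kg) and the model is
linear, calibrating to the mid dose necessarily leaves the low dose
over-predicted and the high dose under-predicted — by factors well
inside the band. The internals of the original commercial-platform
model are not disclosed, so this configuration is the package's own,
recorded in `rat_pbpk_model()$config`, the validation report, and the
CSV emitted by `analysis/05_pbpk_rat_validation.R`.

The human prediction simulates 5, 15, 30, 50, 80, 120 and 150 mg
single oral doses for 24 h; the model is linear, so exposure ratios
equal dose ratios exactly, consistent with the dose-dependent behaviour
reported for the compound.

## Synthetic data

Every input the pipeline consumes has a seeded generator
(`generate_profiles()`, `generate_microsomal_assay()`,
`generate_dialysis()`, `generate_excretion()`,
`generate_tissue_profiles()`), each a pure function of its arguments
including the seed. Residual error is multiplicative lognormal
(concentrations are positive; assay CVs are relative); an additive
option is deliberately omitted. Defaults mirror the study designs: the
0–12 h plasma schedule (pre-dose 0, 0.0333 h … 12 h), the
0/6/15/30/60/120 min incubation (0/3/6/9/15/30 for fast metabolizers),
three dialysis levels at 1/4/20 µg/mL × 3 replicates, and the 0–96 h
urine/feces and 0–72 h bile interval schedules. In vivo profiles use
one- or two-compartment closed forms with lognormal between-subject
variability (mean-preserving on each parameter).

What the generators emulate — and what they do not: they reproduce the
statistical structure the analysis assumes (compartmental kinetics,
multiplicative error, mono-exponential microsomal decay, dialysis
equilibria, first-order excretion). They do not emulate assay
artefacts (matrix effects, carryover, calibration drift), absorption
complexities (lag times, double peaks, enterohepatic recirculation), or
the supra-proportional exposure the real rat data show. Passing
recovery tests therefore demonstrates the estimators are correct under
their stated assumptions, not that those assumptions hold in any given
real data set.

Problem sizes in the tests are chosen to keep the full suite fast while
leaving Monte Carlo margins comfortable: 100–200 subjects for NCA
recovery, 200–500 seeds for ke recovery, 0.01–0.05 h ODE output grids.

## Known limitations

* Perfusion-limited tissues only; no permeability limitation, no
  mechanistic gut (dissolution/transit), no enterohepatic recycling,
  no virtual-population variability.
* The blood:plasma ratio was not measured and defaults to 1.
* Physiology tables are standard compilations, not the commercial
  platform's database; dog PBPK is out of scope (only the rat model
  was described and validated in the source study).
* The reported tissue-to-plasma multiples and the subject-level
  concentration data are unpublished, so those quantities are checked
  structurally (on synthetic data) rather than numerically.
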