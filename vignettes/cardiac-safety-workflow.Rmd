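---
title: "From oral dose to QT: the PBPK-to-electrophysiology workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From oral dose to QT: the PBPK-to-electrophysiology workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cardiopbpk` chains four quantitative stages to ask one question: given an
oral dose of amitriptyline (AT) — therapeutic or toxic — what happens to a
(virtual) patient's QT interval? The stages are (1) an oral-absorption
PBPK model producing plasma and heart-tissue concentrations of AT and its
demethylated metabolite nortriptyline (NT), (2) a translation of those
concentrations into free cardiac exposure, (3) pharmacodynamic links —
an Emax model for the drug's effect on heart rate, and a ventricular
cardiomyocyte model for its effect on repolarization — and (4) the
population layer: sampled between-subject variability and patient-matched
"virtual twins". This vignette explains each model, its assumptions, the
parameters that matter, and the choices made where the design was open.

## 1. The oral-absorption PBPK model

### Structure

The parent drug uses a whole-body perfusion-limited model: venous and
arterial blood pools, a lung compartment carrying the full cardiac
output, and eleven parallel tissues (including the heart and liver) each
described by a volume, a blood flow and a tissue-to-plasma partition
coefficient Kp. The metabolite uses a minimal two-compartment leg — a
central volume and one lumped "rest" tissue with a single partition
coefficient `Kp_re` — reflecting how little tissue-specific information
exists for NT disposition.

Oral input is empirical first-order absorption with a lag:

* a systemic depot receives `F x Dose` at time `t_ingestion + t_lag` and
  drains into the venous pool at rate `ka`;
* a first-pass metabolite depot receives
  `(MW_NT / MW_AT) x (1 - Fh) x (fa x Fg) x Dose` — the metabolite mass
  formed during the hepatic first pass — and drains at the same `ka`
  into the metabolite central compartment, so metabolite appearance is
  synchronized with parent absorption.

Bioavailability factors as `F = (fa x Fg) x Fh`. Because `F` already
nets out gut and hepatic first-pass losses, absorbed parent enters the
venous compartment directly. Systemically, hepatic intrinsic clearance
converts parent to metabolite (scaled by the molecular-weight ratio
263.384 / 277.4); an additional linear clearance removes parent from
venous blood, and the metabolite has its own linear clearance.

A first-order depot is a deliberate reading of the absorption rate
equation, which written literally has a constant right-hand side; the
first-order form is what "first-order kinetics" means operationally and
reduces to the same total absorbed mass. Similarly, the first-pass
formation expression is read as the *total* metabolite mass routed
through a parallel depot, preserving its mass prediction while giving
the metabolite a realistic appearance profile. Metabolite formed by
gut-wall metabolism is deliberately not added (a known reason for
underprediction of metabolite exposure).

### Parameters and units

Everything internal is mg, L and hours; concentrations are reported in
ng/mL, molar concentrations in uM (uM = (ng/mL)/MW with MW in g/mol).
The heart constants are fixed literature values: `Kp_ht` 11.77 and
`fu_ht` 0.0012 for AT; 35.63 and 0.001 for NT. The remaining disposition
parameters (tissue Kp values, clearances, metabolite leg) are shipped as
*plausible defaults*, chosen once to give the parent a lipophilic-amine
profile — systemic clearance about 45 L/h, Vss near 950 L, terminal
half-life about 15 h — and the metabolite a half-life near 35 h. They
are configuration inputs (`load_model_config()`), not claims about any
previously published parameterization. Mean absorption parameters are
`ka` 0.24 1/h, `t_lag` 1.33 h, `F` 0.459, `fa x Fg` 0.832.

### Numerics

All clearances are linear, so the full system is linear time-invariant
between dose events. Two integration paths are provided and
cross-checked: `lsoda` (stiff-safe, rtol 1e-8 / atol 1e-10) and an exact
piecewise matrix-exponential propagation via eigendecomposition
(`method = "matexp"`), which the fitting loops use because it makes one
simulation cost a fraction of a millisecond. If the rate matrix were
ever non-diagonalizable the matexp path refuses and the caller falls
back to `lsoda`; in practice the physiological rate constants are
distinct. Dose events are applied exactly (no event-localization
error), which is why concentrations before `t_lag` are identically
zero and superposition holds to machine precision.

A collapse configuration (`collapse_physiology()`) reduces the model to
one well-stirred pool, for which the single-dose solution is the
closed-form Bateman function — the analytic oracle used by the tests.
A mass-balance audit (`mass_balance()`) checks at every output time
that depot + circulating + eliminated + converted mass equals the
delivered mass, to 1e-6 relative.

## 2. Population variability and virtual twins

Between-subject variability enters through the absorption parameters:

* `F` ~ Normal(0.459, 0.093) truncated to [0.33, 0.62] (rejection
  sampling);
* `fa x Fg` ~ lognormal with arithmetic mean 0.832 and CV 0.131,
  *untruncated* — draws above 1 are physiologic (enterohepatic
  recirculation). The CV is read as the arithmetic CV and
  moment-matched (sdlog 0.13044, meanlog -0.19240); a switch
  (`cv_is_log_sigma`) exposes the alternative reading;
* `t_lag` ~ lognormal, mean 1.33 h, CV 30%. The family is not dictated
  by the source material; lognormal was chosen for guaranteed
  positivity, with a truncated-normal alternative behind a flag. One
  draw per individual is reused across all of that individual's doses.

Joint draws with `F > fa x Fg` would imply a hepatic escape fraction
above 1 — i.e. *negative* first-pass metabolite formation — and are
rejected and redrawn; the count is recorded. Physiology is held fixed
across individuals (only absorption is sampled) — a conservative
default, since which covariates beyond absorption were varied in the
original population analyses is not recoverable.

A *virtual twin* (`make_virtual_twin()`) fixes whatever a case record
states — age, sex, RR interval, plasma electrolytes, prior treatment —
and samples the rest. Missing ions default to normal physiology
(K 4.2, Na 140, Ca 2.4 mM, configurable).

## 3. Free cardiac exposure and the three case methodologies

The electrophysiological driver is the *free* drug concentration in
heart tissue. Two routes are provided:

* from observed plasma: `C_free = C_plasma x Kp_ht x fu_ht`;
* from the simulated heart-tissue total: `C_free = C_heart x fu_ht`.

The two coincide at distribution equilibrium (the simulated
heart/plasma ratio equals Kp_ht there, verified in tests to 2%); during
rapidly changing overdose kinetics the tissue route is the more
faithful one, so the simulated modes use it while observed-plasma cases
use the plasma route. Overdose case records are handled by three
methodologies mirroring what data each kind of report contains:

1. **observed_plasma** — no trustworthy dose: convert the measured
   plasma levels; if NT was not measured it is imputed as half the AT
   level.
2. **simulated_full** — dose and plasma both reported: simulate the
   twin's toxicokinetics and read the cardiac concentrations at the
   time of the simulated AT plasma maximum *within the reported ECG
   window*.
3. **simulated_dose_only** — no plasma level: simulate from the
   estimated dose alone and use the global AT plasma maximum.

If the record indicates prior chronic treatment, the toxic dose lands
on a 75 mg q.d. steady-state background.

## 4. The Emax heart-rate model

In overdose the dominant ECG change is often tachycardia — a shortening
of the RR interval — rather than QT prolongation. The package models RR
as a decreasing sigmoid of the total plasma AT concentration C (uM):

RR = RR0 - (RR0 - RRmax) * C^n / (EC50^n + C^n)

with defaults RR0 = 995.3 ms, RRmax = 500.8 ms, EC50 = 0.4 uM,
n = 1.5. Note the algebraic form: the published expression, read
literally, returns RR = 0 at C = 0, contradicting the stated meaning of
RR0 as the baseline. The decreasing-sigmoid form above — baseline at
zero drug, approach to RRmax at high concentration — is the default;
the literal form is kept behind `form = "as_printed"` and warns when
evaluated, so the interpretation is visible rather than silent.

`fit_emax()` reproduces the stochastic fitting protocol: simulated
annealing (10,000 iterations, geometric schedule as implemented by the
standard SANN annealer) followed by a bounded quasi-Newton polish, with
box bounds RR0 in [600, 1400] ms, RRmax in [200, 995] ms, EC50 in
[0.01, 10] uM, n in [0.5, 5]. On noise-free data the truth is recovered
essentially exactly; under the realistic noise level (residual SD about
121 ms) the estimator's spread is substantial, which is exactly what
the recovery experiments quantify.

## 5. The cardiomyocyte stage

The QT endpoint comes from a reimplementation of the 2006 ten Tusscher
& Panfilov human ventricular cell model (19 state variables; epicardial
parameter set by default, endo/mid available). Drug action enters as
multiplicative conductance scalers from an independent pore-block
model: `scaler = prod over analytes of 1 / (1 + (C_free/IC50)^Hill)`.
IC50/Hill values for AT and NT on the individual currents are **not
public**; the shipped `channel_blocks_synthetic.yaml` carries clearly
labelled synthetic illustrative values, and no quantitative conclusion
in the package depends on them.

Integration uses forward Euler for the membrane potential and
concentrations plus Rush-Larsen exponential updates for the twelve
gates at dt = 0.02 ms — the scheme used by the model's original
authors. The control epicardial cell paced at 1000 ms reproduces the
published APD90 (about 301 ms) within about 1%, and APD90 lengthens
monotonically as the rapid delayed-rectifier current is blocked.

Endpoints per paced run (default 30 beats, last beat analyzed):

* **APD90**, measured from the maximal-upstroke time to 90%
  repolarization;
* **QT** = APD90 + 40 ms — a *single-cell surrogate* (the offset
  stands in for the depolarization width of a real ECG complex and is
  configurable), not a claim of equivalence with a pseudo-ECG. A 1-D
  strand/pseudo-ECG mode was considered and deliberately left out: it
  is two orders of magnitude costlier and changes none of the
  package's testable claims;
* **QTc** by Bazett (`QT / sqrt(RR in s)`) or Fridericia; Bazett is
  known to overcorrect in tachycardia, so the correction method is an
  explicit argument rather than a default hidden in the pipeline;
* **arrhythmia flags**: early afterdepolarizations (sustained positive
  dV/dt, default threshold 0.05 mV/ms for at least 2 ms, during late
  repolarization) and repolarization failure (membrane above -40 mV at
  the next stimulus). In this cell model, pure IKr block prolongs APD
  but rarely triggers EADs — the model's strong L-type inactivation
  makes it EAD-resistant — so in practice the flag fires as
  repolarization failure under severe combined potassium-current
  block. The drug concentration is held constant during a paced run
  (quasi-static approximation: a pacing run spans seconds, the
  toxicokinetic time scale is hours).

`run_case()` repeats the simulation ten times (seed 1111 by default).
Because a real simulator varies the *cell* as well as the exposure,
each run draws lognormal conductance multipliers (CV 0.15, package
design choice, configurable to 0) for the six main currents; this is
why ten runs at identical exposure still spread and why occasionally
only some of the ten virtual patients flag arrhythmia.

## 6. Synthetic data: what it does and does not show

No clinical concentration data ship with the package; the
`synthetic_data` generators create every input the pipeline needs:

* `generate_trial()` / `generate_fit_problem()` — mean AT/NT profiles
  for 25/50/75 mg single doses at truth ka = 0.24, t_lag = 1.33,
  perturbed with 10% proportional noise plus a 0.5 ng/mL additive
  floor (the noise model is the package's choice; the digitization
  error of published mean profiles is unknowable);
* `generate_emax_dataset()` — 40 log-spaced concentrations from 0.01
  to 10 uM with Gaussian RR noise of SD 120.98 ms;
* `generate_case()` — overdose records with exactly the fields each
  case-group methodology requires, doses 500-3000 mg and plasma levels
  straddling the Emax EC50 (about 30-1000 ng/mL).

Passing recovery tests on these data demonstrates that the estimation
machinery is unbiased enough and the pipeline internally consistent
under the stated noise; it does *not* validate the disposition defaults
against real patients, and the synthetic data have none of the
structure that makes real data hard (assay LLOQ censoring, sparse and
irregular sampling, model misspecification).

## 7. Fitting machinery

The two-stage absorption fit follows a global-then-local protocol:

1. **CRS2-LM** — controlled random search with local mutation, written
   for this package: a population of `10 x (d + 1)` points; each
   iteration reflects a random simplex anchored at the current best
   point through its centroid, falling back to a coordinate-wise
   mutation about the best point; accepted points replace the worst
   member; 1500 iterations over `ka` in [0.1, 2], `t_lag` in [0, 2]
   from starts (1, 1).
2. **L-BFGS-B** — 50 iterations, relative tolerance 1e-20, numeric
   gradients, never leaving the box.

The internal cost is a time-weighted MSE reported as its square root
(W-RMSE). "Weighted by time" is ambiguous, so the default weight is
the trapezoid interval width `(t_{i+1} - t_{i-1})/2` — compensating
uneven sampling — with `1/t`, `t` and uniform selectable; the choice is
recorded in the result. With both analytes in one cost, residuals are
normalized by each analyte's mean observed concentration so the parent
(higher concentrations) does not drown out the metabolite.

## 8. Problem sizes and reproducibility

The recovery experiments used throughout the tests and the acceptance
script are: 20 replicate seeds for each recovery experiment; three
trials of nine sampling times, two analytes each, per absorption fit;
40 points per Emax dataset; 12-30 beats per paced-cell run; 1e4-1e6
draws for the sampling checks. Every stochastic entry point takes an
explicit seed, populations and case protocols are bit-reproducible
given the seed, and each runner writes a manifest with the seed and
configuration that produced its outputs.

## Known limitations

* Disposition defaults are plausible, not validated; metabolite
  exposure in particular inherits a single lumped `Kp_re`.
* Gut-wall metabolite formation is omitted (expected NT
  underprediction); enterohepatic recirculation is not modelled
  mechanistically, only through fa x Fg draws above 1.
* No CYP-phenotype stratification; clearances are linear even at toxic
  concentrations.
* The QT surrogate is a single-cell quantity plus a fixed offset; no
  tissue, transmural-dispersion or torso-level ECG effects.
* Real AT/NT channel potencies are not included; the block
  specification is synthetic and swappable.
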