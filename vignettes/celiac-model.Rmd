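---
title: "A kinetic model of the celiac immune response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of the celiac immune response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celiacqsp)
```

## The disease circuit

Celiac disease couples two feedback systems through the gut epithelium. In
the innate arm, gluten peptides in the lumen bind receptors on intestinal
epithelial cells (IEC); activated IEC secrete zonulin, which opens tight
junctions, and interleukin-15 (IL-15), which converts resting
intraepithelial lymphocytes (IEL) into natural killers and also arrests
their apoptosis. Natural killers and the merged IFN-γ/IL-21 cytokine pool
(written IF-21 throughout) kill mature IEC. In the adaptive arm, peptides
that cross into the lamina propria are deamidated by tissue transglutaminase
(TG-2), which lowers their EC50 for activating DQ2/DQ8 antigen-presenting
cells (APC) about five-fold; activated APC secrete more IL-15 and prime
T cells (a pooled Th1 + Th17 variable) through a transient compartment that
represents the delay of clonal expansion and B-cell affinity maturation;
activated T cells drive antibody production against gluten and TG-2, and the
antibodies in turn kill IEC and inhibit their maturation. Epithelial loss
and zonulin both increase permeability, closing the loop between the two
arms.

`celiacqsp` encodes this circuit as a mass-action/Hill reaction network over
16 state variables with 54 rate constants, integrated as
$\dot{x} = N\,v(x)$ with stoichiometric matrix $N$ and non-negative rate
vector $v$. Two structural bookkeeping choices keep the state at 16: the
TG-2–peptide complex is pooled with free deamidated peptides (both activate
APC at the deamidated EC50, so they are kinetically indistinguishable at
this resolution), while the transient T compartment is kept as its own
variable because the antibody-appearance delay measured after a
gluten challenge is load-bearing for validation.

The healthy variant of the model has no DQ2/DQ8 APC equations and zero
IEC/IEL activation rates: a healthy subject mounts no response at any
gluten intake, so every activated species, cytokine, zonulin and antibody is
exactly zero at its steady state. This is the model's definition of health,
and it pins the villous-area normalization.

## Observables and normalization

Two readouts connect the state vector to the clinic:

* **antibody level** — percent of the antibody concentration at the
  untreated steady state of a patient on a gluten-containing diet (100% by
  construction there);
* **villous area** — percent of the healthy mature-IEC level. The mature
  epithelial pool is the model's only villous-mass proxy; every published
  villous statement the model reproduces (100% healthy, 50% on a
  gluten-free diet, 10% on a gluten diet) is driven by IEC death and
  maturation, so `villous_area_pct = 100 * IEC / IEC_healthy`.

```{r conditions}
params <- cd_parameters()
cd_condition_table(params)
```

## Rate-law choices

Each rate law realizes one documented regulatory fact with as few constants
as possible:

* **IEC activation** is a steep Hill function (coefficient 4) of luminal
  gluten — a receptor-occupancy threshold. Its half-point sits far below
  the trace gluten intake of a gluten-free diet (GFD), because patients on a
  GFD still show roughly half the healthy villous area: the innate arm stays
  engaged even at the <20 ppm contamination level that defines
  "gluten-free". The gluten-free inflow is set 350-fold below the
  gluten-diet inflow (tens of milligrams versus about ten grams of gluten
  per day).
* **Transport into the lamina** is
  `(kz*Zon + ki*max(0, 1 - IEC/IEC_healthy)) * Glut_lum`: zonulin and the
  epithelial deficit act additively, and the flux vanishes for an intact,
  zonulin-free epithelium. The deficit term uses `max(0, ·)` so an
  epithelium transiently above its healthy level cannot pump peptides
  backwards.
* **APC activation** sums a native-peptide and a deamidated-peptide
  saturation term with `EC50_deam` five-fold below `EC50_nat` at baseline.
  Both EC50s sit well above the lamina peptide levels, so APC activation
  responds linearly to peptide load; deamidated peptides also turn over
  about twice as fast as native ones (uptake consumes them). This regime is
  what makes the EC50-ratio scan discriminate: at an 80-fold ratio,
  removing deamidation cuts APC activation nearly two orders of magnitude,
  while at the baseline 5-fold ratio most activation survives through the
  native route.
* **IEL activation** is a mildly cooperative Hill function of IL-15, and
  activated-IEL death is divided by `(1 + IL15/Ki)` — IL-15 both recruits
  and protects natural killers. Both the resting IEL and resting T pools
  are supply-limited, which makes the activated pools saturate at strong
  stimulation and respond steeply once the stimulus collapses; this
  supply-limited design is what lets a DQ2 blocker quench the innate arm
  indirectly while a TG-2 inhibitor barely moves it.
* **Antibody synthesis** requires activated T cells and lamina peptides
  (`ksab * aT * Pep/(K + Pep)`); production stops when either is gone, the
  model's reading of the observation that antibody levels depend directly
  and exclusively on activated T cells and lamina peptide load.
* **IF-21 degradation** is the average of IFN-γ and IL-21 turnover, the
  price of merging two cytokines with similar synthesis, decay and action
  into one variable. All degradations are first order.

Time is measured in days; concentrations are in arbitrary units fixed by
the normalization anchors (the antibody and IEC scales are pinned by the
100%/50%/10% constraints). The antibody degradation constant (half-life
about two weeks, at the fast end of IgG turnover) controls both transient
anchors: decay to background within two to three months of starting a GFD,
and reappearance within two weeks of a gluten challenge (rate-limited
upstream by the transient T-cell step).

## Parameters: sources and the re-fit

Of the 54 constants, 17 are tagged `literature` (turnover and supply rates
with well-known magnitudes: peptide, cytokine, zonulin and antibody
half-lives, epithelial renewal, cell death rates), 2 `assumed` (the IEL
activation Hill coefficient, a mild cooperativity of about 1.5; the
transient-T death rate), 4 `calculated`
(the two diet inflows from the ppm facts; the native EC50 from the 5-fold
ratio; IF-21 degradation as the IFN-γ/IL-21 average), and 31 `fitted`. The
primary study's full parameter table is not included here, so the shipped
table (`inst/extdata/parameters_synthetic.tsv`) is a synthetic reference
set: the 31 free constants were re-estimated with the package's own
Hooke-Jeeves search against the quantitative readouts the model is built to
reproduce — villous area 100/50/10%, antibody normalization and background,
the two transient time bounds, the published efficacy readouts of the five
candidate therapies, and the EC50-ratio behaviour under complete TG-2
inhibition — with mechanistic share constraints (natural killers carry a
substantial part of epithelial killing; IL-15 in the inflamed state is
predominantly APC-derived; IF-21 is predominantly NK-derived) keeping the
fit on the documented wiring. The core anchors are exposed as
`cd_constraint_dataset()`, and `fit_problem()`/`fit_model()` re-run the
same estimation machinery. The
`ci_lo`/`ci_hi` columns are ±10% plausibility boxes around those refit
values — synthetic, like the rest of the table — and exist to drive
`robustness_scan()`; with only the anchor set, formal profile intervals are
unbounded for most constants (see `confidence_intervals()` and its
`at_bound` flag), so shipping those would make the robustness scan
meaningless.

## Numerical choices

* Integration: `lsoda` (stiff-capable) at `rtol 1e-8`, `atol 1e-10`;
  states are clipped at zero inside the right-hand side, which only guards
  round-off because every rate law vanishes with its substrates.
* Steady states: damped Newton on the right-hand side with a
  finite-difference Jacobian, converged per species relative to the total
  flux through that species; on failure the solver falls back to long
  integration (up to ~11 years simulated) followed by a Newton polish. A
  steady state returned by Newton is accepted only in the non-negative
  orthant.
* The inflamed patient state is reached from a mildly activated initial
  guess (`cd_initial_state()`); the gluten-free steady state is computed by
  relaxing from the gluten-diet state, matching the clinical situation of a
  diagnosed patient changing diet.
* Complete cytokine-antibody interventions nominally send a degradation
  constant to infinity; the factor is capped at `1e4`, which drives the
  cytokine to ~1e-4 of baseline — numerically zero on every scale the model
  reports — while keeping the system integrable.
* The one-dimensional `ksab` re-fit inside `ec50_ratio_scan()` is a
  monotone root find (`uniroot` on `log ksab`), tolerance 1e-8.
* Pattern-search defaults: step 0.25 in log10-parameter space, shrink 0.5,
  terminal step 1e-4, at most 10,000 iterations; all parameters are
  searched in log space because they are positive and span decades.
* Profile-likelihood intervals use the F-based SSE threshold
  `SSE_min * (1 + qF(0.95, 1, n-p)/(n-p))` with the other parameters
  re-optimized at each profile point by a short pattern search; endpoints
  that run into the search box are reported at the bound and flagged
  non-identifiable.

## Scenarios

```{r interventions, eval = FALSE}
refs <- cd_references(params)
dose_response(params, "tg2_inhibitor", strengths = c(0, 0.5, 1),
              refs = refs)
ec50_ratio_scan(params)
```

Interventions rescale exactly one parameter family (TG-2 level, IF-21 or
IL-15 degradation, IEC activation, APC activation) with a strength in
[0, 1]; endpoints are new steady states reached from the untreated inflamed
state, normalized against the *untreated* references. The simulated
treatment duration is therefore "until stationary" — the model's reading of
a chronic therapy. Diet protocols are piecewise-constant inflows
(assumption: meals are averaged into a constant arrival rate). "Antibodies
appear" is operationalized as the normalized level crossing 10%, and "drops
nearly to zero" as falling below 5% — robust, scale-free thresholds on a
quantity normalized to 100.

The robustness scan draws parameter sets uniformly and independently within
the per-parameter confidence boxes — the simplest faithful reading of
"taking the values from the confidence intervals" — recomputes the
normalization references per draw, and summarizes endpoint quantiles;
non-convergent draws are recorded as failed rather than fatal.

## The synthetic-observation generator

`synth_observations()` simulates any set of (observable, condition) pairs at
a supplied "true" parameter table and perturbs the values with
multiplicative lognormal noise of a given CV (mean-one parameterization).
It emulates the heterogeneous in vitro / ex vivo / clinical anchor points
the real calibration drew on, in their role as fitting targets only: it
reproduces neither inter-patient variability structure, nor measurement
censoring, nor the correlation between readouts taken from the same
subject. Parameter-recovery and coverage results on these synthetic
datasets therefore validate the estimation machinery, not the biological
identifiability of the real data.

## Problem sizes used in the shipped checks

The test-suite and acceptance runs use the full 16-state patient model
throughout; transient scenarios integrate 80–250 simulated days, long-run
steady-state verification uses 2–8 simulated years, the EC50 scan covers
seven ratios spanning 1–160, robustness examples use tens of draws, and the
coverage study uses 100 replicates of a two-parameter regression toy. These
sizes were chosen so that each check exercises the full machinery at the
precision the anchors are stated to, with the whole suite completing in
minutes on a laptop.

## Known limitations

* Oral-tolerance breakdown, transcellular (vesicular) peptide transport and
  non-DQ2/DQ8 stimulation routes are structurally absent, as in the source
  network; the healthy variant is quiescent *by assumption*, not by
  bifurcation.
* Drugs are parameter changes; there is no pharmacokinetic dose-to-strength
  mapping and no combination therapy.
* TG-2 is a constant level, not a dynamic species, matching how the TG-2
  inhibitor scenario is defined (a reduction of that level).
* Zonulin acts as a single well-mixed pool; no spatial geometry.
* With the constraint anchors alone the 31 free constants are not uniquely
  identifiable; the shipped set is one calibrated representative, and
  conclusions that depend on individual constants (rather than the
  normalized observables) should be read through `confidence_intervals()`
  and `robustness_scan()`.
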