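---
title: "Statistical methods of the early-phase trial toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods of the early-phase trial toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlyphase)
```

## Scope and motivation

`earlyphase` implements the complete statistical machinery of a Phase 1/2
single-arm trial of an oral selective estrogen receptor degrader (SERD) in
ER+/HER2− advanced breast cancer: a 3+3 dose escalation gated by
¹⁸F-fluoroestradiol (FES) PET receptor occupancy, a minimax Simon two-stage
monitoring rule for the expansion cohort, exact response-rate analysis,
noncompartmental pharmacokinetics, an Emax concentration–occupancy model,
and longitudinal *ESR1*/IHC biomarker summaries. Patient-level data from
such trials are access-restricted, so the package ships a seeded synthetic
generator reproducing the statistical structure those analyses assume;
every stage of the pipeline can therefore be exercised and tested end to
end.

## Simon two-stage monitoring

A design is parameterized as $(n_1, r_1, n, r)$ in Simon's original
convention: stop for futility after stage 1 if $X_1 \le r_1$ responders are
seen among the first $n_1$ patients (a *binding* rule — it is part of the
error calculation), and reject $H_0\!: p \le p_0$ at the end if
$X_1 + X_2 \ge r + 1$ among all $n$. A protocol phrased "reject if at least
13 responders of 78" is stored as $r = 12$; `print()` displays both forms
to avoid the classic off-by-one reading.

All operating characteristics are exact, by full enumeration of the joint
binomial distribution:

$$
P(\text{reject}; p) \;=\; \sum_{x_1 = r_1 + 1}^{n_1}
\binom{n_1}{x_1} p^{x_1} (1-p)^{n_1 - x_1} \;
P\!\left(X_2 \ge r + 1 - x_1\right),
\qquad X_2 \sim \mathrm{Bin}(n - n_1, p).
$$

No normal approximation is used anywhere; the tail probabilities come from
`pbinom`, which works in log space internally, and the test suite
cross-checks the enumeration against an independent brute-force double sum
and against $10^6$ simulated trials.

```{r simon}
d <- simon_design(n1 = 45, r1 = 4, n = 78, r = 12, p0 = 0.10, p1 = 0.20)
simon_oc(d)
```

`simon_search()` scans all $(n_1, r_1, n, r)$ with $n \le n_{\max}$
(default 100). For the hypotheses above the unconstrained minimax solution
coincides with the constrained design: fixing $n_1 = 45$, $n = 78$ and
searching only the boundaries returns $(r_1, r) = (4, 12)$, and the free
search over all $n \le 80$ returns the identical design. The search
minimizes expected sample size under $p_0$ within the smallest feasible
$n$ ("minimax") or globally ("optimal").

## PET-gated 3+3 dose escalation

The dose ladder (`default_dose_ladder()`) has main once-daily levels from
10 to 600 mg plus conditional *bis* levels (50 and 150 mg QD; 200 and
300 mg BID at matched daily intensity). Cohort decisions follow the
classical 3+3 counting rule (`cohort_decision()`), and are functions of
counts only, hence invariant to patient ordering.

Bis levels are entered only through the occupancy trigger
(`bis_trigger()`): a bis level is tested when at least one patient at the
lower reference level shows ≤30 % target inhibition, or when every patient
at the upper reference level shows >85 %. In the simulator the low-
inhibition clause *jumps* the walk past the next main level to its bis
insertion (small dose increments are pointless when the current dose barely
engages the target), while the all-high clause *inserts* the intermediate
level to refine the minimal saturating dose. This generalization of the
stated DL2bis rule to the other bis levels is an extrapolation — the full
per-level decision table lives in an unavailable protocol appendix — and is
flagged as such here. It reproduces the published escalation path
(20 mg → 150 mg, skipping 50 and 100 mg, then 200, 400, 600 mg).

The MTD is the highest level with ≤1/6 evaluable DLTs; with no boundary hit
it is *not reached*. The RP2D anchor is the lowest tested level at which
**all** evaluable patients exceed the saturation threshold (default >90 %
reduction in corrected SUVmax); the nominal RP2D sits two *main-ladder*
steps above it (bis levels are conditional insertions, not backbone steps,
and are excluded from the count — users changing ladders should note this),
capped at the highest cleared level. If DLTs occurred at the nominal level
the rule drops to the highest DLT-free level that reached saturation. Two
fallback readings are possible ("any saturating dose" versus "a dose
between the anchor and the nominal level"); both are exposed via
`fallback =`, with `"any_saturating"` as default since that is the stated
protocol wording.

```{r replay}
cohorts <- data.frame(label = c("DL1", "DL2bis", "DL3", "DL4", "DL5"),
                      n_evaluable = c(3, 3, 4, 3, 3), n_dlt = 0L)
occupancy <- list(DL1 = c(5, 10, 60), DL2bis = c(92, 95, 99),
                  DL3 = c(91, 96, 100), DL4 = c(87, 100, 100),
                  DL5 = c(95, 100, 100))
replay_escalation(cohorts, occupancy)[c("mtd", "anchor", "rp2d")]
```

## Response analysis

`clopper_pearson()` is the exact beta-quantile interval; 90 % is the
default level, matching single-arm Phase 2 reporting convention. Exact
coverage at or above nominal is verified by enumeration over all $k$ for
$n \le 30$ in the test suite.

`best_overall_response()` derives BOR from timepoint responses. Decisions
made where the source conventions are not fully specified:

* Confirmation requires a second CR/PR-or-better assessment **≥28 days**
  after the first, dates compared inclusively. Unconfirmed responses
  downgrade (to SD when the stable-disease clock allows, else PD/NE).
* The minimum SD duration is **6 weeks from baseline** (the RECIST
  convention; only the 24-week clinical-benefit bar is stated in the trial
  reports). Both windows are configurable.
* Clinical benefit = confirmed CR/PR or SD maintained ≥24 weeks.
* Patients with early progression or death from progression count as PD and
  stay in denominators; non-evaluable patients also remain in ORR/CBR
  denominators, as the published tables imply.
* Report percentages are rounded half-up to one decimal **only in the
  reporting layer** (the printed tables are consistent with half-up
  rounding, though true ties are unobservable); full precision is kept
  internally.

```{r response}
summarize_population(
  response_counts(cr = 1, pr = 4, sd_ge24 = 8, sd_lt24 = 11, pd = 20,
                  ne = 2),
  population = "expansion, central review")
```

Relative dose intensity uses the trial's dosing-day denominator
`weeks × 7 − 1`, reflecting the protocol's single omitted dosing day at
treatment start.

## Noncompartmental pharmacokinetics

`nca()` computes Cmax and tmax from the observed samples (earliest time on
ties), AUC over the dosing interval by the **linear-up/log-down**
trapezoid (the industry default; pure linear is available and used in the
worked examples), the trough as the last sample in the interval, and
`CLss/F = dose / AUC` with a centralized mg / (ng·h/mL) → L/h conversion.
Below-LLOQ samples (LLOQ 5 ng/mL, the assay's validated lower bound) are
zeroed before the first quantifiable sample and excluded elsewhere; the
trapezoid variant and BLQ policy are declared package decisions, not
reported facts. Profiles with fewer than three quantifiable samples are
returned as not evaluable rather than guessed at.

Accumulation ratios and the CYP3A-induction ratio use `paired_gmr_ci()`,
the t-interval on paired log differences. Dose proportionality is the
power model (slope of log AUC on log dose, proportional when the CI
contains 1).

## Occupancy and the concentration–occupancy model

The scan statistic is the mean over index lesions of background-corrected,
body-weight-standardized SUVmax. Correction is by **subtraction** (the
source states "corrected for background" without a formula); negative
corrected uptake is clipped to zero per lesion with a warning, since
negative specific binding is non-physical. Occupancy is
$100\,(1 - \mathrm{SUV}_{cor,on}/\mathrm{SUV}_{cor,screen})$; negative
occupancy (increased uptake on treatment) is meaningful and retained.
Occupancy is scale-invariant under joint rescaling of both scans.

`fit_emax()` fits $E = E_{\max} C / (EC_{50} + C)$ by Levenberg–Marquardt
least squares (`minpack.lm`), requiring ≥4 pairs spanning more than a
decade of concentration; fits with $\mathrm{SE}(EC_{50}) > EC_{50}$ are
flagged rather than rejected. With $E_{\max} = 100$ the curve passes 90 %
at $C = 9 \cdot EC_{50}$, so the default generator $EC_{50} = 100/9 \approx
11.1$ ng/mL places 90 % occupancy at 100 ng/mL.

## Biomarker summaries

H-scores are the standard $1 p_1 + 2 p_2 + 3 p_3$ on intensity-fraction
percentages (range 0–300). Relative change from screening is undefined for
zero screening values; such records are excluded with a flag (an absolute-
change track is the appropriate analysis there). `mutation_clearance()`
declares a mutation *cleared* when it was detected at baseline and falls
below the assay detection threshold on treatment; the threshold defaults to
an allele frequency of **0.05 %**, a plausible droplet-digital-PCR limit —
the assay's true limit is not published, so this is a configurable
assumption. Mutations first emerging on treatment are reported separately
and never enter the clearance fraction, whose denominator is the
baseline-detected set (conservation: cleared + persisting = baseline
detected). `cb_variant_table()` tabulates baseline variants by subsequent
clinical benefit using mutated-patient denominators within stratum, so a
multi-variant patient contributes to several rows.

## The synthetic generator: what it emulates

`simulate_trial()` draws, per patient: stratum labels (baseline *ESR1*
status, prior CDK4/6-inhibitor exposure), individual PK parameters,
steady-state concentration profiles, occupancy, DLT flags, RECIST
assessment series, allele-frequency trajectories and paired IHC measures.
Identical seed and `families` give identical output.

Calibration targets and the choices behind them:

* **PK.** One-compartment first-order absorption with steady-state
  superposition — the minimal model reproducing a ~3 h absorption peak and
  an apparently biphasic decline; richer models are out of scope. Typical
  values: $CL/F = 10.6$ L/h (the reported steady-state clearance),
  $k_a = 0.811\,h^{-1}$ solved jointly with the volume so the typical
  single-dose tmax is 3 h, and $V/F = 120.2$ L chosen so the **population
  geometric mean** trough at 400 mg equals 466 ng/mL under the default
  between-patient variability (the typical-subject trough is slightly
  higher, 511 ng/mL — the lognormal variability shifts the geometric mean
  of the nonlinear trough downward, and the calibration absorbs that
  shift). Between-patient CVs (30 % on $k_a$, 25 % on $CL/F$ and $V/F$) are
  calibration knobs, not reported quantities; they yield a trough CV near
  80 %. A one-compartment model cannot simultaneously match the reported
  trough CV (87.3 %) and AUC CV (37.5 %) because the trough amplifies
  elimination-rate variability; the trough targets take priority here.
  Residual assay noise is 10 % lognormal; concentrations below the 5 ng/mL
  LLOQ are stored as 0 with a flag.
* **Occupancy** equals $E_{\max} C_{trough} / (EC_{50} + C_{trough})$ of
  the individual's noise-free trough *exactly*, and the paired PET scans
  are constructed so that `fes_occupancy()` recovers it exactly — a
  deliberate internal-consistency invariant used by the tests.
* **DLTs** follow a logistic model on log daily dose with default
  intercept −6 and slope 0.5: probabilities rise from ~1 % at 20 mg to
  ~6 % at 600 mg/day, consistent with an escalation in which no DLT was
  observed among 16 patients.
* **Responses** are drawn per stratum with the expansion cohort's
  category frequencies by *ESR1* status (wild-type: 1 CR, 3 PR, 10 SD of
  which 5 prolonged, 11 PD, 1 NE of 26; mutated: 0/1/9 (3 prolonged)/8/1
  of 19). The published tables do not cross *ESR1* status with prior
  CDK4/6-inhibitor exposure, so the default probabilities do not vary
  along that second axis, though the configuration accepts four distinct
  strata. Drawn categories are expanded into 8-weekly assessment series
  whose derived BOR equals the drawn category by construction.
* **Allele frequencies** start lognormal (median 0.5 %) and decline by a
  lognormal multiplicative per-cycle factor (median 0.25), censored below
  the 0.05 % detection threshold.

What the generator does **not** emulate: dropout and adherence, imaging
voxel data, lesion-level RECIST measurements (timepoint categories are
primitive), correlations between response and PK exposure, and any
within-patient time structure beyond the fixed assessment grid. Passing
tests on synthetic data therefore validate the *computational machinery* —
decision rules, estimators, exact intervals — not clinical conclusions
about real patients.

## Numerical choices and problem sizes

Enumeration replaces simulation wherever exact answers exist (Simon
boundaries, Clopper–Pearson coverage for $n \le 30$, the BOR rule set over
all short assessment series). Stochastic checks use fixed seeds: $10^6$
trials for the Simon cross-check, 1,000 replicates for GMR interval
coverage, 10,000 patients for the generator's trough and outcome-frequency
calibration — sizes at which Monte Carlo error is several times smaller
than the tolerance being asserted. Tie-breaks: earliest tmax, lowest
saturating level as RP2D anchor, first maximum in `which.max`. Degenerate
inputs (empty assessment series, zero screening uptake, $k_a = k_e$,
fewer than three quantifiable samples) return explicit flagged results or
errors, never silent numbers.

## Known limitations

The escalation trigger generalization and the RP2D fallback wording are
declared interpretations of incompletely published rules; the generator's
variability structure is a calibration, not an estimate; and the BOR
engine operates on timepoint categories, not lesion measurements, so
nadir-based progression rules are out of scope.
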