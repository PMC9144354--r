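---
title: "Validating claims-based CKD case-finding against an eGFR working standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating claims-based CKD case-finding against an eGFR working standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdvalid)
library(dplyr)
```

## The problem

Regional health administrations need prevalence estimates for chronic
kidney disease (CKD), but the disease is silent in its early stages and
its clinical definition requires *repeated* laboratory evidence:
an estimated glomerular filtration rate (eGFR) persistently below
60 mL/min/1.73 m² for at least three months. Administrative data —
hospital discharge diagnoses, co-pay exemption registrations,
outpatient specialist services, drug dispensings — are available for
entire populations at no extra collection cost, so rule-based
*case-finding algorithms* over those streams are attractive. Before
such an algorithm can be used for surveillance or research, its output
has to be validated against a laboratory reference.

`ckdvalid` implements that validation as a reusable, fully tested
pipeline:

1. an **eGFR engine** (2021 race-free CKD-EPI creatinine equation and
   G-stage bands);
2. a **cohort builder** that applies eligibility rules, selects each
   subject's index date and assigns the longitudinal *working-standard*
   label;
3. a **rule engine** reproducing the administrative classification from
   coded events in a six-year linkage window;
4. a **validation module** computing sensitivity, specificity,
   predictive values and prevalence with confidence intervals,
   stratified by sex and age class;
5. a **synthetic-records generator** with known ground truth, so the
   whole pipeline is testable without access to any real registry.

## The working standard

For each subject, all serum creatinine measurements dated inside the
accrual window (default 2012-01-01 to 2015-01-31) are converted to eGFR
and the date of the *last* in-window measurement becomes the **index
date**. A subject is eligible when

* at least two in-window measurements exist with some pair separated by
  at least the chronicity gap (90 days by default);
* completed age at the index date is at least 19 years;
* residency intervals cover the span from 5 years before to 1 year
  after the index date without interruption (abutting intervals count
  as continuous).

The working-standard label is then a three-level outcome. Writing $L$
for the eGFR at the index date (same-day duplicates resolved to the
*highest* eGFR, i.e. the lowest creatinine — a conservative,
deterministic tie-break):

* **ADVANCED_CKD** if $L < 30$ and some measurement with eGFR $< 60$ is
  dated at least 90 days *before* the index date;
* **CKD** if $L < 60$ with such an earlier measurement;
* **NO_CKD** otherwise.

Only earlier measurements can establish chronicity: the index
measurement is by construction the most recent one, so later values
cannot qualify. "Three months" is implemented as 90 days and exposed as
configuration, because calendar-month arithmetic is ambiguous at month
ends.

## The eGFR equation

`egfr_ckd_epi()` implements the 2021 race-free CKD-EPI creatinine
equation,

$$
\mathrm{eGFR} = 142 \cdot \min(S_{cr}/\kappa, 1)^{\alpha} \cdot
\max(S_{cr}/\kappa, 1)^{-1.200} \cdot 0.9938^{\mathrm{age}} \cdot
1.012\,[\text{if female}],
$$

with $\kappa = 0.7/0.9$ and $\alpha = -0.241/-0.302$ for
females/males. Three numerical choices matter:

* **No rounding before thresholding.** Stage bands compare the full
  floating-point value; rounding is a reporting concern only.
* **Half-open stage bands, closed at the lower edge**: $[60, \infty)$,
  $[45, 60)$, $[30, 45)$, $[15, 30)$, $(0, 15)$, so that 60.0 is
  non-CKD-range, consistent with "eGFR ≥ 60" as the reference band.
* **Fractional age.** Age enters as exact fractional years at the
  measurement date, avoiding birthday step artifacts in longitudinal
  series. Eligibility and age classes use completed years.

Creatinine is accepted in mg/dL only; other units are rejected rather
than silently converted. The equation is strictly decreasing in
creatinine, so it has a closed-form inverse (`creatinine_from_egfr()`),
used by the generator to turn latent eGFR trajectories into creatinine
values; forward/inverse round-trips are tested to 1e-9, and the inverse
refuses targets whose implied creatinine falls outside the
physiological range (0.05, 25) mg/dL.

## The administrative classification

Subjects are linked to coded events over a closed six-year window
around the index date (5 years before to 1 year after; both boundaries
included — the source design is silent on the boundary convention, so
it is documented and configurable through the window durations).
Matching is case-insensitive exact-prefix, because ICD-9-CM and ATC
code systems are prefix-structured hierarchies.

A subject is flagged **CKD** by any single event whose (source, code)
matches the per-source CKD lists, and **advanced CKD** by any of four
severity criteria:

* *chronic dialysis* — at least 2 dialysis-coded events spanning at
  least 90 days (the source design leaves "chronic dialysis" undefined;
  this operationalization mirrors the creatinine chronicity convention
  and both knobs are configurable);
* at least one *kidney transplant* event;
* one hospital discharge with a *stage G4+* diagnosis code;
* one dispensing of a *listed drug* (erythropoiesis-stimulating agents
  and potassium/phosphate binders: erythropoietin, darbepoetin alfa,
  methoxy polyethylene glycol-epoetin beta, polystyrene sulfonate,
  sevelamer, lanthanum carbonate, sucroferric oxyhydroxide).

Advanced always implies CKD, classification is monotone in the event
set, and the order of events never matters; all three properties are
enforced by tests against a literal brute-force enumeration of the
criteria. The shipped code lists are **synthetic placeholders** shaped
like the real hierarchies (585.x-style discharge codes, B03XA/V03AE
ATC prefixes): operational regional lists are not reproduced here, and
every synthetic cohort emits codes drawn from the active configuration,
so generator and classifier are consistent whatever lists are loaded.
Exemption-registry and specialist-service codes contribute only to the
generic CKD flag, not to the advanced criteria, which follow the four
listed channels exactly.

## Validity metrics and confidence intervals

`build_contingency()` cross-tabulates the two label sources under two
positive definitions: `ckd_60` (positive = CKD or advanced) and
`advanced_30` (positive = advanced only — on *both* axes, so
CKD-but-not-advanced counts as negative for algorithm and working
standard alike). Metrics are ratios of counts; all identities (e.g.
sensitivity × (tp+fn) = 100 × tp) hold exactly on unrounded values, and
percentages are rounded half-up to one decimal only at reporting.

Intervals are Wald by default,
$p \pm 1.96\sqrt{p(1-p)/n}$, clipped to [0, 100]; Wilson is available
behind `ci_method = "wilson"`. Wald was adopted because it reproduces
the published interval for overall sensitivity in the worked example,
(49.3, 52.6), to the printed decimal. Two quirks of the worked
example's published source are worth recording:

* its overall sensitivity is printed as 51.0% where the counts give
  1724/3384 = 50.9% unrounded; the package reports the unrounded value;
* its advanced-definition NPV prints as 99.3% where the counts give
  29334/29557 = 99.2%; the recomputed value is reported;
* its PPV interval (62.9, 66.1) is not Wald on the PPV denominator
  (tp+fp = 2673, which gives 62.7–66.3) but matches Wald computed with
  the sensitivity denominator 3384 — most plausibly a denominator slip
  in the source. The package always uses the correct denominator.

A stratum with no positives yields an `undefined`-flagged metric row
rather than a silent drop or a division error. Stratum tables are
checked to sum to the overall table before any report is returned.

## What the generator simulates

`simulate_population()` draws, per subject: sex (41% male by default),
an entry age class with the cohort's age mix, a latent eGFR trajectory
(class-specific Gaussian baseline, SD 18; linear decline with mean
1 mL/min/1.73 m²/year, SD 0.5, truncated at zero and tripled for a 10%
progressor fraction), measurement dates from a Poisson process (4/year)
over the accrual window, care settings (70% outpatient), multiplicative
lognormal creatinine noise (CV 4%, the scale of enzymatic assays),
residency intervals (2% of subjects get a disqualifying 120-day gap),
and administrative events.

Event emission is keyed to the subject's **latent** working-standard
label — the label a noise-free assay would produce, which is also
written to the truth table: a latent CKD-range subject emits a generic
qualifying event with probability `capture_prob_ckd`; a latent advanced
subject additionally emits one advanced-criterion event (transplant,
G4+ discharge, listed drug, or a chronic-dialysis pair, chosen
uniformly) with probability `capture_prob_advanced`; a latent non-CKD
subject emits a qualifying event with probability `false_flag_rate`.
Events are placed uniformly inside the subject's own six-year linkage
window, so each capture probability maps one-to-one to the probability
that the classifier flags the subject — making expected sensitivity and
specificity analytically predictable (sensitivity → capture,
specificity → 1 − false-flag).

Each subject consumes its own pseudo-random stream seeded from the
global seed plus the subject index, so any subject subset is
byte-reproducible independently of cohort size.

### The parameter-recovery experiment

The recovery experiment (capture 0.5, false-flag 0.035, n = 30,000)
is run with `creatinine_noise_cv = 0`. With exact assays the measured
working standard equals the latent truth, so the pipeline's estimated
sensitivity and specificity are exactly binomial in the capture and
false-flag probabilities and the 3-standard-error recovery bands follow
from first principles. With noise on, a small fraction of
measured-positive subjects are latent-negative and the identity holds
only approximately; turning noise off isolates the classification
channel, which is the quantity under test. `capture_prob_advanced` is
set to 0 there so advanced-criterion events cannot add extra flags on
top of the generic capture channel.

### The reference scenario and its calibration

`reference_scenario()` freezes a configuration whose *expected* cohort
marginals match a large regional validation cohort: male fraction
40.8% and working-standard CKD prevalence 11.1%. The per-class baseline
means are obtained by probit inversion. A subject is
working-standard-positive approximately when its baseline
$b \sim N(\mu_c, \sigma)$ satisfies $b < T$, with the effective
threshold

$$T = 60 + \bar d\, t_{c} - \frac{\sigma_\varepsilon}{\sqrt{\pi}} + \Delta_{MC},$$

where $\bar d = 1.2$ is the progressor-weighted mean annual decline,
$t_c \approx 2.33$ years the expected time of the latest measurement
eligible to establish chronicity, $\sigma_\varepsilon \approx 2.9$ the
eGFR-scale measurement noise SD at the threshold (the
$1/\sqrt{\pi} = \int \Phi(1-\Phi)$ term accounts for requiring *two*
sub-threshold readings), and $\Delta_{MC} = +2.1$ a Monte-Carlo
calibration constant absorbing what the closed form glosses over —
chiefly that the chronicity check is an OR over *every* earlier noisy
measurement rather than a single AND. $\Delta_{MC}$ was estimated once
from eight independent 30,000-subject generator runs (which give
prevalence 11.10% ± 0.28 and male fraction 40.80% ± 0.36) and is not a
user knob. Setting $\mu_c = T - \sigma\,\Phi^{-1}(p_c)$ at the target
per-class prevalences $p_c$ = (1.1, 4.7, 14.1, 27.7, 47.6)% yields
class means of roughly 104, 94, 82, 74 and 64 mL/min/1.73 m² — a
plausible age gradient for a hospital-laboratory population.

### What the generator does *not* emulate

* **The advanced-CKD tail is too thin.** A single-Gaussian baseline
  puts about 0.5% of the reference cohort below 30 mL/min/1.73 m² with
  chronicity, versus ~2% in real validation cohorts, where the
  low-eGFR tail is fattened by a distinct referred-nephrology
  subpopulation. A mixture baseline would fix this at the cost of two
  more coupled knobs; since the advanced stratum is exercised through
  the worked-example counts rather than the simulator, the simple
  baseline was kept.
* **No coding epidemiology.** Capture and false-flag probabilities are
  homogeneous per subject; real coding propensity varies with age, sex,
  comorbidity and calendar time — which is precisely the kind of
  structure a validation against real data would quantify. Passing
  recovery tests therefore demonstrates that the pipeline measures what
  the generator encodes, not that any particular algorithm performs
  well on real data.
* **No mortality or censoring**, and measurement timing is independent
  of disease severity (no sicker-measured-more-often feedback).

## Problem sizes and runtimes

The test suite enumerates all rule-engine and chronicity oracles on
hundreds of randomized small cases (≤ 6 measurements, ≤ 8 events),
checks marginal recovery at 4,000 subjects, truth consistency at 800,
and runs the two 30,000-subject experiments (recovery and reference
marginals) once each under fixed seeds; the whole suite completes in
about 90 seconds on one CPU. `scripts/acceptance.R` re-runs both
30,000-subject experiments from scratch at the seed given on the
command line.

## Known limitations

* The shipped code lists are placeholders; any substantive use requires
  loading the regional operational lists via `read_code_config()`.
* The working standard itself is an imperfect reference (laboratory
  measurements only reach subjects who get tested), and the package
  makes no attempt to model that selection process.
* Only the creatinine CKD-EPI 2021 equation is implemented; the engine
  carries an equation-name field so cystatin-based variants can be
  added without interface changes.
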