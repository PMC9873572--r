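---
title: "Methods: paired accuracy analysis of lateralization tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired accuracy analysis of lateralization tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lateralize)
```

## The design and its estimand

Two lateralization tests — metomidate PET-CT (MTO) and adrenal vein
sampling (AVS) — are performed in every patient. Surgery follows when
either test grades a high probability of unilateral disease, and each
test is then scored against the surgical outcome: a test is *accurate*
in a patient if it recommended surgery and surgery achieved the
endpoint, or if it did not recommend surgery and surgery did not. This
is a *partial-verification* design: negative calls can only be verified
when the other test sent the patient to surgery, and patients negative
on both tests are managed medically and assumed to be true negatives.

Two consequences shape everything downstream:

1. Concordant patients carry no information about which test is better;
   only discordant-accuracy pairs do. Power is therefore driven by the
   number of discordant pairs (`discordant_power()` computes the exact
   two-sided sign-test power over them).
2. "Sensitivity" estimated among cured operated patients is conditioned
   on the event that at least one test was positive, which biases it
   upward relative to the per-test operating characteristic; bilateral
   false positives achieving partial success pull it back down. The
   package keeps the printed-trial convention (that is the estimand the
   field reports) and the synthetic-data tests quantify when the
   conditioning is negligible (see *Parameter recovery* below).

## Grading rules

AVS: cannulation is successful when the selectivity index (adrenal to
peripheral cortisol) is at least 3 on both sides; otherwise the run is
`failed` — a failed AVS is treated as not indicating surgery everywhere
downstream. The lateralization index LI is the larger of the two ratios
of side aldosterone/cortisol ratios: LI ≥ 4 grades `high`, LI < 3
`low`, and `[3, 4)` `intermediate`. Thresholds are inclusive exactly as
stated by the consensus wording (SI "≥3", LI high "≥4", LI low "<3");
the SUV ratio for MTO is strictly greater than 1.25. The
unilaterally-cannulated rescue rule for right-sided lesions is
deliberately not implemented.

MTO: per side, the dominant nodule is assessed for three features —
benign density (Hounsfield units at most `benign_hu_max`, default 10 HU,
configurable because no consensus number exists), visible tracer
uptake (a boolean input: there is no numeric definition), and a
SUVmax-to-contralateral-background ratio above 1.25. All three ⇒
`high`; both sides meeting the rule is a bilateral signal and
downgrades to `intermediate`; some but not all features ⇒
`intermediate`; none ⇒ `low`. The literal some-features rule means a
benign avid nodule with ratio 1.1 grades intermediate, not low — this
follows the stated rule; only a featureless scan grades low.

MDT rule: both high on opposite sides ⇒ deferred; either high ⇒
surgery on the high side; both intermediate with a strong clinical
indication ⇒ surgery (the MTO side is used if the sides differ, since
MTO is reviewed first and frozen before AVS is revealed); otherwise
medical. The rule is total and symmetric under left/right relabeling.

## PASO outcomes and the hierarchy

Clinical: `complete` = home BP below 135/85 mmHg off all
antihypertensives (strict inequalities, DDD = 0); `partial` = a fall of
at least 20/10 mmHg without more medication, or no-worse BP on a
reduced DDD; else `absent`. Biochemical: `complete` = normokalemia
without supplements, ARR below 1000 (pmol/L per nmol/L/h) with renin
de-suppressed (activity ≥ 0.5 nmol/L/h, the lower reference bound);
`partial` = corrected potassium with an aldosterone fall of at least
50%; else `absent`. All thresholds live in `paso_criteria()` so users
can match their laboratory's reference ranges; the defaults are
consensus-derived encodings, not a verbatim rule book (the full
consensus document distinguishes some cases — e.g. unmeasurable
baseline renin — that these fragments do not). When only renin mass was
measured it is converted by a configurable factor; the shipped 0.1
(nmol/L/h per mU/L) is a documented placeholder because no universal
factor exists.

The four hierarchical endpoints are h1 = partial-or-complete
biochemical, h2 = complete biochemical, h3 = partial-or-complete
clinical, h4 = complete clinical, analyzed in that fixed order with no
multiplicity adjustment (the hierarchy substitutes for it). Success at
one limb does not require success at the previous one, and each limb
keeps its own denominator because data availability differs per
endpoint.

## The paired interval and the two p-values

For a paired 2×2 accuracy table (both / MTO-only / AVS-only / neither
= e, f, g, h; n = e+f+g+h) the difference estimate is exactly
(f − g)/n. The interval is Newcombe's paired score method: Wilson
limits (l₁, u₁), (l₂, u₂) for the two marginal accuracies are combined
by square-and-add with a φ-coefficient correction for the pairing,

lower = d − √[(p₁−l₁)² − 2φ(p₁−l₁)(u₂−p₂) + (u₂−p₂)²],

and symmetrically for the upper limit, with
φ = (eh − fg)/√[(e+f)(g+h)(e+g)(f+h)] set to 0 when any marginal is
zero. No continuity correction is applied (the uncorrected variant is
the default of the implementation the design cites); endpoints are
clamped to [−1, 1].

Superiority is tested by the exact McNemar test,
p = min(1, 2·min(P(X ≤ min(f,g)), P(X ≥ max(f,g)))) with
X ~ Binomial(f+g, ½) — no mid-p, no asymptotic fallback. The
non-inferiority p against margin m (default −0.17) is obtained by
interval inversion: the z for which the interval's lower bound equals m
is found by root-finding (tolerance 1e−10 on a bracket z ∈ (0, 40]),
and p = 2(1 − Φ(z)). This is the one construction consistent with
using the same interval family for estimation and testing; it is
tagged on the result object so an alternative could be plugged in.
Degenerate cases: estimate at or below the margin ⇒ p = 1; lower bound
above the margin even as z → ∞ ⇒ p = 0.

## The synthetic cohort generator

The generator emulates the *statistical structure* of a 128-patient
within-patient trial, not its physiology:

* **Truth**: unilateral with probability `p_unilateral` (default 0.62),
  side 50:50, else bilateral.
* **Grades first, measurements second.** High-grade indicators for the
  two tests are drawn from a shared-latent Gaussian copula: each test's
  indicator thresholds a standard normal variable built from a shared
  "detectability" component with weight √|ρ| (ρ < 0 flips the sign of
  the sharing, modelling complementary detectability). Marginal
  probabilities are `sens_*` given unilateral and `1 − spec_*` given
  bilateral; AVS additionally fails with probability `p_avs_failure`
  (default 0.12), independently of the latents. Non-high grades become
  intermediate with probability `p_intermediate` (default 0.30) —
  defined *conditionally on non-high* so that the calibrated high-grade
  marginals are untouched.
* **Calibration.** By default `spec_mto`, `spec_avs` and ρ are solved
  (`calibrate_concordance()`, bivariate-normal probabilities by
  conditional integration, root-finding to 1e−12) so that the expected
  per-128 Venn structure is exactly 67 MTO-high, 58 AVS-high, 39 both,
  42 neither. Infeasible targets (marginals unreachable, or a joint
  cell outside the Fréchet bounds of the copula) raise an error rather
  than a silent compromise.
* **Raw measurements are synthesized to grade back to the drawn
  grade**: log-normal cortisol with selectivity indices above (or, for
  failed runs, below) 3, a log-normal non-dominant A/C ratio scaled by
  an LI drawn inside the band of the target grade, and MTO nodules
  whose HU/uptake/ratio features encode the target grade. Because the
  thresholds are the grading rules themselves, `grade_cohort()` applied
  to the written numbers reproduces the drawn grades exactly — the
  package's own tests rely on this round trip.
* **Outcomes.** Biochemical outcomes are drawn categorically given
  truth and management (defaults 0.93/0.05/0.02 for operated unilateral
  and 0.60/0.25/0.15 for operated bilateral — removing the dominant
  gland in asymmetric disease often still normalizes biochemistry),
  then follow-up laboratory values are synthesized inside the
  classification regions. Clinical outcomes are *derived*, not drawn:
  Oldham-corrected systolic changes after spironolactone and after
  surgery are generated jointly bivariate-normal with correlation
  `spiro_surgery_correlation` (default 0.53), follow-up pressures are
  back-transformed exactly (post = base·(200+c)/(200−c), the exact
  inverse of the corrected change), and a medication policy (withdraw
  all antihypertensives with probability 0.67 when the follow-up BP is
  controlled, otherwise reduce with probability 0.6) determines DDD.
  The change-scale means (−13/−11%, SD 12/10) and the withdrawal
  probability were fixed once so that complete clinical success lands
  near 31% and partial-or-complete near 65% of operated patients, the
  rates the design targets; they are not tuned per analysis.
* **Genotype** is assigned only to unilateral tumors, with KCNJ5
  enriched among women and good BP responders and CACNA1D among Black
  patients and poor responders, implemented by tilting the assignment
  weights with the realized response (logit shift `genotype_effect` per
  SD) — deliberately *after* the BP draw, so the generating correlation
  of 0.53 is exactly preserved.

What the generator does **not** emulate: measurement error correlated
across visits, regression to the mean in the labs, site effects,
informative AVS failure, wrong-side lateralization in truly unilateral
patients, or any coupling between biochemical category and BP response.
Passing tests therefore demonstrate that the *analysis chain* is
correct and calibrated under a clean mechanism consistent with the
trial's headline structure — not that real cohorts behave this way.

## Parameter recovery and the verification bias

`diagnostic_rates()` estimates sensitivity among operated patients who
achieved the endpoint. Under the default (trial-like) configuration
this conditions on detection and is biased relative to the configured
`sens_*` — upward within unilateral patients (the conditioning divides
by the probability that at least one test is positive) and downward
through bilateral partial successes entering the denominator. That bias is a property of the design, and it is why
the default cohort's measured rates resemble the published ones rather
than the configured inputs. The recovery test therefore uses a
configuration in which the design approximates full verification —
prevalence 0.85, sensitivities 0.90/0.85, complementary detectability
ρ = −0.3, no AVS failures, no clinical-indication surgeries — so the
probability that a unilateral patient reaches surgery is near 1 and the
estimand collapses onto the configured value (recovered within ±0.02 at
n = 10,000).

## Bootstrap sensitivity analysis

Operated patients are split into AVS-failed and AVS-successful strata;
each replicate resamples within each stratum with replacement,
preserving stratum sizes, and records the accuracy difference on the
full replicate minus the difference on its AVS-successful part. The 95%
percentile interval of that statistic (no BCa) declares the result
*sensitive* to AVS failures when it excludes zero. Implementation
detail: per-patient accuracy is a function of a four-category label, so
replicates are drawn as multinomial counts — this makes one million
replicates cheap and makes the statistic's exact distribution
enumerable for small strata, which is how the tests validate it
(compositions of each stratum over the four categories, ≤ 8 patients
per stratum). With an empty failed stratum the statistic is identically
zero and the interval is exactly (0, 0), flagged as degenerate.

## Design tools

Minimization uses the Pocock–Simon range method over site, sex and age
band (<55 / ≥55): the candidate arm minimizing the summed
post-assignment |count difference| across the patient's three factor
levels is chosen with biased-coin probability 0.8 (configurable); exact
ties fall back to a fair coin. The design literature names the
balancing goal but not the algorithm; this choice is the field's
default. Balance is a per-factor-level property — the tests validate
that at least 90% of factor levels end long runs within 3 of balance;
the maximum across all seven levels is a stricter statistic that sits
lower.

`simulate_design()` draws cohorts from a joint table of (MTO high, AVS
high, cure | surgery) cells; the shipped default encodes the design
assumptions (one quarter of patients discordant-high, cure 80:20 in
favour of MTO among them) and its superiority power cross-validates
against the closed-form `discordant_power()`.

## Numerical choices and degenerate inputs

* Clopper–Pearson bounds come from beta quantiles with exact endpoints
  at x = 0 and x = n; coverage is validated by summing binomial mass,
  not by simulation.
* Fisher's exact test delegates to `stats::fisher.test` (probability
  method, full enumeration); tables too large to enumerate require an
  explicit, seeded Monte Carlo opt-in rather than silently switching.
* Odds ratios use the Woolf log-scale interval with Haldane–Anscombe
  0.5 correction when any cell is zero (flagged); a fully zero row or
  column is an error, not a number.
* The bivariate-normal probability in the calibration integrates the
  conditional normal (rel. tol 1e−10) and short-circuits |ρ| ≈ 1 to the
  Fréchet bounds.
* CSV round trips write 17 significant digits so doubles survive
  exactly; JSON uses full precision.
* Deferred patients (opposite-side double-positives) have no follow-up
  and are excluded from scoring with an explicit unscored signal rather
  than a silent drop.

## Problem sizes

The shipped tests use a 2×10⁶-replicate bootstrap oracle on single
tables, 1,000-table coverage sweeps, 100 seeds of 128-patient cohorts
for calibration, one 10,000-patient cohort for recovery and 200 seeds
for correlation-recovery coverage; the full suite runs in a couple of
minutes on one core. The default one-million-replicate bootstrap is
used in production runs, while tests and the example pipeline use 10⁴,
which changes only the smoothness of the percentile estimate, not the
estimand.

## Known limitations

* PASO criteria are encoded from the in-text consensus fragments;
  laboratories should align `paso_criteria()` with their own reference
  ranges before applying the pipeline to real data.
* The false-positive-rate denominator (all medically managed patients)
  is one of several defensible conventions when surgery-refusers carry
  high grades; it is the most conservative for the tests.
* The published headline accuracy differences depend on unpublished
  patient-level tables and are not reproduced here; the package instead
  proves the method properties those numbers rest on.
* Medically managed patients are never PASO-classified for inference
  (the criteria are not validated for medical outcomes), though the
  classifier will mechanically label their follow-up values.
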