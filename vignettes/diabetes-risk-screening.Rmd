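---
title: "Validating a diabetes risk score: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a diabetes risk score: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drscreen)
```

## The problem

Roughly half of the people living with diabetes do not know they have it.
A cheap, non-invasive first-line screen is an additive risk questionnaire:
the Finnish Diabetes Risk Score (FINDRISC) sums points over eight items
(age, BMI, waist circumference, blood-pressure medication, a history of
elevated glucose, daily physical activity, daily fruit/vegetable intake,
family history). People above a score cutoff are referred for a blood
test; glycated haemoglobin (HbA1c) then classifies them as normal,
prediabetic (39--47 mmol/mol) or diabetic (>= 48 mmol/mol), the combined
non-normal class being *undiagnosed diabetes and prediabetes* (UDPD).

`drscreen` implements the full analytical pipeline of such a screening
study: scoring, cutoff validation against HbA1c, cohort follow-up
(incidence, odds ratios, logistic adjustment), behaviour-change tests,
the two design-stage power calculations, and two supporting layers that
make the pipeline testable without access to individual-level data --
exact integer *reconstruction* of rounded published summary tables, and a
seeded *synthetic cohort generator*.

## Scoring

Items are banded exactly as the instrument prints them, with shared edges
read as closed intervals: BMI `[25, 30]` scores 1 and strictly above 30
scores 3; waist (men) `[94, 102]` scores 3, above 102 scores 4 (women 80
and 88); age bands 45--54, 55--64, above 64. Every real-valued input maps
to exactly one category, and the score is monotone in age, BMI and waist
(property-tested over the full categorical product space). BMI is banded
at full precision: the instrument computes it internally from weight and
height (pounds and inches are converted by exact factors), so no
intermediate rounding is applied.

Two printed variants of the fruit/vegetable item circulate: 1 point for
"no" (the original instrument, total range 0--26) and 2 points (range
0--27). A stated score range of 0--26 is arithmetically consistent only
with the 1-point variant, so that is the default; the 2-point variant is
available as `scoring_config(fruit_veg_no_points = 2)`.

High risk is `total >= 9` by default. Cutoff tables index rows as
"score > c", so the narrative cutoff 9 is row `> 8`.

## Diagnostic accuracy and cutoff selection

`diagnostic_summary()` reports sensitivity, specificity, PPV and NPV with
exact Clopper--Pearson 95% intervals (beta-quantile form). The exact
interval was fixed deliberately: on the reconstructed validation tables
it reproduces the published bounds at two decimals, while Wilson and Wald
intervals do not come close. Both Youden conventions are returned:
`youden_j` = sens + spec - 1 (the standard index) and `youden_plus` =
sens + spec, a convention some reports print; they differ by a constant,
so the argmax over cutoffs is identical.

ROC analysis (`roc_auc()`) computes the AUC by the tie-corrected rank
statistic -- P(score_pos > score_neg) + P(tie)/2 -- which equals
trapezoidal integration over the cutoff-swept operating points exactly on
integer scores (a property the test suite checks to 1e-12). The AUC
interval uses the Hanley--McNeil standard error with Q1 = A/(2-A),
Q2 = 2A^2/(1+A), consistent with the power calculator.

**Selection precision.** `select_cutoff()` maximises Youden J (or kappa)
with ties broken toward the *lower* cutoff -- in a screening context the
cheaper error is a false positive, so sensitivity is favoured. When a
published table is the input, selection can be run at the table's
reporting precision (`digits = 2`): exact reconstructed counts can
reorder cutoffs whose printed criteria tie. On the bundled validation
table, rows `> 8` and `> 10` both print a Youden sum of 1.27; the exact
reconstructed counts put `> 10` marginally ahead (0.2713 vs 0.2650),
while at two decimals the tie resolves to `> 8`. The original optimum was
computed on unreleased individual data; neither ordering at the third
decimal is recoverable from print.

**Display rounding.** Core functions never round. The display layer uses
half-up rounding (`round_half_up()`; base R's round-half-even turns 1.265
into 1.26, manuscripts print 1.27). Confidence bounds and p values are
formatted with `round_report()`, which rounds at a 3-decimal working
precision first and then at 2: statistical software displays three
decimals (or percentages at one decimal), and manuscripts round that
display. A Clopper--Pearson bound of 0.7947 therefore prints as 0.80 (via
79.5%), and an exact p of 0.0546 prints as .06 (via .055) -- boundary
cases that single-stage rounding cannot reproduce.

## Cohort follow-up

Person-time is months/12, summed per risk group. Both person-time
conventions are implemented because neither is innocent with ~15 events:
censoring cases at diagnosis (the default) or counting full follow-up
for everyone. The choice is an explicit argument rather than a hidden
constant.

The unadjusted group effect is the 2x2 cross-product odds ratio with the
Wald interval exp(ln OR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d)) and the
two-sided Fisher exact p under the probability-mass rule (sum of
hypergeometric probabilities no larger than the observed table's), the
dominant convention and the one `stats::fisher.test()` applies; the test
suite checks it against exhaustive enumeration. Zero cells follow an
explicit policy: error, or Haldane's +0.5 with a flag.

`fit_logistic()` fits the adjusted model by IRLS (binomial logit) and
then polishes the solution with analytic Newton steps: the usual
deviance-based stopping rule leaves roughly 1e-7 in the coefficients,
and the saturated binary-exposure fit should reproduce the 2x2 closed
form to 1e-8 -- an invariant the suite asserts, alongside agreement with
a grid-search likelihood maximiser. Wald standard errors come from the
inverse observed information at the polished solution. Reference coding
follows the study's contrasts (low risk, female, tertiary-or-higher
education; see `cohort_factors()`). Complete separation is flagged, not
silently reported; rank-deficient designs are an error. Calibration uses
the Hosmer--Lemeshow chi-square over deciles of fitted risk, collapsing
tied-boundary groups and reducing the degrees of freedom accordingly.

Behaviour change is a paired t test on 0/1 indicators
(`paired_binary_change()`): only discordant pairs move the statistic, and
the means/SDs are ordinary sample statistics of the binary vectors, which
is how the published baseline/follow-up summaries are defined.

## Power calculators

*ROC design.* `auc_sample_size()` solves
z_{1-a/2} sqrt(V0) + z_{power} sqrt(V1) = A - 0.5 for a continuous
number of positives with the negatives at a fixed ratio, using the
Hanley--McNeil variance (V0 at A = 0.5). The continuous per-group
solution is rounded to the nearest integer by default -- the convention
of the ROC sample-size software this design mirrors (A = 0.70, ratio 6
gives 19.06 positives, i.e. 19 + 114 = 133); `round = "up"` gives the
conservative 140.

*Logistic design.* `logistic_sample_size()` implements the Demidenko
z-test for a binomial exposure. Under the alternative the slope variance
is V1 = 1/((1-pi) p0 q0) + 1/(pi p1 q1); the *variance correction*
(default) evaluates the null-hypothesis variance at the mean-matched
null model, V0 = 1/(pbar qbar pi (1-pi)), which inflates the requirement
-- without it V0 = V1 and n is strictly smaller. Power analyses for a
risk factor expected to *increase* risk are typically specified
directionally, so the default is one-tailed (`tails = 1`); with OR 4.5,
p0 0.05, pi 0.14, alpha 0.05 and power 0.80 the corrected one-tailed
requirement is n = 292 (continuous 291.4), while the two-tailed variants
give 378 (corrected) and 246 (uncorrected). Only the one-tailed corrected
setting reproduces the published calculation for this design, which is
why it is the default rather than the two-tailed textbook choice.

## Reconstruction oracles

Published tables print proportions rounded to two decimals over known
denominators, which often pins down the underlying integers exactly.
`invert_rounded_count()` inverts a single rounded proportion;
`rebuild_confusion()` solves the joint system over (TP, TN) given all
four accuracy metrics; `reconstruct_case_split()` splits total incident
cases across groups to match reported incidence rates;
`solve_discordant_pairs()` recovers gain/loss counts from a rounded
paired t. Half-up rounding is assumed throughout (it reproduces every
printed cell tested; round-half-even does not). Ambiguity is never
guessed away: zero or multiple candidates raise a `drs_not_unique`
error listing them, forcing the caller to add constraints -- the
specificity of one validation row is ambiguous on its own ({42, 43}) and
is disambiguated by the NPV.

## The synthetic generator

`generate_study()` emulates the data flow of the study: a large app-user
table, a small assessed subsample with HbA1c, and a follow-up subsample
with events and behaviour flags, linked by id. Design choices:

* **Category-level items with age linkage only.** Items are drawn at
  category level with per-age-band probabilities; no latent continuous
  traits and no other cross-item correlation. The band-linked marginals
  were calibrated once, deterministically (law-of-total-variance moment
  matching), so the expected score mean and SD equal the targets 9.10
  and 4.85; the probabilities rise with age band as real risk factors
  do. Raw anthropometry (weight, height, waist) is drawn inside the
  intended category with a margin so that rounding cannot cross a band
  edge.
* **Score-to-UDPD link.** P(UDPD | score) is logistic;
  `calibrate_hba1c_link()` solves deterministically (nested
  root-finding on the score distribution, no simulation noise) for the
  intercept and slope that hit a target prevalence and AUC. The shipped
  defaults (-1.5468, 0.13152) give prevalence 0.42 and AUC 0.67 over the
  default score distribution.
* **Follow-up.** Months follow a truncated normal (22.66, SD 5.83) on
  [1, 28] -- the truncation reflects the observed 1--25-month diagnosis
  range plus margin. Events are Bernoulli with a low-risk 2-year
  probability of 0.016 and high-risk odds multiplied by `or_true`
  (default 4.59); diagnosis months are uniform over the individual
  follow-up window. Event probability is per subject, not per
  person-month, matching the logistic (not survival) analysis model.
* **Seeding.** A single seed feeds a named stream per table, so each
  table is reproducible independently; generation is bit-reproducible.

What the generator does *not* emulate: self-selection of the assessed
and follow-up subsamples (respondents in real studies skew older and
higher-risk), self-report measurement error, attrition mechanisms, and
interval censoring of diagnosis dates. Passing tests therefore show that
the pipeline recovers known parameters under clean sampling -- not that
the estimates are unbiased under the selection processes of a real
deployment.

## Problem sizes and numerical choices

The test suite exercises the generator at 1,000--40,000 users (chi-square
goodness of fit of the marginals at 12,000; cutoff-selection consistency
at 40,000; odds-ratio recovery at 10,000) and runs the parameter-recovery
study at the study's own follow-up size, n = 326, over 200 seeded
replicates. With ~15 events per replicate roughly a tenth of replicates
have an empty low-risk event cell; the Wald interval does not exist
there, so coverage is assessed over the estimable replicates (patching
with Haldane intervals, which almost always cover, would measure a
different estimator). Near-nominal coverage at ~15 events is itself at
the edge of what the Wald log-OR interval can deliver -- it is mildly
conservative in small samples.

Other numerical conventions: IRLS convergence at relative deviance 1e-10
plus Newton polish to a 1e-12 step norm (max 50 + 5 iterations);
root-finding by `uniroot` at 1e-10 tolerances; Clopper--Pearson via
`qbeta`; Fisher p via `fisher.test`; percent HbA1c converted by the
IFCC relation (pct - 2.15) x 10.929 and rounded to integer mmol/mol.

## Limitations

HbA1c is the only gold standard modelled (no oral glucose tolerance
test); the follow-up analysis is plain logistic regression, not a
survival model, so interval censoring is ignored by design; the BMI and
waist bands are the instrument's European ones -- re-deriving
Asian-specific bands is out of scope; and quantities that depend on the
unreleased individual-level data (the exact AUC, kappa, adjusted OR,
overall incidence) are calibration targets for the generator, not values
the package claims to reproduce exactly.
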