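---
title: "Statistical methods in snpcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in snpcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcohort)
```

`snpcohort` re-implements, as reusable and tested components, the complete
statistical workflow of a small candidate-gene case-control study of
coronary artery disease (CAD) with a prospective survival arm: genotype
association under inheritance-model contrasts, EM haplotype and linkage
disequilibrium (LD) analysis, additive and multiplicative gene-environment
interaction from 4x2 tables, and Kaplan-Meier/log-rank survival over
truncated follow-up horizons. A seeded synthetic-cohort generator stands in
for patient-level data, which studies of this kind rarely deposit.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and the limits of what the synthetic data
can establish.

## Data model

A `cohort()` couples a subject table (status `case`/`control`, one
genotype-dosage column per SNP, covariates, optional survival record) with a
SNP annotation table. Genotypes are dosages (0/1/2) of a *counted* allele;
by convention the counted allele is the minor allele of the combined sample,
with ties broken lexicographically, so that published "minor-allele
homozygote" contrasts are reproducible from data alone. Missing calls are
`NA`, never 0, and every analysis drops incomplete subjects pairwise — the
motivating study genotyped 94–97% of participants, so per-SNP denominators
differ, and the package mirrors that behaviour.

Survival records (`time` in years from diagnosis, `event` = death from the
cardiovascular endpoint) are only accepted on cases: controls are blood
donors with no follow-up. Deaths from other causes are censoring events.

## Association statistics

For one SNP with genotype counts $(n_{AA}, n_{Aa}, n_{aa})$ per group, the
package emits the contrasts used in the motivating table: dominant
(major-allele homozygotes vs the rest), additive (heterozygotes vs
major-allele homozygotes), recessive in both orientations, and the
allele-level odds ratio in both orientations. Each is a 2x2 cross-product
odds ratio

$$\widehat{OR} = \frac{ad}{bc}, \qquad
  \ln \widehat{OR} \pm z_{0.975}\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}$$

with a Woolf (log-normal) confidence interval and a Pearson chi-square
p-value *without* continuity correction. Both choices were validated against
the published table: the uncorrected chi-square reproduces the printed
p-values at rounding precision and the Woolf interval reproduces the printed
CIs at two decimals; a Yates-corrected chi-square does not. Zero cells
follow a policy argument: `haldane` (add 0.5 to all cells, flagged, the
default), `error`, or `risk_ratio` — the fallback the study itself states —
which reports $RR = \frac{a/(a+c)}{b/(b+d)}$ with a log-RR interval.

Hardy-Weinberg equilibrium is tested against expectations
$n\hat p^2, 2n\hat p\hat q, n\hat q^2$ with a 1-df chi-square, plus an exact
enumeration of heterozygote counts conditional on the allele count
(probability-mass two-sided rule) as a cross-check. The exact test is
conservative relative to the chi-square at moderate counts (differences up
to ~0.1 in mid-range p-values are normal and the two only converge in the
asymptotic regime); the test suite asserts the exact method against a
Monte-Carlo allele-pairing oracle rather than against the chi-square.

`logistic_fit()` provides covariate-adjusted odds ratios through the
standard binomial GLM (iteratively reweighted least squares), with explicit
errors for non-convergence and (quasi-)complete separation. A univariate fit
on a single binary indicator reproduces the cross-product odds ratio to
1e-6, which the suite asserts.

`posthoc_power()` implements one defensible reading of post-hoc power
statements that accompany such tables: the power of the two-sided pooled
two-proportion z-test at the observed proportions and group sizes. The
original computation behind the published power figures is not specified,
so this operation is generic and is not used to reproduce any printed value.

## Haplotypes, LD and blocks

`em_haplotypes()` runs expectation-maximisation over diplotype expansions:
each multi-heterozygous subject distributes fractional weight over its
compatible haplotype pairs in proportion to current frequency products
(random-mating assumption), and the M-step re-estimates frequencies from
expected counts. Initialisation is the product of marginal allele
frequencies — deterministic, and adequate for the 2–3 SNP windows this
package targets (an optional seed-controlled restart is unnecessary there).
Convergence is declared when the largest frequency change drops below
`tol = 1e-10` (cap `max_iter = 1000`); the log-likelihood is checked to be
non-decreasing at every iteration and estimated frequencies below 1e-6 are
truncated and renormalised on output. The test suite pins the EM output to a
brute-force grid maximiser of the multinomial likelihood (1e-4 final grid
resolution) on small instances, and to direct counting whenever no subject
is ambiguous.

From the four two-locus haplotype frequencies, `ld_measures()` derives
$D = p_{AB} - p_Ap_B$, $D' = |D|/D_{\max}$, and
$r^2 = D^2/(p_Ap_ap_Bp_b)$. The $D'$ confidence bounds come from a seeded
nonparametric bootstrap over subjects, 1000 resamples by default, reported
as a 90% percentile interval to match the one-sided 5%/95% bounds used in
Gabriel-style block calling. This is a deliberate dialect difference from
Haploview's likelihood-based bounds; with the sample sizes involved the two
are close, but bootstrap bounds are simpler to reason about and reproducible
under a seed. Cases and controls are pooled for LD work, as the motivating
analysis reports a single study-group block structure.

`gabriel_blocks()` classifies each pair (strong LD if the upper bound
$\ge 0.98$ and lower bound $\ge 0.70$; strong recombination if the upper
bound $< 0.90$; otherwise inconclusive) and accepts a contiguous candidate
block when at least 95% of its informative pairs are strong LD, reporting
maximal non-overlapping blocks.

## Gene-environment interaction

`build_4x2()` classifies subjects by a genotype risk-carrier rule and a
dichotomous exposure, against the fixed doubly-unexposed reference cell.
Numeric exposures use an inclusive threshold (total cholesterol
$\ge$ 5 mmol/L is the canonical one). Three odds ratios against the common
reference ($OR_{01}$ exposure only, $OR_{10}$ genotype only, $OR_{11}$
joint) yield

$$RERI = OR_{11}-OR_{10}-OR_{01}+1, \quad AP = RERI/OR_{11},$$
$$SI = \frac{OR_{11}-1}{(OR_{01}-1)+(OR_{10}-1)}, \quad
  SIM = \frac{OR_{11}}{OR_{01}\,OR_{10}}.$$

The published formula strings for SI and SIM are typeset linearly; the
package restores conventional precedence, which is the standard Rothman /
Knol–VanderWeele definition the study cites. The four identities are exact
at point estimates by construction and asserted to 1e-12.

Interval estimation:

* **RERI, AP** — Hosmer–Lemeshow delta method by default, using the full
  3x3 covariance of the log-odds-ratios (the shared reference cell
  contributes $1/a_{00}+1/b_{00}$ to every covariance); MOVER and a seeded
  multinomial bootstrap are available alternatives.
* **SI** — Zou's MOVER construction: the numerator $OR_{11}-1$ takes its
  limits from the Woolf interval; the denominator
  $(OR_{01}-1)+(OR_{10}-1)$ takes MOVER-sum limits with the shared-reference
  correlation; the two are combined with the Donner–Zou MOVER-R ratio step
  *including* the numerator–denominator correlation (delta method on the OR
  scale). Without that correlation the interval is far too wide — the suite
  checks MOVER against bootstrap limits at n = 5000 and they agree to
  about 1% of the interval width. When the denominator interval spans zero
  the ratio interval is undefined and flagged rather than extrapolated.
* **SIM** — normal interval on
  $\ln SIM = \ln OR_{11} - \ln OR_{01} - \ln OR_{10}$ with the same
  covariance matrix.

SI is undefined when $(OR_{01}-1)+(OR_{10}-1)=0$ and is then reported as
`NA` with a flag while the other measures are returned. When $OR_{01}$ and
$OR_{10}$ are not both above 1, SI estimates are reported with an
interpretability warning rather than suppressed. Note that $AP \le 1$ is
only guaranteed when $OR_{01}+OR_{10} \ge 1$; with two strongly protective
factors AP can exceed 1, which is a property of the measure, not a bug.

Zero cells outside the reference trigger a single Haldane correction of all
eight cells (keeping the shared-reference covariance coherent), flagged in
the output; the risk-ratio fallback remains available upstream.

`interaction_scan()` evaluates every SNP-contrast x exposure pair, ranks by
RERI, and reports Bonferroni-adjusted p-values; following the study's
convention, synergy is declared at p < 0.025 (its Bonferroni-corrected
threshold). Default exposure definitions beyond the stated TC >= 5 mmol/L
are documented choices: LDL >= 3.0 mmol/L, BMI >= 25 kg/m^2, and recorded
smoking/hypertension flags; all are configurable.

## Survival

`km_estimate()` is the product-limit estimator with Greenwood variance.
A follow-up horizon (5 or 10 years in the motivating design)
administratively censors subjects beyond it, so an event after the horizon
never counts; at tied times deaths are processed before censorings.
`logrank_2group()` returns the signed statistic
$z = (O_a-E_a)/\sqrt{V}$ with hypergeometric variance accumulated over
distinct event times; group *a* is by convention the minor-allele-homozygote
group, so a negative $z$ means fewer deaths than expected in that group.
`logrank_ksample()` is the k-sample statistic on $k-1$ degrees of freedom
and reduces to $z^2$ at $k = 2$ (asserted to 1e-10). The across-genotype
"chi-square test" of the motivating analysis is interpreted as this
k-sample log-rank — the default multi-group survival comparison in the
statistical software that analysis used; this reading is a documented
design decision. The suite cross-checks both estimators against the
`survival` package on random datasets to 1e-8 and checks empirical power
under a hazard ratio of 2 against the Schoenfeld approximation.

## The synthetic cohort generator

`cohort_sim_config()` defaults describe the emulated study: 231 cases and
240 control blood donors; rs1994016 (C>T) and rs3825807 (A>G) drawn as two
haplotypes per subject from a pool with near-complete LD and margins
matching the published control minor-allele frequencies
(pool CA = 0.560, TA = 0.002, CG = 0.018, TG = 0.420, i.e. $D' \approx
0.99$, $r^2 \approx 0.92$); rs7173743 (T>C, MAF 0.457) drawn independently
under Hardy-Weinberg. The published block analysis implies near-complete
LD between the first two SNPs — a pool with $D'$ materially below 1 would
not reproduce a Gabriel block at this sample size, so near-complete LD *is*
the emulated condition. The separately published leading haplotype
frequency of 0.584 is used verbatim as an explicit pool argument in the EM
parameter-recovery checks.

Disease status is assigned by rejection sampling from a logistic model
until the target group sizes are met:
$\text{logit}\,P(\text{case}) = -2.0 + \log(1.3)\,\text{carrier} +
\log(1.5)\,[TC \ge 5] + \log(2.2)\,\text{carrier}\times[TC \ge 5]$,
where "carrier" is major-allele (A) carriage at rs3825807. The intercept
keeps the attempt budget modest (~15–30% acceptance); the effect sizes are
of the magnitude the motivating study reports (carrier odds ratios near
1.7, clear synergy with cholesterol) without being tuned to any printed
figure. Lipids are lognormal (TC meanlog log 5.1, sdlog 0.18; HDL log 1.25,
0.20; TG log 1.5, 0.35 — all mmol/L), LDL is computed by the Friedewald
formula ($LDL = TC - HDL - TG/2.2$, valid for TG < 4.5 mmol/L, `NA`
outside it), BMI is N(27, 4^2), and male/smoking/hypertension are Bernoulli
(0.75/0.45/0.40) — values typical of premature-CAD cohorts. Case survival
is exponential (baseline hazard 0.035/yr; GG homozygotes at rs3825807 carry
log-HR −0.5, mirroring the reported protective 5-year trend) with
independent exponential censoring (0.02/yr) and truncation at 10 years.
Genotype calls fail independently at rate 0.04, inside the study's stated
94–97% completeness.

Everything derives from one seed; the same seed reproduces the dataset
byte-for-byte.

Two structural caveats on what passing tests show. First, case-control
selection under a genotype-dependent disease model necessarily perturbs
*control* genotype frequencies slightly away from Hardy-Weinberg; at the
study's n this is undetectable, but at n = 2000 controls it is, so the
generator's HWE validity check runs under a genotype-independent risk
model. Second, the generator draws covariates independently of genotype and
of each other, has a single two-SNP LD block rather than reference-panel LD
structure, and has no population stratification or relatedness — so tests
passing on synthetic cohorts demonstrate correctness of the estimators
under the stated model, not robustness to confounding structures absent
from it.

## Problem sizes used by the test and acceptance runs

The suites use the smallest sizes at which each property is informative:
grid-oracle EM checks on <= 10 subjects; EM pool recovery at n = 2000
haplotype draws; RERI coverage at 1000 replicates of n = 2000 per group and
the multiplicative-null SIM mean at 500 replicates; log-rank power at 1000
replicates of 200 per arm (baseline hazard 0.03/yr over a 5-year horizon,
~80 events — a regime where the Schoenfeld approximation is accurate to
well under one point, so the comparison tests the implementation rather
than the approximation); LD bootstraps at 150–1000 resamples. These choices
are stated here so that reported rates can be reproduced exactly.

## Known limitations

* Interaction odds ratios are unadjusted table-based estimates; a
  logistic-adjusted variant is available through `logistic_fit()` but the
  4x2 measures themselves are marginal.
* Exact logistic regression and Firth correction are out of scope; sparse
  tables rely on the Haldane correction or the risk-ratio fallback.
* The EM window is limited to 10 SNPs and does not phase individual
  subjects.
* Haplotype-disease association testing and Cox regression are deliberately
  absent — the motivating analysis fits neither.
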