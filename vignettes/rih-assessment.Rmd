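---
title: "Scoring responsible innovation in health and measuring rater agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring responsible innovation in health and measuring rater agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rihtool)
library(dplyr)
```

## The instrument

Responsible innovation in health (RIH) asks whether a health technology is
designed, produced and distributed in a way that addresses population
health needs, system-level challenges, affordability and environmental
impact — characteristics that conventional health technology assessment
rarely captures upstream. `rihtool` implements the three-step assessment
instrument built around that framework, together with the inter-rater
reliability statistics used to validate such instruments.

**Screening.** Four dichotomous gates: two inclusion criteria
(*determinants of health*, *innovativeness*) that must be "yes", and two
exclusion criteria (*unavailability*, *corporate social irresponsibility*)
that must be "no". `rih_screen()` refuses incomplete answers rather than
guessing: a screening decision is a judgment, not an imputation. An
innovation that fails screening can still be rated — `rih_rate()` reports
the screening outcome alongside the score so the two judgments stay
distinct.

**Assessment.** Nine attributes in five value domains (population health ×3,
health system ×3, economic, organizational, environmental), each graded on a
4-level ordinal scale. The point mapping is deliberately non-equidistant:

| grade | meaning | points |
|---|---|---|
| A | high degree of responsibility | 5 |
| B | moderate | 4 |
| C | low | 2 |
| D | no particular signs | 1 |

The B–C gap encodes a substantive judgment — a clear break between
innovations with and without recognisable responsibility features — and is
why the mean score of a half-A/half-C profile lands near 3.5 rather than 4.
All nine attributes carry equal weight: no evidence base justifies ranking
one domain above another, and unweighted means keep trade-offs explicit.

**Rating.** Two components qualify the overall score:

* *availability*: at least 7 of 9 attributes must carry a grade;
* *quality*: the mean of best-source points (type 1 producer documentation,
  type 2 institutional reports, type 3 peer-reviewed literature, worth
  1/2/3 points) over sourced attributes must reach 2. When several sources
  back one attribute, only the highest-quality type counts
  (`best_source()`).

The overall score — the mean of grade points over documented attributes —
is `meaningful` only when both components clear their thresholds, and is
classified into four intervals: 1.0–2.0 "Almost no RIH features are
present", 2.1–3.0 "Few", 3.1–4.0 "Many", 4.1–5.0 "Almost all".

```{r rating-example}
sc <- scorecard("example",
                grades  = points_to_grade(c(5, 1, NA, 2, 4, 1, NA, 1, 2)),
                sources = c(3, 3, NA, 2, 3, 2, NA, 2, 3))
rih_rate(sc) |> select(n_documented, quality_mean, overall_score,
                       interval, meaningful)
```

## Numerical conventions

These choices are not dictated by the instrument's published description
and are fixed here as package policy:

* **Rounding** is half-up to one decimal (`round_half_up()`), applied to
  the overall score and the quality mean. The published worked examples
  (41/9 → 4.6, 32/9 → 3.6, 16/7 → 2.3) are consistent with several
  rounding rules; half-up is the convention people apply by hand.
* **Interval edges** operate on the *rounded* score, so the printed bands
  partition exactly: a raw 2.05 rounds to 2.1 and reads "Few". Scores are
  only ever reported at one decimal, so no information is lost.
* **Thresholds compare rounded values** for the same reason; the quality
  boundary is inclusive (a mean of exactly 2.0 suffices).
* **"Documented" means the grade is present.** An attribute graded without
  any recorded source counts toward availability but is excluded from the
  quality mean (with a warning): the two rating components are independent
  measurements. If *no* attribute has a source, quality — and hence
  meaningfulness — is reported as `NA`, not silently failed.
* All thresholds live in `rih_config()`; overriding them is supported for
  sensitivity analysis but results are conspicuously marked non-canonical.

## Agreement statistics

Reliability of the instrument is established by having two raters assess
the same innovations. Three indices are provided.

**Weighted percent agreement.** `percent_agreement()` is the mean credit
`w(x_1, x_2)` over items rated by both raters. For ordinal grades the
credit is quadratic, `w_kl = 1 − ((k−l)/(q−1))²`: adjacent-grade
disagreements retain 8/9 of the credit on a 4-level scale. Identity
weights (exact matches only) are used for the nominal screening answers.

**Gwet's AC.** Chance-corrected agreement with the paradox-resistant
chance term
\[
p_e = \frac{T_w}{q(q-1)} \sum_k \pi_k (1 - \pi_k), \qquad
AC = \frac{p_a - p_e}{1 - p_e},
\]
where \(T_w\) is the total weight mass and \(\pi_k\) the average
proportion of raters using category \(k\). Unlike kappa-type corrections,
\(p_e\) stays small when the marginal distribution is concentrated, so
high observed agreement on skewed scales is not paradoxically penalised.
Identity weights give AC1, quadratic weights AC2.

Standard errors use the two-rater linearization: per-item influence values
of the coefficient, corrected for the fact that the chance term is itself
estimated, without finite-population correction (the rated innovations are
treated as a sample from an unlimited universe of innovations).
Confidence limits use Student's *t* with *n* − 1 degrees of freedom,
clipped to \([-1, 1]\); the p-value tests the coefficient against zero,
two-sided (the convention when sidedness is unstated). Perfect agreement
yields SE 0, CI [1, 1] and no p-value. The test suite cross-checks the
linearized SE against a delete-one jackknife — an independent variance
route over the same estimator — and requires agreement within 10% on
random tables of 25 items.

Items missing either rating are dropped per attribute (pairwise deletion),
which is what produces attribute-specific *N*s when information is
unavailable for some innovations; \(\pi_k\) is estimated from the retained
items.

**Pearson's r** (`rih_correlation()`) complements agreement on the
continuous overall scores: it measures linearity, not identity. Verbal
interpretation uses the conventional magnitude bands, resolved on the
2-decimal |r| (≤ 0.30 negligible, ≤ 0.50 low, ≤ 0.70 moderate, < 0.90
high, ≥ 0.90 very high — 0.90 itself belongs to the top band, its printed
lower bound). Agreement coefficients get Landis–Koch labels, with band
edges resolved on the 2-decimal coefficient so the printed bands
partition.

**Sample-size planning.** `agreement_sample_size()` returns the smallest
*n* whose worst-case normal-approximation half-width for a proportion,
\(z \sqrt{0.25/n}\), fits the error margin; a ±0.20 margin at 95%
confidence gives 25 items.

```{r agreement-example}
tbl <- simulate_rating_pair(n_items = 25, q = 4,
                            marginal = c(0.5, 0.2, 0.2, 0.1),
                            agreement_prob = 0.85, seed = 42)
gwet_ac(tbl$rater_1, tbl$rater_2, weights = "quadratic", categories = 1:4)
```

## What the synthetic generator emulates — and what it does not

`simulate_rating_pair()` mirrors a two-rater reliability design: rater 1
draws i.i.d. from a marginal over *q* ordered categories; rater 2 copies
with probability `agreement_prob`, otherwise errs by one rank
(`adjacent_category`, reflected at the scale edges — the plausible error
of a careful rater on an ordinal scale) or redraws from the marginal
(`independent_redraw`, apt for nominal answers). Missingness is applied
per cell or per item; per-item masking reproduces the situation where no
information exists for an innovation, so *both* raters are silent.

`simulate_scorecards()` draws whole scorecards. Its defaults are the
observed composition of a published 25-innovation validation sample:
per-attribute grade marginals (e.g. health relevance ≈ 84/4/4/8% over
A–D), per-attribute missingness (none for health relevance, 14/25 for
eco-responsibility, whose evidence base is thinnest), screening
include/exclude rates (100/100/88/88% favourable answers), and a
source-type marginal (0.40/0.30/0.30) fixed so that roughly a third of
simulated samples clear the quality threshold, as observed (36%). These
defaults are study conditions, not tuning knobs.

Real data differ in ways the generator deliberately ignores: rater errors
are independent across items (no halo effects or shared documentation
asymmetries), attribute grades are independent of each other within an
innovation (real responsibility features correlate), and missingness is
completely at random rather than driven by the kind of innovation.
Passing tests therefore validate the *estimators and scoring arithmetic*,
not the behaviour of human raters.

The generator also supports analytic verification:
`expected_pair_agreement()` computes the population values of weighted
agreement, chance agreement and the AC coefficient implied by a design,
and — with `order = 2` and a sample size — adds the delta-method
\(O(1/n)\) term (from the exact item-level moments of the generator),
giving the expectation of the *estimator* at that sample size. The AC
estimator is a smooth ratio of sample means, so at *n* = 25 its mean over
replicates sits visibly above the population value; the second-order
expectation accounts for that and is what Monte-Carlo calibration tests
compare against (500 replicates per design, sizes chosen to keep the
whole suite within a couple of minutes on one core).

## Known limitations

* Strictly two raters; multi-rater generalisations of AC and its variance
  are out of scope.
* Alternative chance-corrected indices (Cohen's kappa, Scott's pi,
  Krippendorff's alpha) are intentionally not provided.
* The substantive appraisal — reading evidence and deciding that a
  business model merits a B — is a human task; grades and source types are
  inputs here, including the burden-of-disease quartile behind the health
  relevance attribute.
* The reliability of a *given* published study cannot be re-derived from
  summary tables alone (the raw two-rater data are not public); what the
  package reproduces exactly are the worked scorecard examples, the
  perfect-agreement patterns, the benchmark labelling and the design
  sample size, plus the estimator's properties under simulation.
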