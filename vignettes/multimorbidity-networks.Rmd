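---
title: "Multimorbidity association rules and networks by HRQoL status: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity association rules and networks by HRQoL status: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbnet)
```

## The problem

Older adults rarely live with one chronic disease at a time. Multimorbidity
— the coexistence of two or more chronic conditions — is both common and
strongly tied to health-related quality of life (HRQoL), and the *pattern*
of co-occurrence matters: some disease pairs travel together far more often
than their individual prevalences predict. `morbnet` implements a complete
analysis chain for this question on survey-style data: EQ-5D-3L utility
scoring and HRQoL grouping, pairwise association-rule mining, construction
of support-weighted disease networks, and a survey-weighted logistic model
of poor HRQoL on multimorbidity burden. A synthetic-cohort generator with
known ground truth backs every stage, so the statistical machinery can be
validated end to end without access to restricted survey microdata.

The package works on a fixed panel of 15 chronic diseases (see
`disease_panel()`): hypertension, arthritis, asthma, stroke, angina
pectoris, myocardial infarction, diabetes, thyroid disease, renal failure,
hyperlipidemia, liver disease, depression, tuberculosis, chronic kidney
disease (CKD, defined as eGFR < 60 mL/min/1.73 m², strict inequality), and
cancer (all sites collapsed).

## EQ-5D-3L scoring and HRQoL groups

The EQ-5D-3L describes a health state by five dimensions (mobility,
self-care, usual activities, pain/discomfort, anxiety/depression) at three
levels each. An additive "N3" value set maps a state to a utility index:

$$ \mathrm{index} = 1 \;-\; c \cdot \mathbb{1}[\text{any} > 1] \;-\;
   \sum_d \delta_{d,\ell_d} \;-\; n_3 \cdot \mathbb{1}[\text{any} = 3]. $$

Full health (1,1,1,1,1) scores exactly 1.0; the worst state (3,3,3,3,3)
scores the set's floor. The bundled `korean_3l_synthetic` set is a
*synthetic* Korean-style tariff: the published Korean coefficients are not
redistributed, so the shipped coefficients are stand-ins of realistic
magnitude constrained to reproduce the documented Korean index range
$[-0.17, 1.00]$ exactly. Value sets are editable YAML; substantive
applications should substitute licensed coefficients.

HRQoL groups partition the index range:

* **poor**: index $\le$ 0.721 (ties at the cutoff are poor),
* **good**: index $= 1.0$ exactly,
* **normal**: strictly between.

The default cutoff 0.721 is the lowest-5% cutpoint of the source survey's
full adult EQ-5D distribution; deriving it requires that microdata, so it
enters as a fixed constant. `derive_cutoff()` exists for applying the
lowest-quantile rule to data you do hold; it uses the order-statistic
(inverse-ECDF, `type = 1`) quantile so that "the lowest 5%" is exactly the
set of records at or below the returned value — a linear-interpolation
quantile can return a value observed by nobody, which muddles the
membership semantics.

## Association rules

For each ordered disease pair $X \to Y$ in a stratum of size $n$ with
counts $n_X$, $n_Y$, $n_{XY}$:

$$ \mathrm{support} = \frac{n_{XY}}{n}, \qquad
   \mathrm{confidence} = \frac{n_{XY}}{n_X}, \qquad
   \mathrm{lift} = \frac{n \, n_{XY}}{n_X n_Y}. $$

Lift above 1 means the pair co-occurs more than expected under
independence. Mining is always exhaustive over the 105 unordered pairs
(both directions emitted); itemsets larger than two are out of scope
because every quantity reported downstream is a two-disease rule. The
`min_support` default is 0 — truncation to a top-*k* table
(`top_rules()`, default 20 directed rules = 10 pairs) is presentation, not
mining. Numerical conventions:

* internal statistics are full precision; printed percentages and lifts
  are rounded **half-up** to one decimal (`round_half_up()`), the
  convention that reproduces every checked cell of the bundled reference
  tables (`reconstruct_reference_rules()` demonstrates this: printed
  confidences and lifts are recovered exactly from printed marginals and
  supports in the male poor-HRQoL stratum);
* ties in support order by descending lift, then the alphabetical pair
  key, then antecedent — deterministic, and the two directions of a pair
  are never separated;
* a pair involving a disease absent from the stratum has undefined
  (masked, `NA`) lift — never 0.

## Disease networks and node strength

`build_network()` returns, per stratum, prevalence-sized nodes and
support-weighted edges. Node strength is the support row-sum over **all**
14 partners,

$$ s_i = \sum_{j \ne i} w_{ij}, \qquad w_{ij} = \mathrm{support}(i,j), $$

computed before any display threshold. The exported `edge_threshold` only
filters which edges appear in the serialized graph; strengths are
threshold-invariant by construction. Supports enter in proportion units
(0–1), which puts strengths on the familiar 0–1.5 scale for a 15-disease
panel. Layout, colour and size scaling are deliberately out of scope: the
GraphML/edge-list exports carry the underlying quantities so any plotting
tool can render the figure.

## Survey-weighted logistic regression

`fit_weighted_logistic()` maximises the weight-multiplied Bernoulli
log-likelihood by iteratively reweighted least squares (relative deviance
tolerance $10^{-8}$, at most 50 iterations; divergence of any coefficient
beyond $|\beta| > 15$ is reported as separation, naming the term).
Standard errors are sandwich estimates — cluster-aggregated scores when
cluster ids are supplied, per-record otherwise. Full survey-design Taylor
linearization with strata and finite-population corrections is *not*
implemented: the source design's strata/PSU structure is not available,
point estimates are unaffected by that choice, and cluster-robust sandwich
variance is the standard stand-in. Consequences worth knowing:

* point estimates are invariant to rescaling all weights by a constant,
  and so are robust SEs; model-based SEs are not (both behaviours are
  tested);
* a single-binary-covariate fit reproduces the closed-form 2×2
  cross-product odds ratio exactly;
* reference levels follow the survey convention (age 65–69, male, married,
  high income, employed, college-educated, normal BMI, no risk behaviour,
  no disease) and records missing a model term are dropped listwise with a
  reported count.

## The synthetic cohort generator

The generator is the package's ground-truth instrument, not a data
faithful clone. Diseases are drawn by **latent-Gaussian thresholding**
(Gaussian copula): a latent $Z \sim N(0, R)$ is thresholded at
$\Phi^{-1}(p_j)$ per disease, giving exact marginal prevalences while $R$
controls pairwise dependence. This was chosen over iterative pairwise
odds-ratio fitting because marginals are closed-form, positive
semi-definiteness is easy to diagnose (near-PSD inputs are repaired by
eigenvalue clipping with a warning; repairs that would move an entry by
more than 0.05 are an error), and the pair-level joint probability has an
independent oracle — the bivariate-normal orthant probability — used in
the tests.

The spec of a cohort is over-determined if one demands *both* fixed
per-(sex × HRQoL)-stratum prevalences *and* arbitrary logistic
coefficients linking multimorbidity to poor HRQoL: with stratum-first
sampling the implied category odds ratios follow from the prevalence rows
by Bayes' rule. `generate_cohort()` therefore has two modes, dispatched on
the prevalence matrix:

* **stratified** (6 rows): stratum-first sampling; per-stratum prevalences
  converge to their targets (the defaults are the bundled reference-table
  rates, so descriptive tables, rule tables and networks have realistic
  structure). The HRQoL link coefficients are unused.
* **linked** (2 sex rows): diseases first from sex-level marginals, then
  poor HRQoL assigned by a logistic model in the multimorbidity category
  with log-odds increments `hrqol_link_beta` (default
  $\log(1, 1.47, 1.88, 2.70)$) and a sex-specific intercept calibrated by
  root-finding so the poor fraction hits its target (default 14.2%); good
  HRQoL is then assigned among the non-poor by the mirrored link
  calibrated to the good mass (default 44.9%). Here the category odds
  ratios are true by construction — the recovery target for the
  regression machinery.

The EQ-5D index is a point mass at 1.0 for the good group and a
Beta(5, 1.5) rescaled to $[-0.17, 1)$ — left-skewed, most mass near full
health — truncated to the group's interval otherwise. Survey weights are
log-normal with configurable coefficient of variation (default 0.5, a
moderate dispersion typical of raked survey weights) normalised to mean 1;
the source survey publishes no weight distribution. Covariates are drawn
independently from the survey's overall marginal distributions with ~1%
item missingness to exercise the missing-data paths.

The default latent correlation (`default_latent_corr()`) was calibrated
once, against the reported qualitative co-occurrence structure: a
cardiometabolic block, strong renal–thyroid / cancer–liver /
tuberculosis–asthma / arthritis–depression pairs, and hypertension coupled
slightly more tightly to the block. It reproduces orders of magnitude
(e.g. the female poor-HRQoL strength ranking hypertension > arthritis >
hyperlipidemia > diabetes), not printed third decimals.

What the generator does **not** emulate: multistage cluster sampling
geometry, covariate–disease confounding (covariates are independent by
design, so adjusted and crude simulation estimands coincide), item-level
EQ-5D response patterns, and longitudinal structure. Passing tests
therefore validate the *estimators*, not any claim about real survey
behaviour beyond the bundled printed tables.

## Problem sizes and test design

The suite uses cohorts of $n \approx 10^5$ for law-style checks (marginal
calibration, independence ⇒ all 105 lifts within [0.95, 1.05], odds-ratio
recovery within 3 SE), $n = 12{,}000$ for reference-structure checks, 200
replicates at $n = 5{,}000$ for CI coverage (accepted band [0.91, 0.985]),
and $n \le 500$ for the brute-force oracle equivalence of the rule miner
(50 random cohorts, machine precision). All randomness flows through
per-test fixed seeds; regenerating a cohort from the same configuration is
bit-identical, and the pipeline writes a manifest (config hash, seed,
package version) sufficient to reproduce every table byte-for-byte.

## Known limitations

* The bundled value set is synthetic; results on real data require the
  licensed national tariff.
* Cluster-robust sandwich SEs approximate, but do not equal, full
  survey-design linearized SEs; published survey CIs are context, not
  targets.
* The cross-sectional design of the emulated survey supports association
  statements only — nothing here is causal.
* Rule mining is pairwise by design; higher-order disease clusters are out
  of scope.

## A worked example

```{r example, eval = FALSE}
cfg <- default_sim_config("stratified", n_total = 12000, seed = 42)
cohort <- generate_cohort(cfg)
rules <- top_rules(mine_rules(cohort, stratum_spec("male", "poor")), 20)
net <- build_network(cohort, stratum_spec("female", "poor"))
head(strength_ranking(net), 4)
fit <- regress_poor_hrqol(generate_cohort(
  default_sim_config("linked", n_total = 1e5, seed = 7)),
  c("multimorbidity", "sex"))
fit
```
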