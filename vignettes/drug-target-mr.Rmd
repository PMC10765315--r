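---
title: "Drug-target Mendelian randomization with correlated cis-pQTL instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with correlated cis-pQTL instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(targetmr)
library(dplyr)
```

## The problem

Circulating proteins are attractive drug targets: if genetically predicted
levels of a protein associate with disease risk, the protein's pathway is a
candidate for therapeutic modulation. Two-sample Mendelian randomization
(MR) estimates that association from GWAS summary statistics alone, using
genetic variants as instruments. For proteins, the credible instruments are
*cis*-pQTLs — variants near the encoding gene (here within ±200 kb) that
associate with the protein's plasma level — because their effect on the
protein is most plausibly direct rather than mediated.

The price of restricting to one small region is that the usable variants are
few and correlated through linkage disequilibrium (LD). Every estimator in
this package therefore works on the correlated-instrument generalization of
the familiar machinery, taking the LD correlation matrix $\rho$ as an input.
The motivating application is hypertensive disorders of pregnancy (HDPs):
gestational hypertension and preeclampsia, two related binary outcomes with
large GWAS meta-analyses, screened against a panel of cardiovascular
disease-related plasma proteins.

## The model

For variant $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be the marginal
association with the protein (per SD) and $\hat\beta_{Yj}$ (SE
$\sigma_{Yj}$) the marginal association with the outcome (log-odds). Under
the MR assumptions the instrument–outcome effects satisfy
$\beta_{Yj} \approx \theta\,\beta_{Xj}$ with $\theta$ the causal effect of a
1-SD increase in genetically predicted protein on the outcome log-odds.

With correlated variants the sampling covariance of $\hat\beta_Y$ is
$\Omega_{ij} = \sigma_{Yi}\sigma_{Yj}\rho_{ij}$, and the
inverse-variance-weighted (IVW) estimate is the generalized-least-squares
(GLS) solution

$$\hat\theta = \frac{\hat\beta_X^\top \Omega^{-1} \hat\beta_Y}
                    {\hat\beta_X^\top \Omega^{-1} \hat\beta_X},\qquad
  \mathrm{se}(\hat\theta) = \big(\hat\beta_X^\top \Omega^{-1}
  \hat\beta_X\big)^{-1/2}.$$

With an identity $\rho$ this collapses to the classic
$\sum_j \hat\beta_{Xj}\hat\beta_{Yj}/\sigma_{Yj}^2 \big/ \sum_j
\hat\beta_{Xj}^2/\sigma_{Yj}^2$. The estimator-selection rule mirrors common
cis-MR practice: a single variant uses the Wald ratio
$\hat\beta_Y/\hat\beta_X$ (delta-method SE $\sigma_Y/|\hat\beta_X|$), 2–3
variants use fixed-effect GLS-IVW, and more than three use multiplicative
random effects — the SE is inflated by
$\hat\phi = \sqrt{r^\top\Omega^{-1}r/(J-1)}$ (residuals $r$), floored at 1
so a random-effects analysis never claims more precision than fixed
effects.

### Sensitivity estimators

**MR-Egger** adds a free intercept that absorbs directional horizontal
pleiotropy; the slope remains the causal estimate. Each variant is first
oriented so $\hat\beta_{Xj}\ge 0$. Orientation negates
$(\hat\beta_{Xj},\hat\beta_{Yj})$ jointly, which is a recoding of the
variant's effect allele; the same recoding flips the sign of row and column
$j$ of $\rho$, so the GLS covariance is built from the oriented
correlation matrix. The residual scale is estimated with $J-2$ degrees of
freedom and inference uses the $t_{J-2}$ distribution. We deliberately do
*not* floor the Egger residual scale: with an estimated scale the $t$
statistic is exactly $t_{J-2}$-distributed under the model, and flooring
would make the pleiotropy intercept test conservative (we measured its
size dropping from ~0.05 to ~0.02 under the null in our simulations),
weakening the very diagnostic the estimator exists for. The floor remains
in random-effects IVW, where its purpose is a conservative *interval*, not
a calibrated test.

**Principal-components IVW** addresses near-collinear instruments directly:
it eigendecomposes
$\Phi_{ij} = \hat\beta_{Xi}\hat\beta_{Xj}\rho_{ij}/(\sigma_{Yi}\sigma_{Yj})$,
keeps the smallest number of components explaining at least 99% of the
variance (the `variance_target` default), projects
$\hat\beta_X,\hat\beta_Y,\Omega$ onto them, and runs fixed-effect GLS in
the projected space. With `variance_target = 1` on a full-rank system it
reproduces fixed-effect IVW exactly (a change of basis); with two
near-duplicate variants it keeps one component and approaches the Wald
ratio.

**Steiger filtering** guards against reverse causation at the variant
level: variance explained is computed from the $t$ statistic as
$r^2 = t^2/(t^2 + n - 2)$ per trait, and a variant is removed iff it
explains strictly more variance in the outcome than in the exposure (ties
retained). The $t$-statistic form needs no allele frequencies, which keeps
it usable on the standardized scale of the simulator.

## Instrument construction

From a harmonized ±200 kb cis region, `select_instruments()` applies the
region-wide p-value filter (default $p < 10^{-4}$) and then greedy LD
clumping at $r^2 < 0.4$: variants are processed in ascending exposure
p-value (ties broken by position, then ID, for determinism across
platforms) and kept iff their squared correlation with every already-kept
variant is below the threshold. "No instrument" (no variant passes the p
filter) is a first-class outcome — in the motivating screen only 75 of 90
candidate proteins yielded an instrument — and such proteins are excluded
and logged rather than estimated. Instrument strength is summarized by the
mean per-variant $F_j = (\hat\beta_{Xj}/\sigma_{Xj})^2$; the simulator's
default settings produce mean F well above the conventional weak-instrument
comfort threshold of 10–15.

Harmonization joins exposure and outcome by variant ID, aligns the outcome
to the exposure's effect allele (negating $\hat\beta_Y$ and complementing
the allele frequency when the pair is swapped), drops non-matching allele
pairs with a recorded reason, and — by default — drops palindromic A/T and
C/G variants, whose strand cannot be verified from summary data; the flag
exists because reasonable pipelines differ and the convention in the source
analyses is unknown.

## The pipeline

`run_primary()` maps the rule-based estimator over a protein × outcome
panel and controls the false discovery rate at 5% by Benjamini–Hochberg.
FDR is pooled across both HDP outcomes by default (one decision per screen)
with a per-outcome option, since either reading of "the primary analyses"
is defensible.

`run_sensitivity_battery()` re-runs the analysis over exactly ten
sensitivity settings: IVW at six LD thresholds
($r^2 < 0.001, 0.01, 0.1, 0.2, 0.6, 0.8$), IVW at two stricter instrument
p-value thresholds ($10^{-6}$, $5\times10^{-8}$), PCA-IVW, and MR-Egger
(the latter two on the primary instrument). A grid point whose re-selected
instrument is empty is omitted and recorded rather than silently skipped; a
grid point that collapses to one variant falls back to the Wald ratio per
the selection rule.

`assess_robustness()` grades an association robust iff (1) the primary
analysis is FDR-significant, (2) every sensitivity estimate is
directionally consistent — point-estimate signs only, significance not
required, matching the verbal criterion literally — and (3) the
reverse-direction MR (outcome as exposure, instrumented by caller-supplied
genome-wide significant outcome loci; the pipeline never invents them) has
unadjusted $p > 0.05$.

`phenomewide_scan()` estimates the protein's association with a panel of
phecode-style phenotypes, flags significance at the lenient threshold
$0.05/n_\text{proteins}$ (0.0083 for six prioritized proteins), and
classifies each hit as *beneficial* or *adverse*: beneficial iff moving the
protein in its HDP-risk-lowering direction also lowers the phenotype's
risk. The HDP-protective direction is an explicit input.

## Colocalization

An MR signal can be confounded by LD between distinct causal variants, so
`coloc_posteriors()` tests whether the protein and outcome share a causal
variant. Each variant gets a Wakefield log approximate Bayes factor per
trait ($\log\mathrm{ABF} = \tfrac12\log(1-r) + \tfrac12 r z^2$,
$r = w/(w+V)$), and the five regional hypotheses H0–H4 are enumerated with
per-variant priors $p_1 = p_2 = 10^{-4}$ and $p_{12} = 10^{-5}$, prior
effect SD 0.2 for the quantitative protein and 0.15 for the binary
log-odds — the standard defaults of the enumeration method, exposed in
`coloc_priors()` because the source analyses do not print theirs. All sums
run in log space; a naive-summation oracle confirms the log-sum-exp path on
small instances. PP(H4) > 0.80 is the conventional evidence threshold for
a shared variant, and both the gene-body-only and ±200 kb windows are
supported because the two can genuinely disagree (they do for NT-proBNP in
the motivating analysis).

## Gestational trend meta-regression

The observational arm pools review-style study-level data: per study, mean
protein concentration in the HDP and non-HDP groups at a known gestational
week. The contrast is $\log_{10}(\bar x_\text{HDP}/\bar x_\text{ctrl})$ —
unit-free, so studies on different assays pool — regressed on gestational
week by weighted least squares with weight $n_\text{HDP}+n_\text{ctrl}$
(the caption-level "weighted by each study's sample size", made concrete as
the total; weights matter only up to scale). Inference is $t$-based with
$n-2$ df. Mixed-subtype studies are excluded by default because trends are
subtype-specific; an optional quadratic term probes nonlinearity (its form
is our choice — the source mentions nonlinear models without specifying
them). Studies reporting medians can be accepted under a mean≈median flag,
a known limitation of pooling heterogeneous reports.

## The simulator

`simulate_region_sumstats()` generates the inputs every stage consumes, on
the standardized-genotype, standardized-trait scale
($\mathrm{se} = 1/\sqrt{n}$, allele frequency emitted as a synthetic 0.5
placeholder): AR(1) LD $\rho_{ij} = c^{|i-j|}$; sparse true pQTL effects
$\gamma$ on `n_causal` positions; marginal exposure means $\rho\gamma$ with
$\mathrm{MVN}(0, \rho/n_X)$ noise; outcome means
$\rho(\theta\gamma + \alpha)$ with $\mathrm{MVN}(0, \rho/n_Y)$ noise, where
$\alpha$ are optional direct (pleiotropic) effects. Binary outcomes are
simulated on the linear log-odds approximation — adequate because the
estimators consume marginal beta/SE only. Defaults (50 variants, $c=0.7$,
3 causal pQTLs with effect SD 0.15, $n_X = 20{,}000$, $n_Y = 300{,}000$)
represent a well-powered protein GWAS region against a large binary-outcome
meta-analysis: the exposure cohort size matches the SCALLOP-scale proteomic
meta-analyses and the outcome size the HDP GWAS. The study-table generator
`simulate_observational_studies()` draws 30 studies with lognormal sizes
around 150 participants (~30% HDP), weeks uniform on [6, 40], and log-ratio
noise shrinking as $1/\sqrt{n/100}$; its default intercept $-0.6$ with
slope 0.039/week crosses zero mid-gestation, the early-deficit/late-excess
pattern described for NT-proBNP.

What the simulator does *not* emulate: realistic human LD panels (AR(1) is
smooth and one-dimensional), allele-frequency-dependent power, sample
overlap between the two GWAS, case-control ascertainment, or
between-study heterogeneity in assay calibration. Passing tests therefore
certify the statistical machinery under its stated model, not performance
on any particular real dataset.

## Numerical choices

* **Conditioning.** If the LD matrix's condition number exceeds $10^8$,
  $\rho$ is shrunk toward the identity as $(1-\lambda)\rho + \lambda I$
  with $\lambda = 10^{-6}$, escalating once to $10^{-3}$ before raising an
  error that advises a stricter clumping threshold. For any valid
  correlation matrix of realistic size the escalation succeeds, so exact
  duplicates degrade gracefully toward the single-variant answer.
* **Factorization.** All GLS solves go through the Cholesky factor of
  $\Omega$ (whitening), never an explicit inverse; the tests compare
  against explicit-inversion oracles at $10^{-8}$ relative error.
* **P-values** come from the standard normal for Wald/IVW/PCA-IVW and from
  $t_{J-2}$ for Egger; extreme z-scores are clamped so p stays in (0, 1].
* **Ties.** Clumping ties on p-value break by position then ID; Steiger
  ties (equal variance explained) retain the variant.
* **Reproducibility.** Every simulation takes an explicit integer seed;
  replicate streams use seed + replicate-index offsets.

## Worked example

```{r example}
sim <- simulate_region_sumstats(sim_config(theta = 0.1, seed = 42))
h <- sim_harmonized(sim)
inst <- select_instruments(h)
mr_fit(inst)

prof <- run_sensitivity_battery(h, reverse_p = 0.4)
tidy(prof) |> select(label, method, theta, ci_low, ci_high, p)
assess_robustness(prof, fdr_significant = TRUE)
```

```{r trend}
studies <- simulate_observational_studies(seed = 3)
fit <- fit_weighted_trend(studies)
tidy(fit) |> select(slope, se, ci_low, ci_high, p, n_points)
```

Problem sizes throughout the test-suite and validation scripts (500
replicates for recovery/coverage, 1,000 for estimator-oracle and Egger
calibration checks, 200 for colocalization and trend recovery) were chosen
to bound Monte-Carlo error well inside the asserted tolerance bands while
keeping a full run in the order of a minute.

## Known limitations

* The correlated-instrument GLS assumes the supplied $\rho$ is the true LD
  of the GWAS samples; reference-panel mismatch is not modelled.
* The enumeration colocalization assumes at most one causal variant per
  trait in the region; multi-signal regions need SuSiE-style methods,
  which are out of scope.
* Reverse-direction MR requires caller-supplied outcome instruments.
* The robustness verdict is a reported grade, not an error-controlled
  test; its components (especially directional consistency) are
  deliberately simple sign checks.
* The quadratic gestational-trend term is an optional probe, not a model
  of the true nonlinear trajectory.
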