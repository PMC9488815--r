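---
title: "Methods: two-sample MR of insomnia and pregnancy outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR of insomnia and pregnancy outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insomniamr)
```

## The model

Two-sample Mendelian randomization treats SNPs as instrumental variables
for a lifelong predisposition to insomnia. For SNP $j$ let $\gamma_j$ be
its association with the exposure (here estimated by linear regression of
binary insomnia on dosage, i.e. on the risk-difference scale, or by
logistic regression on the log-odds scale — the tables carry an explicit
scale tag and the estimators refuse to mix scales) and $\Gamma_j$ its
association with a binary pregnancy outcome (log odds ratio from logistic
regression). Under the instrumental-variable assumptions (relevance,
independence from confounders, and effect on the outcome only through the
exposure), each Wald ratio $\hat\Gamma_j/\hat\gamma_j$ estimates the same
causal effect $\theta$, reported as an odds ratio per one unit higher
log-odds (or unit risk) of insomnia.

The three estimators the package implements differ in how they pool the
ratios and in which violations they tolerate:

* **IVW** is the weighted regression of $\hat\Gamma$ on $\hat\gamma$
  through the origin with weights $w_j = 1/\mathrm{se}(\hat\Gamma_j)^2$.
  It is efficient but biased by any unbalanced (directional) horizontal
  pleiotropy. The fixed-effect SE is $(\sum_j w_j\hat\gamma_j^2)^{-1/2}$;
  the default multiplicative random-effects variant inflates it by
  $\max\{1, \sqrt{Q/(k-1)}\}$, which is the correct heterogeneity model
  when the extra between-SNP variation scales with the sampling variance.
  Both variants are always co-reported.
* **MR-Egger** frees the intercept; under the InSIDE assumption
  (pleiotropic effects independent of instrument strength) the intercept
  estimates the mean directional pleiotropic effect and the slope is a
  corrected estimate of $\theta$. Its residual scale is floored at 1
  (same multiplicative model) and inference uses $t_{k-2}$. The exposure
  is oriented so all $\hat\gamma_j \ge 0$ first; orientation flips both
  betas (and complements both EAFs), which leaves every Wald ratio
  unchanged.
* **The weighted median** of the Wald ratios is consistent while invalid
  instruments carry less than half the total weight. The estimate
  interpolates the cumulative-weight midpoints $p_j = \sum_{i\le j} w_i -
  w_j/2$ at $p = 0.5$; the SE is the standard deviation over seeded
  parametric-bootstrap replicates that redraw $\hat\gamma^*$ and
  $\hat\Gamma^*$ from normal distributions at the reported SEs
  (1000 replicates by default; the SNP set is sorted by rsid before
  drawing so the result is invariant to input order).

## Preparation of summary statistics

Harmonization aligns each SNP to the exposure's effect allele: swapped
records have the outcome beta negated and EAF complemented. Palindromic
(A/T, C/G) SNPs cannot be strand-resolved from alleles alone: they are
excluded when the exposure EAF lies in (0.42, 0.58) and otherwise
oriented by frequency agreement. The window (configurable,
`palindromic_eaf_window = 0.08`) follows common two-sample MR practice;
nothing in the source analyses pins it down, so it is this package's
choice. LD pruning is greedy at $r^2 \ge 0.01$: repeatedly keep the
remaining SNP with the smallest p-value and drop everything correlated
with it, ties broken by rsid so the result is order-independent. The MAF
filter removes SNPs with $\min(f, 1-f)$ below 1% by default (the rule
that excluded two SNPs from the smallest birth cohort), applied per study
before harmonization.

## Diagnostics

Cochran's $Q = \sum_j w_j(\hat\beta_j - \hat\beta_{\mathrm{IVW}})^2$ over
Wald ratios (chi-square, $k-1$ df) and leave-one-SNP-out flag pleiotropic
outliers. Steiger filtering guards against reverse causation: per SNP the
variance explained in exposure and outcome is compared via Fisher-z,
$z = (\operatorname{atanh} r_{\mathrm{exp}} - \operatorname{atanh}
r_{\mathrm{out}})/\sqrt{1/(n_{\mathrm{exp}}-3) + 1/(n_{\mathrm{out}}-3)}$,
and a SNP is removed iff $r^2_{\mathrm{out}} > r^2_{\mathrm{exp}}$ with
$p < 0.05$. For log-odds betas the variance explained is computed on the
latent logistic scale, $r^2 = \beta^2 2f(1-f) / (\beta^2 2f(1-f) +
\pi^2/3)$ — chosen because it needs only summary data; an observed-scale
formula ($\beta^2 2f(1-f)/(p(1-p))$ given a prevalence, or a unit trait
variance for continuous traits) sits behind the same interface. The two
samples are treated as independent, which the split design guarantees by
construction. Instrument strength is reported as per-SNP $F =
(\beta/\mathrm{se})^2$ and $r^2 = \beta^2 2f(1-f)/\mathrm{Var}(X)$;
`mean_f_from_r2()` gives the aggregate-level identity $F \approx r^2(n-2)
/(1-r^2)$ used when only totals are published.

## Individual-level stages

Per-SNP association fits are complete-case regressions of trait on dosage
plus covariates. Linear scans use one QR residualization of trait and
dosages on the covariates (Frisch–Waugh–Lovell), which reproduces the
per-SNP `lm()` fits exactly and makes 81-SNP scans on 50,000-row cohorts
cheap. Logistic fits use IRLS with deviance tolerance `1e-10` and at most
100 iterations; non-convergence is flagged and the record dropped with a
warning rather than silently reported. Reported CIs are estimate ±
1.96·se throughout.

The split cross-over design halves a cohort at random (simple 50/50 by
seed, unstratified), estimates SNP-exposure associations in half A and
SNP-outcome associations in half B (and vice versa), runs IVW both ways
and pools the two cross-estimates by fixed-effects meta-analysis; the
combined estimate is that meta-analysis *by construction*, an identity
the tests assert exactly. The split is refused when either half has fewer
than 10 outcome cases. Where women contribute several pregnancies, one is
selected uniformly at random per woman under a seed.

The multivariable comparator is plain logistic regression of each outcome
on in-pregnancy insomnia, crude and adjusted for the measured confounder
block, each on its own complete cases (so adjusted n ≤ crude n), with
quasi-separation flagged. Characteristic tables print mean (SD) for
continuous variables, N (%) of the total column N for categorical levels,
and cases/controls with prevalence $100\,\mathrm{cases}/(\mathrm{cases}+
\mathrm{controls})$, all rounded half-up to one decimal — the convention
that makes the printed cells (e.g. 42,717/139,034 → 23.5) reproduce
exactly.

## Cross-study combination

Study-level estimates are pooled on the log-OR scale by fixed-effects
inverse variance weighting (ORs are presentation-layer), with
between-study Q and leave-one-study-out, optionally restricted to a named
subset of studies. SNP-level pooling of association tables
(`pool_snp_associations()`) is provided for combining the smaller cohorts
before MR, mirroring a two-stage pooling in which a split-sample combined
estimate enters the final meta-analysis as a single study. The pipeline
accepts a YAML config, derives one child seed per (outcome, study) cell
from the global seed, records every seed and threshold in `run.log` and a
manifest, sorts studies by name so results are order-invariant, and
continues past a failing outcome while recording the failure.

## The synthetic-data generator

The generator stands in for access-restricted cohort data. It emulates:
~81 independent biallelic instruments with small effects on a binary
(liability/logistic) exposure of 28% prevalence; binary outcomes of
configurable prevalence (default 5%); a causal log-odds effect $\theta$;
balanced ($d_j \sim N(0,\sigma^2)$) or directional ($d_j \sim N(\mu,
\sigma^2)$ for a proportion of invalid instruments) horizontal
pleiotropy; a shared standard-normal confounder with configurable
loadings; and fetal genotypes by Mendelian transmission (one maternal
allele plus a population-frequency paternal allele, giving the expected
maternal–fetal dosage correlation of 0.5). Default instrument strength is
a total $r^2$ of 0.42% — the published aggregate for the insomnia
instruments, implying a mean F near 11 at UKB scale. The total $r^2$ is
split across SNPs with squared-uniform shares: GWAS lead-SNP effects are
heterogeneous, and with near-equal exposure effects the Egger slope is
close to unidentified (the limiting case of all-equal effects is a
collinearity error), so an equal-share design would be both unrealistic
and diagnostically degenerate. Logistic intercepts are solved by
bisection to a prevalence error below 1e-4. Identical config + seed gives
byte-identical output; one global seed expands into per-stage child seeds
via `child_seeds()`.

What the generator does **not** emulate: LD between instruments (they are
independent, as after pruning), assortative mating, selection into the
cohorts, misclassification of self-reported insomnia, and SAIGE-style
mixed-model association (plain logistic regression stands in for it).
Passing tests therefore show the machinery is correct under the assumed
causal structure, not that those real-data complications are handled.

## Reference study conditions for the simulation checks

The simulation studies shipped with the package run at fixed, documented
sizes:

* **Parameter recovery** (`mr_recovery_study()`): 200 replicates, each
  drawing one architecture and two *independent* 50,000-woman samples
  from it (exposure associations from one, outcome associations from the
  other — the two-sample design), continuous exposure and outcome so the
  estimand equals $\theta = 0.3$ without non-collapsibility. Instrument
  strength is set to a total $r^2$ of 5% (a strongly instrumented
  continuous exposure, mean F ≈ $n r^2/k \approx 31$): two-sample IVW is
  attenuated by roughly $S/(S+k)$ with $S = n r^2$, so at 0.42% the
  attenuation alone (~0.11 of $\theta$) would swamp any bias criterion,
  while at 5% it is second-order (~0.01). The pleiotropy variant uses 30%
  invalid instruments with $d_j \sim N(0.01, 0.002^2)$, under which IVW
  is visibly biased, the weighted median markedly less so, and the Egger
  intercept estimates the mean direct effect $0.3 \times 0.01 = 0.003$.
* **Null calibration** (`mr_null_calibration()`): 1000 summary-level
  replicates at $\theta = 0$ with balanced pleiotropy $\sigma = 0.01$,
  81 instruments at the 0.42% strength, reported SEs 0.0016 (exposure,
  risk-difference scale) and 0.05 (outcome, log-odds) — magnitudes
  matching large-biobank association tables. Equal outcome SEs make the
  multiplicative heterogeneity model exact, so the default IVW test
  should reject at close to 5%.
* **Regression coverage** (`mvreg_coverage_study()`): 400 cohorts of
  1500 women, binary exposure (28%) with no effect on a binary outcome
  (15%) and no confounding; the adjusted 95% CI should cover the null OR
  at close to 95% (judged against a 3-SD binomial band).

These sizes are the package's reference conditions; the vignette states
them so that any reproduction uses the same ones.

## Numerical choices

* CIs use the conventional 1.96 multiplier on the log-OR scale
  (Wald-type; profile intervals are not used anywhere).
* IVW/median p-values are normal, Egger's are $t_{k-2}$.
* Wald-ratio SEs are first-order delta method by default
  ($\mathrm{se}(\hat\Gamma)/|\hat\gamma|$); the second-order form is
  available and affects only the median's weights.
* LD-pruning ties on p-value break by rsid; the weighted median sorts by
  rsid before bootstrap draws; pipeline studies are processed in name
  order — all so that results never depend on input order.
* Degenerate inputs error early with typed conditions: se ≤ 0, duplicate
  or missing rsids, empty harmonization intersections, all-equal
  exposure betas in Egger (collinear), zero-variance dosages,
  unattainable simulated prevalences.
* Bisection tolerances: 1e-10 on the intercept bracket, 1e-4 on realized
  prevalence. Logistic IRLS: deviance tolerance 1e-10, 100 iterations.

## Known limitations

* With a binary exposure the MR estimand is "per unit higher log-odds of
  insomnia" and is attenuated by non-collapsibility; recovery checks
  therefore use the continuous-exposure mode, and binary-mode runs should
  be read as direction/scale-consistency checks, not unbiased recovery.
* Steiger filtering inherits the latent-scale $r^2$ approximation and is
  sensitive to measurement error in either trait.
* Reproduction of the published pooled odds ratios (miscarriage 1.60,
  perinatal depression 3.56, low birthweight 3.17) requires the
  per-source estimate tables from the journal supplement, which are
  access-gated and not redistributed; the corresponding check runs only
  when a user supplies `inst/extdata/supplementary/
  per_source_mr_estimates.tsv` (columns `outcome`, `study`, `beta`,
  `se`). The aggregate mean-F figure is reproduced from printed totals
  instead.
* No multiple-testing correction is applied across outcomes, matching
  the source analysis; mode-based estimators, multivariable MR and
  random-effects cross-study models are out of scope.
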