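---
title: "Correcting volunteer bias in association scans: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting volunteer bias in association scans: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large genotyped cohorts recruit volunteers, and volunteers differ
systematically from the population that was invited: they tend to be
healthier, better educated and older. An association scan run on such a
cohort estimates the SNP-phenotype relationship *among people who chose to
participate*, not in the sampling population. Two selection mechanisms
matter:

* **Phenotype-related selection.** If the probability of participating
  depends on the phenotype, per-SNP regression slopes are attenuated
  towards zero. Effects look smaller than they are, some true loci fall
  below the significance threshold, and SNP heritability — which
  aggregates squared effects genome-wide — is underestimated.
* **Phenotype-genotype-related (collider) selection.** If participation
  depends on both a genotype and the phenotype, conditioning on
  participation opens a non-causal path between them. A SNP with no effect
  can show a spurious association, and true effects can be shifted or even
  sign-flipped.

The correction implemented here is inverse-probability weighting (IPW):
estimate each participant's probability of participation from variables
observed in both the cohort and a population-representative reference
(census-style) sample, weight each participant by the reciprocal of that
probability, and rerun every downstream analysis weighted. The weighted
scan (WGWAS) estimates the association that would have been obtained in
the sampling population, at the price of a larger standard error.

## The estimators

**Participation model.** Participation is modelled by a probit regression
of the participation indicator on categorical predictors, expanded into
all one-hot main effects plus all two-way interactions, with an L1
(lasso) penalty to keep the interaction-rich design from overfitting. The
penalty is chosen by 5-fold cross-validated deviance, a standard default
the methodology itself does not pin down. The solver is a
proximal-gradient (FISTA) iteration on the penalised probit
log-likelihood; the unpenalised limit is checked against
`glm(family = binomial("probit"))` in the test suite. A logit link is
available as an option.

**Weights.** Raw weights are `1 / p_hat`. To limit the influence of
estimation noise in tiny probabilities they are winsorised at the 1st and
99th percentiles of the raw-weight distribution (linear-interpolation
percentiles; conventions differ and this one is documented). Because
every downstream statistic is invariant to a positive scale factor, the
winsorised weights are rescaled to mean one purely for interpretability.
Whether the original methodology renormalised after winsorisation is not
stated anywhere; mean-one is this package's choice.

**Association scans.** The phenotype is first residualised on the
confounder set (an auxiliary regression on sex, principal components,
batch, birth-cohort dummies, or whatever the analyst supplies); the
weighted scan residualises with the same weights. Each SNP is then fitted
in `y_tilde = alpha + beta * SNP` by least squares — weighted or not —
with White (HC0) heteroskedasticity-robust standard errors and two-sided
normal p-values. The unweighted scan is implemented as the unit-weight
special case of the same arithmetic, which makes the equal-weight
equivalence (`w` constant implies bit-identical output) structural rather
than approximate. Missing genotypes are dropped pairwise per SNP, the
residualisation being done once on the full sample, matching the per-SNP
`n` of standard GWAS tools. An HC1 small-sample factor exists behind a
flag but is off by default, since the reference methodology specifies
White's estimator.

**Per-SNP comparison.** The Hausman statistic
`H = (b_g - b_w)^2 / (se_w^2 - se_g^2)` contrasts the efficient-under-
the-null unweighted estimator with the consistent-under-selection
weighted one; under the null it is chi-squared with one degree of
freedom. The denominator is implemented as weighted-minus-unweighted
variance — the only orientation that is positive when the weighted scan
is the noisier one, which it always is in practice. Where the variance
difference is non-positive the SNP is flagged invalid and its p-value
left missing rather than clamped.

**Effective sample size.** Per SNP,
`N_eff = sigma2_y / (SE^2 * 2 * MAF * (1 - MAF))`: the size of a simple
random sample that would have produced the observed standard error. The
`sigma2_y` used is the (weighted) variance of the *residualised*
phenotype — the variable the per-SNP model actually fits. With the raw
phenotype variance instead, the unweighted scan's `N_eff/n` would exceed
one by exactly the share of variance the covariates explain, breaking the
estimator's calibration; the reference text does not say which variance
it used, and this choice is the internally consistent one.

**Clumping, top-hit slope, novel loci.** Clumping is the standard greedy
PLINK procedure (sort significant SNPs by p, absorb neighbours within the
physical window with `r^2` at or above the threshold; secondary p
threshold 1; ties broken by chromosome, position, SNP id). The top-hit
slope regresses weighted on unweighted effect sizes over a supplied SNP
set with an intercept and equal SNP weighting, testing slope = 1 by a
two-sided t test. A locus counts as discovered-only-by-weighting when its
weighted-scan clump index is genome-wide significant in the weighted
scan, insignificant in the unweighted one, and the Hausman p for the
difference is itself genome-wide significant.

**LD-score regression.** LD scores sum squared allele-count correlations
within a 1,000 kb window (inclusive, same chromosome, self included),
with the small-sample correction `r2 - (1 - r2)/(n - 2)` floored at zero
per pair. Heritability is the slope of `chi2` on `N_eff * l / M` by
weighted least squares with a free intercept — weights `1/max(l, 1)`,
updated once by the heteroskedasticity factor `1/(2 * fitted^2)` — and
delete-one jackknife standard errors over contiguous SNP blocks (200 by
default, reducible for small panels). The cross-scan regression of
`z_1 * z_2` on `sqrt(N_1 N_2) * l / M` gives the genetic covariance; its
intercept estimates the correlation of the two scans' estimation errors
and enters the heritability-difference test
`Z = (h2_g - h2_w) / sqrt(se_g^2 + se_w^2 - 2 * cov)`, with
`cov = intercept * se_g * se_w` and the intercept clamped to `[-1, 1]`.
The difference-test denominator uses variances (squared standard errors),
the only dimensionally consistent form. Heritabilities are reported on
the observed scale throughout; no liability transformation is offered.
`M` is the number of SNPs in the regression.

## What the synthetic cohorts emulate

The generator exists so that every stage can be exercised, and its claims
tested, without access-restricted data.

* **Genotypes.** SNPs live in contiguous blocks. Within a block each
  haplotype allele copies a block-level ancestral allele with probability
  `sqrt(rho)` and is drawn fresh otherwise, so any two SNPs of a block
  have genotype correlation exactly `rho` whatever the allele frequency
  — the reason this construction was preferred over a Gaussian copula,
  whose genotype-scale correlation decays with MAF. Blocks are
  independent, block allele frequencies are uniform on the requested
  range, and a per-block correlation *range* can be requested: LD-score
  regression needs across-genome variation in LD to identify its slope,
  and a constant-correlation genome has almost none.
* **Phenotype.** `y = genotype effects + covariate effects + noise`, with
  causal SNPs drawn uniformly among SNPs with MAF at least 0.05, effects
  rescaled so the realised genetic variance share equals `h2` exactly,
  genotypes centred at twice the allele frequency so allele coding cannot
  leak into the intercept, and a covariate block (five categorical
  variables: sex, birth cohort, region, education, self-rated health)
  whose realised variance equals `covariate_effect_sd^2` (default 0.2,
  i.e. 4% of variance — covariates matter but do not dominate).
* **Participation.** `p = link(intercept + coef_y * z(y) + coef_g * g +
  covariate effects)`, probit link by default, intercept calibrated by
  root finding so the mean participation probability hits the target rate
  (default 5.45%, the acceptance rate of the UK Biobank invitation).
  The three scenario kinds — random, phenotype, phenotype-genotype —
  correspond to no bias, attenuation bias and collider bias.
* **Outcome proxy for weight estimation.** Real census-shared weighting
  variables (self-rated health, education) are themselves noisy,
  coarsened phenotypes — that is what lets covariate-based weights
  capture phenotype-related selection at all. The pipeline emulates this:
  when selection acts on the phenotype and weights are estimated, a
  binned noisy transform of the phenotype (default reliability 0.7, five
  bins) joins the participation-model covariates, available for the
  whole population like any register variable. Without it,
  covariate-only weights are nearly constant under pure phenotype
  selection and correct nothing, which is the omitted-variable caveat
  real IP weights carry too; with it the pipeline's weighted scan
  recovers most of the attenuation while the oracle-weight arm defines
  the ceiling.
* Each simulation function draws from its own salted RNG stream, so
  nearby user seeds passed to different functions can never alias into
  correlated draws (participation indistinguishable from a covariate
  column, for example, which a shared stream can produce silently).

What the generator does *not* emulate: realistic human LD maps and
recombination, ancestry structure and its principal components,
relatedness, X chromosome, genotyping error or imputation uncertainty.
Passing tests therefore demonstrate the estimators' statistical
behaviour under the assumed selection models, not robustness to
population structure or data artefacts.

## Numerical choices and degenerate inputs

* The Hardy-Weinberg QC test is the exact conditional (enumeration) test,
  not the chi-square approximation, which misbehaves at low MAF; the
  recursion works on log-probabilities and the p-value sums
  configurations no more probable than the observed one (with the usual
  `1 + 1e-7` tie guard).
* QC order is individuals first (call rate, then heterozygosity within
  mean plus/minus 3 SD computed on SNPs passing a provisional MAF
  screen), then SNPs (MAF, HWE, missingness) on the retained sample.
* Monomorphic SNPs yield `NA` with a reason code, never a silent zero.
* Winsorisation bounds are reported on the same scale as the returned
  weights; with constant input probabilities winsorisation is a no-op
  and the normalised weights are exactly one.
* In `ldsc_h2` a constant chi-square input gives slope 0 and intercept 1
  exactly, with a degenerate zero jackknife spread.
* Identical heritability estimates with a clamped cross-intercept of 1
  have a zero-variance difference; this returns `Z = 0, p = 1` rather
  than the error reserved for genuinely contradictory inputs.
* Intercept calibration for participation fails loudly if the target
  rate cannot be bracketed on the link scale within [-20, 20].

## Scales used by the shipped experiments

The test-suite experiments run at desk scale, chosen so each property is
measurable with comfortable Monte-Carlo margins: attenuation/recovery at
a population of 100,000 with 250 SNPs (200 causal) over ten seeds;
Hausman calibration on 10,000 null SNPs in a population of 8,000 with
covariate-driven selection and estimated weights; the heritability
replicates at 20,000 individuals and 1,000 SNPs with moderate phenotype
selection and an oracle-weighted comparison arm. The attenuation
experiment uses a covariate-free phenotype so that the only systematic
difference between the scans is the selection mechanism itself. Because
per-replicate LD-score-regression noise at desk-scale panels (about 0.1
on the heritability scale) is comparable to the attenuation gap it
measures, the weighted-closer-to-truth claim is assessed on the
replicate-averaged estimates, while the direction claim (weighted above
unweighted) is a per-replicate sign test.

## Known limitations

* With strongly varying weights and modest effective sample sizes the
  weighted scan inherits the small-sample behaviour of HC0 sandwich
  errors (slightly anti-conservative), and IPW least squares carries an
  O(1/n_eff) ratio bias — a contraction of a few percent of the effect
  size at effective sample sizes in the low thousands. This is a
  property of the estimator, not of the implementation; it vanishes as
  the effective sample grows and is visible only because the simulated
  truth is known exactly.
* The Hausman variance difference can be negative for a minority of SNPs
  by sampling noise; such SNPs are reported invalid rather than forced.
* LD-score regression at a few hundred SNPs is noisy; the shipped
  defaults reduce the jackknife block count accordingly, and
  single-panel heritability estimates should be read with their
  jackknife intervals, not as point values.
* Mixed-model association (for cryptic relatedness) and binary-trait
  logistic scans are out of scope; the weighted estimator here is
  weighted least squares on a quantitative (or 0/1-coded) phenotype.
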