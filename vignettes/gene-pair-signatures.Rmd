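---
title: "Rank-based gene-pair signatures: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair signatures: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irgpairs)
```

## The model

Cross-platform transcriptomic prognosis models fail most often at
normalization: absolute expression values from RNA-seq counts and microarray
intensities are not comparable, and between-cohort batch correction is
impossible when the validation cohort arrives later or from another
laboratory. The gene-pair approach sidesteps the problem by using only
within-sample ranks. For a pair of genes $(a, b)$ and sample $s$, the
feature is the indicator

$$ I_{ab}(s) = \mathbf{1}\{x_{a s} > x_{b s} \}, $$

and a patient's risk score under a signature of $K$ pairs with Cox
coefficients $\beta_k$ is

$$ \mathrm{score}(s) = \sum_{k=1}^{K} \beta_k \, I_{a_k b_k}(s). $$

Any strictly increasing per-sample transform of the expression values —
scaling, log transforms, per-sample quantile distortions, platform response
curves — leaves every $I_{ab}(s)$ and hence every score unchanged. This is
the package's headline invariant and is enforced bit-for-bit in the test
suite over multiple transform families. The invariance holds for monotone
distortions only; the generator includes a deliberately non-monotone
"broken" mode that demonstrates the failure case (e.g. a saturating sensor
folding high values back down).

Ties score 0, by the "otherwise" reading of the scoring rule. This matters
in practice: RNA-seq zero counts make ties common, and under heavy ties the
complement identity $I_{ab} = 1 - I_{ba}$ no longer holds, so downstream
consumers should not assume antisymmetry unless the data are tie-free.

Pairs are unordered with a single canonical direction given by the input
row order. The reverse direction is the complement and would add a
perfectly collinear column to the penalized regression, so it is never
generated.

## The filter cascade

1. **Gene-list intersection** (optional): restrict to an immune-related
   list, e.g. the ImmPort catalogue of ~2,500 genes. The intersection size
   is logged, not asserted — it is cohort- and platform-specific.
2. **MAD filter**: keep genes whose median absolute deviation (median of
   absolute deviations from the median, *no* 1.4826 consistency constant)
   is strictly greater than 0.5. A gene at exactly 0.5 is removed. The
   threshold was published for intensity-scale data without a stated
   scale; for counts the package offers `scale = "log2"` (MAD computed on
   `log2(x+1)`), with the native scale as the default.
3. **Pair binarization**: all $G(G-1)/2$ pairs.
4. **Prevalence filter**: a pair is kept only when its minority state
   occurs in at least 20% of samples; "less than 20%" is read literally,
   so exactly 20% survives. The published rule says "discard the gene" but
   the context is unambiguous that the *pair* is the unit; the package
   filters pairs.

Whether the MAD filter preceded or followed the gene-list intersection in
the original workflow is unstated; the pipeline applies the intersection
first (a cheaper and more reproducible order, since the MAD set depends on
the cohort), and both functions are exported so callers can swap the order.

## Stability selection

"1,000 iterations" of LASSO admits several readings (bootstrap, repeated
cross-validation, repeated penalty paths). The package implements it as
stability selection: each iteration subsamples 80% of patients without
replacement, fits an L1-penalized Cox model (`glmnet`, partial-likelihood
deviance, 5-fold internal cross-validation for the penalty, Breslow ties),
and records which pairs receive nonzero coefficients at `lambda.min`. A
pair's *frequency* is the fraction of iterations selecting it. The default
selection rule is frequency ≥ 0.5; the published work reports "highest
frequency" pairs without a threshold, and its choice of exactly 22 pairs is
not reconstructible, so the bundled 22-pair signature ships as a fixture
rather than being re-derived. A subsample is redrawn when it contains fewer
events than cross-validation folds (each fold needs an event for the
partial likelihood to exist), a slightly stronger condition than "no
events".

Final coefficients come from a single penalized fit on the full training
data restricted to the selected pairs, at the cross-validation-optimal
penalty; exact zeros are dropped. The published coefficients' shrunken
magnitudes indicate they are LASSO-scale, which this matches. With a single
selected pair the penalized path is undefined (`glmnet` needs two columns)
and an unpenalized Cox fit is used instead.

Randomness is controlled by one master seed from which per-iteration seeds
are derived; identical seed and inputs give bit-identical results.

## Survival evaluation

**Time-dependent ROC.** The cutoff between high- and low-risk patients is
chosen by a cumulative/dynamic ROC at 36 months (validation AUC uses 60
months). Cases are patients with an event by the horizon, controls those
known to survive past it. A patient censored at $c$ before the horizon is
split between the classes by the Kaplan–Meier conditional survival:
control mass $S(t)/S(c)$, case mass $1 - S(t)/S(c)$ (redistribution to the
right). Sensitivity and specificity are then a weighted binary ROC, which
(i) reduces exactly to the empirical ROC when no censoring occurs before
the horizon, (ii) is monotone along the threshold grid by construction —
the classic subgroup-KM estimator is not — and (iii) needs no bandwidth,
keeping results deterministic. The optimal cutoff maximizes the Youden
index; ties break toward the lower cutoff, which yields the larger
high-risk group. Whether the published cutoff used Youden is unstated; the
printed sensitivity/specificity pair is consistent with it.

**Kaplan–Meier, log-rank, Cox.** These are standard steps and are delegated
to the survival package (`survfit`, `survdiff`, `coxph` with Breslow ties);
the tests verify them against closed forms and a hand-tallied
hypergeometric log-rank example rather than trusting either route alone.
Confidence intervals are Wald, matching forest-plot convention. No
multiple-testing correction is applied anywhere: the upstream analyses
report raw p-values, and this package follows that (documented limitation).

Times are canonicalized to months on ingestion (1 year = 12 months,
1 month = 30.44 days) because the method mixes 3- and 5-year horizons with
cohorts whose native units differ. Rows missing time or status are dropped
with a reported count; missing categorical covariates are retained as an
explicit "Missing" level in the cohort table.

## Immune-fraction association

The original analysis used CIBERSORT (ν-support-vector regression with a
proprietary leukocyte signature matrix and permutation p-values). That
pipeline is out of scope here; the package provides a non-negative
least-squares deconvolution against a user-supplied basis matrix as a
methodological substitute, and the association functions accept externally
computed fraction tables (including genuine CIBERSORT output) for parity.
Group differences use the two-sided Wilcoxon rank-sum test (the published
figures star p-values without naming a test; rank-sum is the conservative
default for bounded, skewed fractions), and score associations use Pearson
correlation as published.

## The synthetic-cohort generator

`simulateCohort()` emulates the statistical structure the analysis relies
on, not the biology of any real cohort:

- latent per-gene Gaussian log-expression; informative pairs chosen so
  their indicator prevalence is in [0.25, 0.75] (a pair whose indicator is
  nearly constant carries no signal and could never be selected);
- survival from a Cox–Weibull model, baseline shape 1.2 (so the hazard is
  non-constant and a proportional-hazards fit is non-trivial but correctly
  specified), scale 60 months; linear predictor
  $\sum \beta_k I_k$ with default $|\beta_k| = 1$;
- independent exponential censoring with the rate solved numerically
  against the realized event times for a target censored fraction
  (default 30%);
- observed expression = per-sample strictly increasing distortion of the
  latent values (exponential, power or affine families), standing in for
  platform/normalization heterogeneity. `simulateTwoPlatform()` sends two
  independent cohorts from one population through different families and
  adds platform-private genes, mimicking a training/validation split
  across technologies.

What the generator does *not* model — and what passing tests therefore do
not establish about real data: negative-binomial count noise and
library-size effects, gene–gene correlation beyond the planted pairs,
informative censoring, cohort-level confounding between covariates and
expression. The covariates (age, gender, T/N/M stage, grade, with ~3%
missingness) are drawn independently of survival and exist to exercise the
table and Cox machinery, not to plant covariate effects.

`simulateImmune()` builds a marker-block basis, draws Dirichlet fractions,
and exponentially tilts selected cell types until their fraction attains a
planted Pearson correlation with the risk score (calibrated by root
finding; because renormalization couples the types, the calibration sweeps
the planted types three times). Correlations beyond |r| = 0.8 are refused
rather than silently under-delivered.

## Numerical and design notes

- Degenerate inputs error early with named offenders: non-numeric cells,
  duplicate sample ids, empty gene-list intersections, signature genes
  absent from a matrix, rank-deficient basis matrices.
- `assignGroups` sends scores exactly at the cutoff to the low-risk group,
  consistent with the strict inequality in the ROC positivity rule.
- The risk score is linear in the coefficients and resolvable against
  reversed pair storage via the complement rule; both are property-tested.
- Test and acceptance problem sizes (n = 300 training cohorts, 100
  candidate pairs, 200 stability iterations, 10 held-out and 20 null
  replicates, n = 1000 calibration cohorts) were chosen as the smallest
  sizes at which the planted-signal recovery and calibration behaviour is
  stable across seeds; the user-facing defaults keep the published values
  (1000 iterations, MAD 0.5, prevalence 0.20, horizons 36/60 months).

## Known limitations

- Tie-heavy data (sparse counts) weaken pairs' information content; the
  prevalence filter removes the worst cases but no tie-specific correction
  is applied.
- Stability-selection frequencies depend on the subsample fraction and the
  penalty-selection rule; the defaults are sensible, not canonical.
- The NNLS deconvolution ignores the noise model and marker weighting of
  ν-SVR deconvolution; with a poorly conditioned basis its fractions are
  less robust.
- Published cohort-level results (hazard ratios near 4, validation AUCs of
  0.765/0.905) depend on the original TCGA/GEO cohorts and are not
  reproduced here; the package demonstrates the method's properties on
  synthetic cohorts and ships the published signature for application to
  real data.
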