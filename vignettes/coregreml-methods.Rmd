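---
title: "Estimating covariance between random effects in multi-kernel mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating covariance between random effects in multi-kernel mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Multi-kernel linear mixed models partition the variance of a quantitative
trait across components — functional genomic regions, the genome and an
imputed transcriptome, omic layers in general. Writing `y = Xb + sum_i g_i +
e` with `g_i ~ N(0, K_i s2_i)` and `e ~ N(0, I s2_e)`, the classic (GREML)
analysis assumes the `g_i` are mutually independent, so

    var(y) = sum_i K_i s2_i + I s2_e.

When random effects are in fact correlated — regulatory regions and DNase I
hypersensitivity sites sharing pathways, genomic effects overlapping with
effects of genotype-imputed expression — this assumption biases every
variance estimate. The generalized model fitted here (CORE GREML) frees the
covariance between each pair of random effects. A covariance `s_ij` between
effects living on kernels `K_i` and `K_j` contributes the symmetrized
Cholesky-root cross-term

    B_ij = sqrt(K_i) sqrt(K_j)' + (sqrt(K_i) sqrt(K_j)')'

so that

    var(y) = sum_i K_i s2_i + sum_(i<j) B_ij s_ij + I s2_e.

`sqrt(K)` is the lower Cholesky factor; `B_ii = 2 K_i`, which is why total
phenotypic variance counts every covariance twice:
`s2_y = sum_i s2_i + 2 sum_(i<j) s_ij + s2_e`. Covariances are
sign-unrestricted; the feasible region is bounded only by positive
definiteness of `var(y)`. The covariance between any genetic component and
the residual is representable in the same way (kernel `I`) but is off by
default, as in standard practice.

## Kernels

- `build_grm()`: `A = W W'/m` over genotypes standardized per SNP as
  `(x - 2f)/sqrt(2f(1-f))`. The mean diagonal equals 1 only in
  Hardy-Weinberg expectation, so the container's mean-diagonal check is a
  loose warning (default tolerance 0.05), not a correction.
- `build_trm()`: `T = Q Q'/p` over expression columns standardized by their
  realized (divisor-n) SD; the mean diagonal is exactly 1. Gene-by-tissue
  combinations are distinct columns; nothing is averaged across tissues.
- `build_weighted_grm()`: `K = W diag(v) W'/sum(v)` with per-SNP weights
  `v_i = w_i^gamma [f_i(1-f_i)]^(1+alpha)` applied to MAF-standardized
  genotypes, i.e. `v_i` is the expected share of genetic variance that SNP i
  contributes. `alpha = -1, gamma = 0` (all weights equal) reproduces
  `build_grm()` exactly — the equal-contribution (GCTA) architecture —
  which is why normalization is by `sum(v)` rather than by the realized
  trace (a `normalize = "trace"` option exists). `alpha = -0.25` is the
  LDAK-recommended default. LD scores `w_i >= 1` are computed by
  `compute_ld_scores()` as 1 plus the sum of squared correlations within a
  symmetric window (default ±100 positions); any monotone local-LD proxy
  serves the purpose, and this is the simplest reproducible one.
- `cholesky_root()` adds jitter only on factorization failure, escalating
  through 1e-10 … 1e-4 times the mean diagonal, and records the jitter used.

## Fitting

`fit_reml()` maximizes the restricted likelihood
`logL = -1/2 [ln|V| + ln|X'V^-1 X| + y'Py]` by average-information (AI)
REML. Numerical contract: one Cholesky factorization of `V` per likelihood
evaluation; determinants and quadratic forms come from the factor; the
explicit inverse is formed once per accepted iteration for the derivative
traces (`tr(P dV_r)`), never for the likelihood itself.

- Initialization splits `var(y)` evenly across components and residual,
  covariances at zero. The first 3 iterations are EM updates on the
  variances (globally stable); later iterations are Newton steps
  preconditioned by the AI matrix.
- A proposed step that loses positive definiteness of `V` or decreases the
  likelihood is halved up to 10 times, then replaced by an EM step.
  Accepted iterations never decrease the likelihood.
- Variances are floored at `1e-6 * var(y)` (floor events recorded);
  covariances are unconstrained in sign.
- Convergence: change in logL below 1e-6 and largest parameter change below
  1e-6 (both overridable); maximum 100 iterations. A singular AI matrix
  triggers an EM fallback and is flagged (`ai_singular`) — deliberately
  confounded kernels surface here rather than in a misleading answer.
- The inverse AI matrix at convergence estimates the parameter sampling
  covariance; delta-method standard errors for heritability ratios and
  effect correlations (`heritability()`, `effect_correlation()`) take their
  variance/covariance cells from it. Both formulas were cross-checked
  against 50,000-draw Monte-Carlo delta oracles (agreement within a few
  percent on well-conditioned fits; the residual gap is second-order
  curvature the first-order delta method ignores).

Significance of covariance terms is assessed by the likelihood-ratio test
between the free-covariance fit and its GREML null (`lrt()`, chi-square
with one df per freed parameter) or per-term Wald tests; `reduce_model()`
drops nonsignificant pairs. Covariance parameters are interior (sign-free),
so the plain chi-square reference applies; for variance components at the
boundary the same reference is conservative, which we accept, following
common practice.

## Prediction

`blup_predict()` is the Gaussian conditional mean with the covariance-aware
signal matrix `C = sum K_i s2_i + sum B_ij s_ij`:
`yhat_test = C[test,train] V_train^-1 (y_train - X_train b)`. With zero
covariances this is standard multi-kernel GBLUP. `cross_validate()` builds
kernels once on the full sample, refits variance parameters on each
training fold (the stricter choice; whether the original analyses refit per
fold is unstated), and averages per-fold Pearson correlations.

## The synthetic-data generator

The generator exists to drive the validation experiments, not to imitate
any cohort:

- `simulate_genotypes()`: per-SNP allele frequency uniform on a range
  (default 0.05–0.5); two haplotypes per sample from a latent AR(1)
  Gaussian thresholded at the frequency quantile, so adjacent SNPs are in
  LD while marginals stay Hardy-Weinberg. `ld_rho` may be a scalar or a
  range; a range draws one correlation per block of `ld_block_snps` SNPs,
  giving heterogeneous ("blocky") LD as recombination-rate variation does.
  The validation default is moderate homogeneous LD (`ld_rho = 0.5`,
  adjacent-dosage r² ≈ 0.11).
- `simulate_imputed_transcriptome()`: each gene is a sparse linear
  combination of SNPs from a cis window plus noise scaled so genotype
  explains 13.7% of expression variance on average — the typical accuracy
  of expression-imputation models — inducing a transcriptomic kernel
  correlated with the genomic one through shared cis SNPs.
- `simulate_effects()` draws component effects as `L_i u_i` with the latent
  vectors correlated across components by the target matrix `M`, so the
  population covariance of `y` equals `assemble_V()` at the true
  parameters (verified empirically at n = 5 over 50,000 replicates).
- `simulate_architecture_effects()` is the SNP-level path: per-SNP effects
  on standardized genotypes with variance proportional to
  `w^gamma [f(1-f)]^(1+alpha)`. Because this implies effect covariance
  proportional to the matching weighted GRM, the kernel-level and SNP-level
  paths agree in distribution; the replicate drivers use the kernel-level
  path so correlated multi-component scenarios are available.

What the generator does not emulate: long-range LD, population structure,
relatedness, selection-driven MAF-LD coupling, and real functional
annotation geometry. Passing validation here shows the estimator is correct
under its own model class, not that any real cohort satisfies it.

## Replicate studies and the sizes used

`run_replicate_study()` builds one kernel set per study (one "cohort") and
redraws phenotypes per replicate — mirroring the validation design of a
fixed genotype sample with many phenotype replicates. Per replicate it fits
GREML, warm-starts the free-covariance fit from the GREML estimates (and
each GREML fit from the previous replicate's optimum; the REML optimum does
not depend on the start), runs the LRT, and records everything, seed
included. Replicates that fail to converge are excluded from summaries with
the count reported.

True-parameter settings follow the validation configuration: variances
(0.4, 0.4), residual 0.2 for the genome–transcriptome model; (0.3, 0.4,
0.1), residual 0.2 for the three-region genomic-partitioning model (regions
interleaved along the chromosome, SNP j to region j mod 3, so region
kernels share LD-induced similarity as interleaved annotations do);
covariances zero under the null and ±0.2 under the bias experiments.

Problem sizes are the package's own desk-scale choices: the acceptance
script runs both type-I-error studies at n = 1,000, m = 2,000 with 300
replicates; the test suite runs the same experiments at n = 500 with 120
replicates, the bias experiment at n = 800 with 60 replicates per sign, and
the misspecification experiment at n = 600, m = 400 with 100 replicates.
Binomial acceptance intervals are always computed at the replicate count
actually used. Checks that compare several parameters simultaneously to
truth use 2 Monte-Carlo standard errors per parameter.

## The misspecification experiment

Phenotypes are generated under the architecture `alpha = -0.25, gamma = 1`
and analyzed both with the matching kernel ("true model") and with the
equal-contribution kernel `alpha = -1, gamma = 0` ("wrong model"). Two
design notes discovered while building it:

- Under homogeneous AR(1) LD, LD scores are nearly constant across SNPs, so
  the two architecture kernels are almost collinear (off-diagonal
  correlation ≈ 0.97) and the wrong model is practically unbiased — there
  is nothing for the exponents to act on. The experiment therefore uses
  blocky LD (`ld_rho = c(0, 0.98)`, blocks of 50) and a full MAF spectrum
  (0.01–0.5), under which the wrong model's genome-variance estimate is
  biased well beyond Monte-Carlo resolution while the likelihood ranks the
  true model first in essentially every replicate.
- The covariance estimate is much more robust to misspecification than the
  variance estimates, but at desk scale it is not exactly unbiased: its
  expectation-level bias is roughly a third of the variance bias in
  standardized units and whether it resolves at 100 replicates depends on
  the simulated panel. The packaged experiment reports both.

`architecture_grid()` packages the likelihood-ranking diagnostic: fit the
same phenotype under candidate kernel sets and rank by restricted
likelihood (ties to fewer parameters), the practical guard against
assuming a wrong architecture.

## Preprocessing and file formats

`qc_genotypes()` filters on MAF (< 0.01), call rate (< 0.95), and
Hardy-Weinberg (chi-square p < 1e-4), reporting every exclusion with its
reasons. `preprocess_phenotype()` applies, in order: OLS covariate
adjustment, standardization, removal beyond ±3 SD (samples dropped
globally so all structures stay aligned). `inverse_normal_transform()`
uses Blom's 3/8 rank offset — one reasonable choice among the rank-based
variants, stated rather than hidden. Imputation-quality (INFO) and
relatedness-cutoff filters require metadata a desk-scale analysis does not
have and are out of scope.

PLINK BED/BIM/FAM (SNP-major, 2-bit) and GCTA GRM binary triplets
(float32 row-major lower triangle with `.grm.N.bin` and `.grm.id`) are
read and written natively and round-trip tested; phenotype/covariate/
expression tables are TSV with a header row, first column the sample id,
`.` for missing. Sample alignment across files happens once, by id
intersection with a logged drop report; downstream modules assume aligned
inputs. The `inst/cli/coregreml` Rscript exposes the workflows
(`make-grm`, `make-trm`, `simulate`, `fit`, `test`, `predict`, `cv`,
`replicate-study`); every run logs the package version, a config
fingerprint, and the seed.

## Known limitations

- Dense algebra throughout: practical up to roughly n = 10,000 on one
  machine; no sparse or low-rank paths, no summary-statistic mode.
- Single-trait, quantitative phenotypes only; binary traits need a
  different likelihood.
- The AI-REML schedule (3 EM iterations, step-halving, EM fallback) is one
  defensible choice among several; alternatives may differ in iteration
  path but should agree at the optimum, which is what the oracle tests pin
  down.
- Chi-square references for boundary (variance) LRTs are conservative.
- The synthetic generator's LD is local and blockwise AR(1); conclusions
  about LD-architecture effects transfer to real data only qualitatively.
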