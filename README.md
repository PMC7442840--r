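# coregreml

Variance partitioning for complex traits with **covariance between random
effects** (CORE GREML).

Multi-kernel linear mixed models estimate how much phenotypic variance is
attributable to components such as functional genomic regions, the whole
genome, or a genotype-imputed transcriptome. The standard GREML analysis
assumes the random effects of these components are independent:

    var(y) = Σ_i K_i σ²_i + I σ²_ε

where `K_i` is the relationship kernel of component i (a GRM `W W′/m` over
standardized genotypes, a TRM `Q Q′/p` over standardized imputed
expression, ...). When the effects are correlated — genomic and
transcriptomic effects overlap by construction, functional regions share
regulatory machinery — that assumption biases every variance estimate.
This package fits the generalized model in which each pair of random
effects may carry a free covariance σ_ij through the symmetrized
Cholesky-root cross-kernel:

    var(y) = Σ_i K_i σ²_i + Σ_{i<j} [√K_i·√K_j′ + (√K_i·√K_j′)′] σ_ij + I σ²_ε

All parameters are estimated by average-information REML; the inverse AI
matrix supplies sampling covariances, from which delta-method standard
errors for heritability ratios `σ²_i/σ²_y` (with
`σ²_y = Σσ²_i + 2Σσ_ij + σ²_ε`) and effect correlations
`r_ij = σ_ij/√(σ²_i σ²_j)` are derived. Covariance terms are tested by the
likelihood-ratio test against the GREML null. The package also provides
covariance-aware BLUP with k-fold cross-validation, a synthetic-data
generator (genotypes with local LD, imputed-transcriptome proxies,
phenotypes from multi-kernel models), replicate-study drivers for
type-I-error / bias / architecture-misspecification experiments, and native
readers/writers for PLINK BED/BIM/FAM and GCTA GRM binary formats.

Audience: quantitative geneticists and methodologists partitioning
phenotypic variance across genomic annotations or omic layers who need the
covariance between components estimated rather than assumed away.

## Worked example

```r
library(coregreml)

# a synthetic cohort: genotypes with local LD and an imputed transcriptome
G  <- simulate_genotypes(n = 500, m = 1000, ld_rho = 0.5, seed = 42)
A  <- build_grm(G)                                  # genomic kernel
E  <- simulate_imputed_transcriptome(G, gene_count = 250, seed = 43)
Tm <- build_trm(E)                                  # transcriptomic kernel
kernels <- list(genome = A, transcriptome = Tm)

# phenotypes with a true genome-transcriptome effect covariance of 0.2
roots <- lapply(kernels, cholesky_root)
M   <- matrix(c(0.4, 0.2, 0.2, 0.4), 2)             # effect (co)variances
eff <- simulate_effects(roots, M, seed = 44)
y   <- simulate_phenotypes(eff, resid_var = 0.2, seed = 45)

# GREML (independence) vs the free-covariance model
spec0 <- model_spec(c("genome", "transcriptome"))
spec1 <- model_spec(c("genome", "transcriptome"), "all")
fit0 <- fit_reml(spec0, y, kernels = kernels)
fit1 <- fit_reml(spec1, y, kernels = kernels)
print(fit1)
print(lrt(fit1, fit0))
print(heritability(fit1, "transcriptome"))
print(effect_correlation(fit1, c("genome", "transcriptome")))
```

Output:

```
reml_fit: n = 500, logL = -210.1662, 9 iteration(s), converged
                          estimate         se
var:genome               0.4965721 0.07879552
var:transcriptome        0.2263512 0.05561862
cov:genome:transcriptome 0.2884125 0.04478753
var:residual             0.2070350 0.05527314
LRT: statistic 37.1345, df 1, p = 1.103e-09
h2:transcriptome = 0.1502 (se 0.0345)
r:genome:transcriptome = 0.8603 (se 0.1626)
```

Reading it: the free-covariance fit recovers a strongly positive
genome-transcriptome covariance (0.29, truth 0.20 in this single draw at
n = 500); the LRT against GREML rejects independence decisively
(p ≈ 1e-9); the imputed transcriptome accounts for an estimated 15% of
phenotypic variance, and the correlation between genomic and
transcriptomic effects is 0.86 ± 0.16 (single-draw estimates at this
sample size are noisy — the replicate drivers quantify the sampling
distributions).

The same workflow is scriptable from a shell via `inst/cli/coregreml`
(`simulate`, `make-grm`, `make-trm`, `fit`, `test`, `predict`, `cv`,
`replicate-study`).

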