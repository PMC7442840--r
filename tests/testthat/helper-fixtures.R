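# Small fixtures built in code; everything seeded.

random_psd_kernel <- function(n, seed, label = "k") {
  set.seed(seed)
  M <- matrix(rnorm(n * (n + 2)), n, n + 2)
  K <- tcrossprod(M) / (n + 2)
  K <- K / mean(diag(K))
  kernel_matrix(K, label = label, diag_tol = Inf)
}

# A well-conditioned two-kernel dataset with a genuinely nonzero covariance,
# used by the delta-method, reduction, and prediction tests.
toy_core_setup <- function(n = 250, m = 500, sigma_gt = 0.2, seed = 101) {
  G <- simulate_genotypes(n, m, ld_rho = 0.5, seed = seed)
  A <- build_grm(G)
  E <- suppressMessages(simulate_imputed_transcriptome(G, m %/% 4, seed = seed + 1))
  Tm <- build_trm(E)
  kernels <- list(genome = A, transcriptome = Tm)
  spec <- model_spec(c("genome", "transcriptome"), "all")
  roots <- suppressMessages(lapply(kernels, cholesky_root))
  M <- matrix(c(0.4, sigma_gt, sigma_gt, 0.4), 2)
  eff <- simulate_effects(roots, M, seed = seed + 2)
  y <- simulate_phenotypes(eff, 0.2, seed = seed + 3)
  crosses <- suppressMessages(build_crosses(spec, kernels))
  list(G = G, kernels = kernels, crosses = crosses, spec = spec,
       roots = roots, y = y, truth = c(0.4, 0.4, sigma_gt, 0.2))
}

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  testthat::expect_lt(max(abs(a - b)), tol)
}
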