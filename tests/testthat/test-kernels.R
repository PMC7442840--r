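test_that("GRM standardization follows the (x-2f)/sqrt(2f(1-f)) definition", {
  # single SNP, dosages (0,1,2): f = 0.5, standardized column (-sqrt2,0,sqrt2)
  G <- genotype_matrix(matrix(c(0, 1, 2), 3, 1))
  W <- coregreml:::standardize_genotypes(G)
  expect_equal(unname(drop(W)), c(-sqrt(2), 0, sqrt(2)))
  # mean diagonal departs from 1 here (HWE holds only in expectation):
  # the validity warning is expected and informative
  K <- suppressWarnings(build_grm(G))
  expect_equal(K$values, tcrossprod(W) / 1, ignore_attr = TRUE)

  # identical genotype rows are perfect relatives: offdiag == diag
  D <- rbind(c(0, 1, 2, 1, 0, 1),
             c(0, 1, 2, 1, 0, 1),
             c(2, 1, 0, 0, 1, 2))
  K2 <- suppressWarnings(build_grm(genotype_matrix(D)))
  expect_equal(K2$values[1, 2], K2$values[1, 1])
})

test_that("GRM mean diagonal is near 1 for a large random panel", {
  G <- simulate_genotypes(60, 4000, seed = 5)
  K <- build_grm(G)
  expect_lt(abs(mean(diag(K$values)) - 1), 0.05)
})

test_that("monomorphic SNPs and degenerate panels are rejected by name", {
  D <- cbind(c(0, 1, 2), c(2, 2, 2))
  expect_error(build_grm(genotype_matrix(D, snp_ids = c("ok", "mono"))),
               "mono")
  expect_error(build_grm(genotype_matrix(matrix(c(0, 1, 2), 3, 1))[
    c("dosages", "sample_ids")]), class = "error")
})

test_that("missing dosages are mean-imputed and MAF recomputed", {
  D <- matrix(c(0, 1, NA, 2, 0, 2, 1, 1), 4, 2)
  G <- genotype_matrix(D)
  expect_false(anyNA(G$dosages))
  expect_equal(G$dosages[3, 1], mean(c(0, 1, 2)))
  expect_equal(G$maf, pmin(colMeans(G$dosages) / 2,
                           1 - colMeans(G$dosages) / 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("weighted GRM reduces to the plain GRM at alpha=-1, gamma=0", {
  G <- simulate_genotypes(40, 120, ld_rho = 0.4, seed = 7)
  K0 <- build_grm(G)
  K1 <- build_weighted_grm(G, architecture_params(-1, 0))
  expect_matrix_equal(K0$values, K1$values, 1e-10)
})

test_that("architecture weights follow w^gamma [f(1-f)]^(1+alpha)", {
  arch <- architecture_params(-0.25, 0)
  v <- coregreml:::architecture_weights(arch, c(0.1, 0.4))
  expect_equal(v[1] / v[2], (0.1 * 0.9)^0.75 / (0.4 * 0.6)^0.75)
  # gamma = 1: weight is linear in the LD score
  a2 <- architecture_params(-0.25, 1, ld_scores = c(2, 1))
  a3 <- architecture_params(-0.25, 1, ld_scores = c(4, 1))
  v2 <- coregreml:::architecture_weights(a2, c(0.3, 0.3))
  v3 <- coregreml:::architecture_weights(a3, c(0.3, 0.3))
  expect_equal(v3[1] / v2[1], 2)
  expect_equal(v3[2], v2[2])
  expect_error(architecture_params(0, 0, ld_scores = c(0.5, 1)), "LD scores")
})

test_that("TRM matches the brute-force Q Q'/p product with exact unit diagonal", {
  set.seed(11)
  raw <- matrix(rnorm(15), 5, 3)
  E <- expression_matrix(raw)
  K <- build_trm(E)
  Q <- apply(raw, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  expect_matrix_equal(K$values, tcrossprod(Q) / 3, 1e-12)
  expect_equal(mean(diag(K$values)), 1, tolerance = 1e-12)

  # rank-1: a single gene gives q q' with top eigenvalue q'q
  E1 <- expression_matrix(matrix(rnorm(6), 6, 1))
  K1 <- build_trm(E1)
  q <- E1$values[, 1]
  expect_equal(max(eigen(K1$values)$values), sum(q * q), tolerance = 1e-10)
  expect_message(expression_matrix(cbind(rnorm(5), rep(1, 5))), "constant")
  expect_error(expression_matrix(matrix(1, 4, 2)), "constant")
})

test_that("LD scores match a brute-force pair loop and boundary cases", {
  G <- simulate_genotypes(200, 10, ld_rho = 0.6, seed = 13)
  expect_equal(compute_ld_scores(G, 0), rep(1, 10))
  w <- compute_ld_scores(G, 3)
  X <- scale(G$dosages)
  brute <- sapply(1:10, function(i) {
    nb <- setdiff(which(abs(G$positions - G$positions[i]) <= 3), i)
    1 + sum(cor(X[, i], X[, nb])^2)
  })
  expect_equal(w, brute, tolerance = 1e-12)
  expect_true(all(w >= 1))
  # two identical adjacent SNPs: r^2 = 1, both scores 2
  D <- cbind(c(0, 1, 2, 1), c(0, 1, 2, 1))
  G2 <- genotype_matrix(D)
  expect_equal(compute_ld_scores(G2, 1), c(2, 2))
})

test_that("Cholesky root reconstructs, handles jitter, and reports failure", {
  KI <- kernel_matrix(diag(4), diag_tol = Inf)
  L <- cholesky_root(KI)
  expect_matrix_equal(L$values, diag(4), 1e-14)
  expect_identical(L$jitter_used, 0)

  K2 <- kernel_matrix(matrix(c(4, 2, 2, 5), 2), diag_tol = Inf)
  expect_matrix_equal(cholesky_root(K2)$values, matrix(c(2, 1, 0, 2), 2), 1e-12)

  K6 <- random_psd_kernel(6, seed = 17)
  L6 <- cholesky_root(K6)
  expect_lt(norm(tcrossprod(L6$values) -
                   (K6$values + diag(L6$jitter_used, 6)), "F") /
              norm(K6$values, "F"), 1e-8)
  expect_true(all(diag(L6$values) > 0))
  expect_equal(L6$values[upper.tri(L6$values)], rep(0, 15))

  # exactly singular kernel: jitter ladder engages and is reported
  v <- c(1, 1, 1) / sqrt(1)
  Ks <- kernel_matrix(tcrossprod(v), diag_tol = Inf)
  expect_message(Ls <- cholesky_root(Ks), "jitter")
  expect_gt(Ls$jitter_used, 0)
  expect_lt(norm(tcrossprod(Ls$values) -
                   (Ks$values + diag(Ls$jitter_used, 3)), "F"), 1e-6)
})

test_that("cross terms are exactly symmetric and self-pairs give 2K", {
  KI <- kernel_matrix(diag(3), diag_tol = Inf)
  LI <- cholesky_root(KI)
  expect_matrix_equal(cross_term(LI, LI)$values, 2 * diag(3), 1e-14)

  K <- random_psd_kernel(5, seed = 19)
  L <- cholesky_root(K)
  expect_matrix_equal(cross_term(L, L)$values, 2 * K$values, 1e-10)

  K2 <- random_psd_kernel(4, seed = 23, label = "b")
  Ka <- random_psd_kernel(4, seed = 29, label = "a")
  La <- cholesky_root(Ka); Lb <- cholesky_root(K2)
  B <- cross_term(La, Lb)
  brute <- La$values %*% t(Lb$values) + Lb$values %*% t(La$values)
  expect_matrix_equal(B$values, brute, 1e-12)
  expect_identical(B$values, t(B$values))

  Lm <- Lb; Lm$sample_ids <- rev(Lm$sample_ids)
  expect_error(cross_term(La, Lm), "sample ordering")
})

test_that("off-diagonal kernel correlation matches the vectorized triangle", {
  K <- random_psd_kernel(6, seed = 31)
  expect_equal(kernel_offdiag_correlation(K, K), 1)
  K2 <- random_psd_kernel(6, seed = 37)
  lt <- lower.tri(K$values)
  expect_equal(kernel_offdiag_correlation(K, K2),
               cor(K$values[lt], K2$values[lt]))
  # constructed anti-correlated off-diagonals
  Kneg <- K
  Kneg$values <- diag(diag(K$values)) - (K$values - diag(diag(K$values)))
  expect_equal(kernel_offdiag_correlation(K, Kneg), -1)
  Km <- K2; Km$sample_ids <- rev(Km$sample_ids)
  expect_error(kernel_offdiag_correlation(K, Km), "sample")
})

test_that("kernel construction is sample-permutation equivariant", {
  G <- simulate_genotypes(25, 80, ld_rho = 0.3, seed = 41)
  K <- build_grm(G)
  set.seed(43)
  for (rep in 1:3) {
    p <- sample(25)
    Kp <- build_grm(subset_genotypes(G, samples = p))
    expect_matrix_equal(Kp$values, K$values[p, p], 1e-10)
  }
})

test_that("kernel validity checks catch asymmetry and indefiniteness", {
  M <- matrix(rnorm(16), 4)
  expect_error(kernel_matrix(M), "symmetric")
  Neg <- diag(4); Neg[1, 1] <- -1
  expect_error(kernel_matrix(Neg, diag_tol = Inf), "PSD")
  expect_warning(kernel_matrix(diag(2, 5)), "mean diagonal")
})
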