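test_that("fold plans partition the sample reproducibly with balanced sizes", {
  p1 <- fold_plan(103, 5, seed = 181)
  p2 <- fold_plan(103, 5, seed = 181)
  expect_identical(p1$assignments, p2$assignments)
  sizes <- tabulate(p1$assignments, 5)
  expect_equal(sum(sizes), 103)
  expect_lte(diff(range(sizes)), 1)
  expect_error(fold_plan(4, 10), "k <= n")
})

test_that("BLUP matches the joint-Gaussian conditional mean on a toy instance", {
  toy <- toy_core_setup(n = 40, m = 100, sigma_gt = 0.2, seed = 191)
  train <- 1:32; test <- 33:40
  sub_k <- lapply(toy$kernels, function(K)
    kernel_matrix(K$values[train, train], sample_ids = K$sample_ids[train],
                  label = K$label, check = FALSE))
  sub_c <- lapply(toy$crosses, function(B) {
    B$values <- B$values[train, train]; B$sample_ids <- B$sample_ids[train]; B
  })
  fit <- fit_reml(toy$spec, toy$y[train], kernels = sub_k, crosses = sub_c)
  pred <- blup_predict(fit, toy$y, toy$kernels, toy$crosses, train, test)
  oracle <- oracle_blup(fit$params$var, fit$params$cov, fit$params$resid,
                        lapply(toy$kernels, `[[`, "values"),
                        lapply(toy$crosses, `[[`, "values"),
                        toy$y, train, test, matrix(1, 40, 1))
  expect_equal(pred, oracle, tolerance = 1e-8)
  expect_error(blup_predict(fit, toy$y, toy$kernels, toy$crosses,
                            train, c(32, 33)), "overlap")
})

test_that("identity kernels transfer no information to held-out samples", {
  n <- 60
  set.seed(193)
  ks <- list(a = kernel_matrix(diag(n), label = "a", diag_tol = Inf))
  spec <- model_spec("a")
  y <- rnorm(n)
  train <- 1:48; test <- 49:60
  sub <- list(a = kernel_matrix(diag(48), label = "a", check = FALSE))
  fit <- fit_reml(spec, y[train], kernels = sub)
  expect_equal(unname(blup_predict(fit, y, ks, train = train, test = test)),
               rep(0, 12), tolerance = 1e-10)
})

test_that("a perfect relative's phenotype is recovered as residual variance vanishes", {
  # duplicate one training individual into the test set; with one kernel and
  # tiny residual variance the conditional mean approaches the centered
  # phenotype of the duplicate
  G <- simulate_genotypes(50, 150, seed = 197)
  D <- G$dosages
  D[50, ] <- D[1, ]   # sample 50 is a genetic copy of sample 1
  G2 <- genotype_matrix(D)
  K <- build_grm(G2)
  spec <- model_spec("genome")
  kernels <- list(genome = K)
  train <- 1:49; test <- 50
  set.seed(199)
  root <- suppressMessages(cholesky_root(K))
  g <- drop(root$values %*% rnorm(50)) * sqrt(0.9)
  y <- g + rnorm(50, sd = sqrt(0.1))
  fit <- fit_reml(spec, y[train],
                  kernels = list(genome = kernel_matrix(K$values[train, train],
                                                        check = FALSE)))
  # doctored parameters: near-zero residual forces interpolation
  fit$params$var[] <- 1; fit$params$resid <- 1e-6
  pred <- blup_predict(fit, y, kernels, train = train, test = test)
  expect_equal(unname(pred), unname(y[1] - fit$beta), tolerance = 0.05)
})

test_that("BLUP with zero covariance equals multi-kernel GBLUP", {
  toy <- toy_core_setup(n = 50, m = 120, sigma_gt = 0, seed = 211)
  train <- 1:40; test <- 41:50
  spec0 <- model_spec(c("genome", "transcriptome"))
  sub_k <- lapply(toy$kernels, function(K)
    kernel_matrix(K$values[train, train], sample_ids = K$sample_ids[train],
                  label = K$label, check = FALSE))
  fit0 <- fit_reml(spec0, toy$y[train], kernels = sub_k)
  g_pred <- blup_predict(fit0, toy$y, toy$kernels, train = train, test = test)
  # same parameters pushed through the free-covariance spec with cov = 0
  fit_c <- fit0
  fit_c$spec <- toy$spec
  fit_c$params <- variance_params(fit0$params$var, 0, fit0$params$resid,
                                  toy$spec)
  c_pred <- blup_predict(fit_c, toy$y, toy$kernels, toy$crosses,
                         train = train, test = test)
  expect_equal(c_pred, g_pred, tolerance = 1e-8)
})

test_that("cross-validation of a pure-noise phenotype finds no accuracy", {
  G <- simulate_genotypes(200, 300, seed = 223)
  K <- build_grm(G)
  set.seed(227)
  y <- rnorm(200)
  cv <- cross_validate(y, list(g = list(spec = model_spec("genome"),
                                        kernels = list(genome = K))),
                       k = 5, seed = 229)
  expect_lt(abs(cv$mean_r), 0.2)  # ~N(0, 1/sqrt(40)) per fold
  expect_true(all(abs(cv$folds$r) <= 1))
})

test_that("identical variants give identical accuracy under a fixed seed", {
  toy <- toy_core_setup(n = 120, m = 200, sigma_gt = 0.2, seed = 233)
  v <- list(spec = toy$spec, kernels = toy$kernels, crosses = toy$crosses)
  cv <- cross_validate(toy$y, list(a = v, b = v), k = 4, seed = 239)
  expect_equal(unname(cv$delta_r["b"]), 0)
  expect_identical(cv$folds$r[cv$folds$variant == "a"],
                   cv$folds$r[cv$folds$variant == "b"])
})

test_that("modeling a real covariance improves predictive accuracy on average", {
  # paired CV comparison on phenotypes generated with a positive
  # genome-transcriptome covariance; the free-covariance model should not
  # predict worse than GREML on average across replicates
  n <- 400
  G <- simulate_genotypes(n, 600, ld_rho = 0.5, seed = 241)
  A <- build_grm(G)
  E <- suppressMessages(simulate_imputed_transcriptome(G, 150, seed = 242))
  Tm <- build_trm(E)
  kernels <- list(genome = A, transcriptome = Tm)
  spec_core <- model_spec(c("genome", "transcriptome"), "all")
  spec0 <- model_spec(c("genome", "transcriptome"))
  crosses <- suppressMessages(build_crosses(spec_core, kernels))
  roots <- suppressMessages(lapply(kernels, cholesky_root))
  M <- matrix(c(0.4, 0.25, 0.25, 0.4), 2)
  gains <- vapply(1:4, function(r) {
    eff <- simulate_effects(roots, M, seed = 250000 + r)
    y <- simulate_phenotypes(eff, 0.2, seed = 950000 + r)
    cv <- cross_validate(y, list(
      greml = list(spec = spec0, kernels = kernels),
      core = list(spec = spec_core, kernels = kernels, crosses = crosses)),
      k = 5, seed = 251)
    unname(cv$delta_r["core"])
  }, 0)
  expect_gt(mean(gains), 0)
})
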