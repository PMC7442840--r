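test_that("LRT handles self-comparison, the chi-square identity, and failures", {
  toy <- toy_core_setup(n = 80, m = 160, seed = 151)
  fit <- fit_reml(toy$spec, toy$y, kernels = toy$kernels, crosses = toy$crosses)
  self <- lrt(fit, fit, df = 1)
  expect_equal(self$statistic, 0)
  expect_equal(self$pvalue, 1)

  # p at the textbook 5% critical value
  fake_null <- fit; fake_null$loglik <- fit$loglik - 3.841 / 2
  fake_null$theta <- fit$theta[-3]
  tr <- lrt(fit, fake_null)
  expect_equal(tr$df, 1)
  expect_equal(round(tr$pvalue, 3), 0.050)
  expect_equal(tr$pvalue,
               pchisq(tr$statistic, 1, lower.tail = FALSE), tolerance = 1e-12)

  # an alternative fit below the null flags optimizer failure
  worse <- fit; worse$loglik <- fit$loglik - 1
  expect_warning(lrt(worse, fake_null <- {
    fn <- fit; fn$theta <- fit$theta[-3]; fn
  }), "optimizer failure")
})

test_that("Wald test matches the chi-square tail of the squared z", {
  expect_equal(wald_test(0, 1)$pvalue, 1)
  expect_equal(wald_test(1.96, 1)$pvalue, 0.05, tolerance = 1e-3)
  tr <- wald_test(0.35, 0.11)
  expect_equal(tr$pvalue, pchisq((0.35 / 0.11)^2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(wald_test(1, 0), "positive")
})

test_that("total phenotypic variance doubles every covariance term", {
  spec <- model_spec(c("g", "t"), "all")
  expect_equal(total_phenotypic_variance(
    variance_params(c(g = 0.4, t = 0.4), 0.2, 0.2, spec)), 1.4)
  expect_equal(total_phenotypic_variance(
    variance_params(c(g = 0.4, t = 0.4), -0.2, 0.2, spec)), 0.6)
  expect_equal(total_phenotypic_variance(
    variance_params(c(g = 0.5), resid = 0.5, spec = model_spec("g"))), 1)
})

test_that("heritability point values follow the variance ratio", {
  toy <- toy_core_setup(n = 150, m = 300, sigma_gt = 0.2, seed = 157)
  fit <- fit_reml(toy$spec, toy$y, kernels = toy$kernels, crosses = toy$crosses)
  h <- heritability(fit, "genome")
  sy <- sum(fit$params$var) + 2 * sum(fit$params$cov) + fit$params$resid
  expect_equal(h$value, unname(fit$params$var["genome"]) / sy,
               ignore_attr = TRUE)
  expect_gt(h$se, 0)
  hr <- heritability(fit, "residual")
  expect_equal(hr$value, fit$params$resid / sy, ignore_attr = TRUE)
  expect_error(heritability(fit, "nope"), "unknown component")
})

test_that("delta-method SEs agree with Monte-Carlo delta oracles", {
  toy <- toy_core_setup(n = 700, m = 900, sigma_gt = 0.25, seed = 163)
  fit <- fit_reml(toy$spec, toy$y, kernels = toy$kernels, crosses = toy$crosses)
  expect_true(fit$converged)
  th <- unname(fit$theta)
  C <- fit$param_cov

  h <- heritability(fit, "genome")
  mc_h <- oracle_mc_delta(function(t_) t_[1] / (t_[1] + t_[2] + 2 * t_[3] + t_[4]),
                          th, C, n_draws = 50000, seed = 7)
  expect_lt(abs(h$se - mc_h) / mc_h, 0.05)

  r <- effect_correlation(fit, c("genome", "transcriptome"))
  mc_r <- oracle_mc_delta(function(t_) t_[3] / sqrt(t_[1] * t_[2]),
                          th, C, n_draws = 50000, seed = 8)
  expect_lt(abs(r$se - mc_r) / mc_r, 0.05)
  expect_equal(r$value, th[3] / sqrt(th[1] * th[2]))
})

test_that("effect correlation handles exact and degenerate cases", {
  toy <- toy_core_setup(n = 80, m = 160, sigma_gt = 0.2, seed = 167)
  fit <- fit_reml(toy$spec, toy$y, kernels = toy$kernels, crosses = toy$crosses)
  # algebraic identities on a doctored copy
  doc <- fit
  doc$theta[1:3] <- c(0.4, 0.4, 0.2)
  doc$params <- coregreml:::theta_to_params(unname(doc$theta), toy$spec)
  expect_equal(effect_correlation(doc, c("genome", "transcriptome"))$value, 0.5)
  doc$theta[3] <- sqrt(doc$theta[1] * doc$theta[2])
  doc$params <- coregreml:::theta_to_params(unname(doc$theta), toy$spec)
  expect_equal(effect_correlation(doc, c("genome", "transcriptome"))$value, 1)
  # variance at the floor: refuse to divide by ~0
  doc$theta[1] <- 1e-12
  doc$params <- coregreml:::theta_to_params(unname(doc$theta), toy$spec)
  expect_error(effect_correlation(doc, c("genome", "transcriptome")), "floor")
})

test_that("genetic variance proportions split covariances evenly and sum to 1", {
  spec <- model_spec(c("r1", "r2", "r3"), "all")
  ks <- lapply(c(r1 = 1, r2 = 2, r3 = 3), function(s)
    random_psd_kernel(40, 170 + s))
  for (l in names(ks)) ks[[l]]$label <- l
  set.seed(173)
  fit <- fit_reml(spec, rnorm(40),
                  kernels = ks, crosses = suppressMessages(build_crosses(spec, ks)),
                  control = reml_control(max_iter = 20))
  # doctored parameter sets exercise the arithmetic deterministically
  doc <- fit
  doc$params <- variance_params(c(r1 = 0.3, r2 = 0.4, r3 = 0.1),
                                c(0, 0, 0), 0.2, spec)
  gp <- genetic_variance_proportions(doc)
  expect_equal(gp$proportion, c(0.375, 0.5, 0.125))
  doc$params <- variance_params(c(r1 = 0.2, r2 = 0.2, r3 = 0.2),
                                c(0, 0, 0), 0.2, spec)
  expect_equal(genetic_variance_proportions(doc)$proportion, rep(1 / 3, 3))
  doc$params <- variance_params(c(r1 = 0.25, r2 = 0.4, r3 = 0.1),
                                c(0.05, -0.02, 0.03), 0.2, spec)
  gp2 <- genetic_variance_proportions(doc, snp_counts = c(r1 = 100, r2 = 300,
                                                          r3 = 600))
  expect_equal(sum(gp2$proportion), 1)
  expect_equal(gp2$snp_share, c(0.1, 0.3, 0.6))
})

test_that("architecture grid ranks by likelihood, deterministically", {
  toy <- toy_core_setup(n = 100, m = 200, seed = 179)
  spec0 <- model_spec(c("genome", "transcriptome"))
  single <- architecture_grid(toy$y, list(
    only = list(spec = spec0, kernels = toy$kernels)))
  expect_equal(single$rank, 1)

  cand <- list(
    a = list(spec = spec0, kernels = toy$kernels),
    b = list(spec = toy$spec, kernels = toy$kernels, crosses = toy$crosses))
  g1 <- architecture_grid(toy$y, cand)
  g2 <- architecture_grid(toy$y, rev(cand))
  expect_equal(g1$model, g2$model)
  expect_equal(g1$loglik, g2$loglik, tolerance = 1e-8)
  # the free-covariance model can never fit worse than its nested null
  expect_gte(g1$loglik[g1$model == "b"], g1$loglik[g1$model == "a"] - 1e-6)
})

test_that("Bonferroni adjustment is pure post-processing", {
  p <- c(0.01, 0.2, 0.6)
  expect_equal(bonferroni_adjust(p), pmin(1, p * 3))
  expect_equal(bonferroni_adjust(p, family_size = 10), pmin(1, p * 10))
})
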