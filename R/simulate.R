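#' Synthetic biallelic genotypes with local LD
#'
#' Per SNP an allele frequency f is drawn from `maf_spectrum`; each sample
#' carries two haplotypes generated from a latent AR(1) Gaussian across SNP
#' positions with lag correlation `ld_rho`, thresholded at the f-quantile, so
#' adjacent SNPs are in linkage disequilibrium while dosages remain marginal
#' Hardy-Weinberg draws. `ld_rho = 0` gives independent SNPs. Columns that
#' come out monomorphic (possible at tiny n) are redrawn.
#'
#' @param n sample count.
#' @param m SNP count.
#' @param maf_spectrum length-2 range for the uniform allele-frequency draw
#'   (default c(0.05, 0.5)).
#' @param ld_rho latent AR(1) lag correlation in [0, 0.99]: a scalar for
#'   homogeneous LD, or a length-2 range from which a per-block correlation
#'   is drawn uniformly (LD "blocks" of `ld_block_snps` SNPs, emulating
#'   recombination-rate variation along the chromosome). Default 0.
#' @param ld_block_snps block length in SNPs when `ld_rho` is a range
#'   (default 50).
#' @param seed integer seed.
#' @return a [genotype_matrix()] with positions 1..m.
#' @export
simulate_genotypes <- function(n, m, maf_spectrum = c(0.05, 0.5), ld_rho = 0,
                               ld_block_snps = 50, seed = 1) {
  if (any(ld_rho < 0) || any(ld_rho > 0.99)) stop("ld_rho must be in [0, 0.99]")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  f <- stats::runif(m, maf_spectrum[1], maf_spectrum[2])
  thr <- stats::qnorm(f)
  rho <- if (length(ld_rho) == 2) {
    nb <- ceiling(m / ld_block_snps)
    rep(stats::runif(nb, ld_rho[1], ld_rho[2]), each = ld_block_snps)[seq_len(m)]
  } else rep(ld_rho, m)
  haplo <- function() {
    Z <- matrix(0, n, m)
    Z[, 1] <- stats::rnorm(n)
    if (m > 1) {
      for (j in 2:m)
        Z[, j] <- rho[j] * Z[, j - 1] + sqrt(1 - rho[j]^2) * stats::rnorm(n)
    }
    Z < rep(thr, each = n)
  }
  D <- haplo() + haplo()
  # guard against monomorphic columns at small n
  for (tries in 1:20) {
    mono <- colSums(D) %in% c(0L, 2L * n)
    if (!any(mono)) break
    for (j in which(mono)) {
      h <- stats::rnorm(2 * n) < thr[j]
      D[, j] <- h[1:n] + h[(n + 1):(2 * n)]
    }
  }
  storage.mode(D) <- "double"
  genotype_matrix(D, positions = seq_len(m))
}

#' Synthetic imputed-transcriptome matrix
#'
#' Emulates genotype-imputed expression: each gene is a sparse linear
#' combination of SNPs from its cis window (standard-normal weights on
#' MAF-standardized dosages) plus Gaussian noise scaled so the
#' genotype-explained fraction of each gene's variance matches `h2_target`
#' (default 0.137, a typical average for expression imputation models). The
#' resulting transcriptomic kernel is correlated with the genomic kernel
#' through the shared cis SNPs.
#'
#' @param G a [genotype_matrix()].
#' @param gene_count number of genes.
#' @param cis_window cis window width in SNPs (default 10).
#' @param weights_per_gene nonzero weights per gene (default 5).
#' @param h2_target genotype-explained fraction of expression variance
#'   (default 0.137); `h2_target = 1` gives noise-free expression.
#' @param seed integer seed.
#' @return an [expression_matrix()]; attribute `"explained"` carries the
#'   realized per-gene explained fractions.
#' @export
simulate_imputed_transcriptome <- function(G, gene_count, cis_window = 10,
                                           weights_per_gene = 5,
                                           h2_target = 0.137, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- ncol(G$dosages)
  if (cis_window > m) stop("cis window wider than the SNP panel")
  if (h2_target <= 0 || h2_target > 1) stop("h2_target must be in (0, 1]")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  W <- standardize_genotypes(G)
  n <- nrow(W)
  starts <- pmin(floor(seq(0, m - cis_window, length.out = gene_count)) + 1,
                 m - cis_window + 1)
  E <- matrix(0, n, gene_count)
  explained <- numeric(gene_count)
  for (g in seq_len(gene_count)) {
    win <- starts[g]:(starts[g] + cis_window - 1)
    sel <- sample(win, min(weights_per_gene, length(win)))
    raw <- drop(W[, sel, drop = FALSE] %*% stats::rnorm(length(sel)))
    vg <- pop_var(raw)
    noise <- if (h2_target < 1)
      stats::rnorm(n, sd = sqrt(vg * (1 - h2_target) / h2_target))
    else rep(0, n)
    E[, g] <- raw + noise
    explained[g] <- vg / pop_var(E[, g])
  }
  out <- expression_matrix(E, sample_ids = G$sample_ids,
                           gene_ids = paste0("gene", seq_len(gene_count)))
  attr(out, "explained") <- explained
  out
}

#' Correlated random effects from kernel roots
#'
#' Draws per-component effect vectors whose joint covariance matches the
#' multi-kernel model at the true parameters: latent vectors u_1..u_k are
#' standard normal across samples with per-sample covariance `M` across
#' components (via a factor of M), and component i's effect is L_i u_i.
#' Then cov(effect_i, effect_j) = M_ij L_i L_j', so the population
#' covariance of the phenotype equals [assemble_V()] at those parameters.
#'
#' @param roots list of [cholesky_root()] objects, one per component, common
#'   sample order.
#' @param M k x k positive-semidefinite effect covariance matrix (variances
#'   on the diagonal, covariances off it).
#' @param seed integer seed.
#' @return named list of effect vectors (names from the root labels).
#' @export
simulate_effects <- function(roots, M, seed = 1) {
  k <- length(roots)
  M <- as.matrix(M)
  stopifnot(nrow(M) == k, ncol(M) == k)
  if (max(abs(M - t(M))) > 1e-12 * max(abs(M), 1)) stop("M must be symmetric")
  ev <- eigen(M, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values)))
    stop("effect covariance matrix M is not positive semidefinite")
  Fm <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  n <- nrow(roots[[1]]$values)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  U <- matrix(stats::rnorm(n * k), n, k) %*% t(Fm)  # rows iid N(0, M)
  out <- lapply(seq_len(k), function(i) drop(roots[[i]]$values %*% U[, i]))
  names(out) <- vapply(roots, function(r) r$source_label, "")
  out
}

#' Phenotypes from simulated effects
#'
#' y = sum of component effects + independent Gaussian residual; mean zero
#' (phenotypes are standardized downstream in any case).
#'
#' @param effects list of sample-aligned effect vectors.
#' @param resid_var residual variance.
#' @param seed integer seed.
#' @return numeric phenotype vector.
#' @export
simulate_phenotypes <- function(effects, resid_var, seed = 1) {
  n <- length(effects[[1]])
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  Reduce(`+`, effects) + stats::rnorm(n, sd = sqrt(resid_var))
}

#' Genetic values under an explicit MAF/LD architecture
#'
#' Draws per-SNP effects beta_i ~ N(0, c v_i) on MAF-standardized genotypes,
#' with v_i = w_i^gamma [f_i(1-f_i)]^(1+alpha) and c calibrated so the mean
#' variance of the genetic values equals `total_var`. At alpha = -1,
#' gamma = 0 this is the equal-contribution architecture: i.i.d. effects on
#' standardized genotypes.
#'
#' @param G a [genotype_matrix()].
#' @param arch an [architecture_params()].
#' @param total_var target mean variance of the genetic values.
#' @param seed integer seed.
#' @return numeric genetic-value vector; attribute `"beta"` carries the
#'   per-SNP effects.
#' @export
simulate_architecture_effects <- function(G, arch, total_var, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"))
  v <- architecture_weights(arch, G$maf)
  W <- standardize_genotypes(G)
  # E[var(W beta)] summed over SNPs: sum_j v_j * mean(W_j^2), up to scale c
  c_scale <- total_var / sum(v * colMeans(W^2))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  beta <- stats::rnorm(ncol(W), sd = sqrt(c_scale * v))
  g <- drop(W %*% beta)
  attr(g, "beta") <- beta
  g
}

#' Simulation study configuration
#'
#' Bundles the generative conditions for a replicate study: sample size, SNP
#' panel, model family, true parameters, architecture, and seeding. The
#' defaults are the validation conditions: variances (0.4, 0.4) with
#' residual 0.2 for the genome-transcriptome model, (0.3, 0.4, 0.1) with
#' residual 0.2 for the three-region genomic-partitioning model, covariances
#' zero unless supplied, equal-contribution architecture, moderate local LD.
#'
#' @param model `"genome_transcriptome"` or `"genomic_partitioning"`.
#' @param n sample size.
#' @param m SNP count (split into three interleaved regions for the
#'   partitioning model).
#' @param replicates replicate count.
#' @param base_seed master seed; replicate r uses seed `base_seed + r`.
#' @param cov_values named or positional covariance values for the free
#'   pairs (default all zero). For the genome-transcriptome model a single
#'   value (sigma_gt); for the partitioning model three values ordered as
#'   (DHS:regulatory, other:regulatory, DHS:other).
#' @param var_values component variances (defaults above).
#' @param resid_var residual variance (default 0.2).
#' @param maf_spectrum,ld_rho genotype generator settings (defaults
#'   c(0.05, 0.5) and 0.5).
#' @param gene_count,cis_window,weights_per_gene,h2_target transcriptome
#'   generator settings (defaults m/4, 10, 5, 0.137).
#' @param architecture an [architecture_params()] used both to weight the
#'   genomic kernel and (through it) to draw genetic effects; the default
#'   alpha = -1, gamma = 0 makes the genomic kernel the plain GRM.
#' @param control a [reml_control()] for the per-replicate fits.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(model = c("genome_transcriptome",
                                        "genomic_partitioning"),
                              n = 1000, m = 2000, replicates = 300,
                              base_seed = 1, cov_values = NULL,
                              var_values = NULL, resid_var = 0.2,
                              maf_spectrum = c(0.05, 0.5), ld_rho = 0.5,
                              gene_count = NULL, cis_window = 10,
                              weights_per_gene = 5, h2_target = 0.137,
                              architecture = architecture_params(-1, 0),
                              control = reml_control(tol_loglik = 1e-6,
                                                     tol_param = 1e-4)) {
  model <- match.arg(model)
  if (model == "genome_transcriptome") {
    components <- c("genome", "transcriptome")
    if (is.null(var_values)) var_values <- c(0.4, 0.4)
    n_pairs <- 1L
  } else {
    components <- c("regulatory", "DHS", "other")
    if (is.null(var_values)) var_values <- c(0.3, 0.4, 0.1)
    n_pairs <- 3L
  }
  if (is.null(cov_values)) cov_values <- rep(0, n_pairs)
  if (length(cov_values) != n_pairs) stop("wrong number of covariance values")
  if (is.null(gene_count)) gene_count <- max(20L, m %/% 4L)
  spec <- model_spec(components, free_covariances = "all")
  true_params <- variance_params(
    stats::setNames(var_values, components), cov_values, resid_var, spec = spec)
  # implied component covariance matrix must be PSD
  k <- length(components)
  M <- diag(var_values, k)
  for (j in seq_along(spec$free_covariances)) {
    p <- match(spec$free_covariances[[j]], components)
    M[p[1], p[2]] <- M[p[2], p[1]] <- cov_values[j]
  }
  if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("true parameter setting implies a non-PSD effect covariance")
  structure(list(model = model, n = n, m = m, replicates = replicates,
                 base_seed = base_seed, spec = spec, true_params = true_params,
                 effect_cov = M, resid_var = resid_var,
                 maf_spectrum = maf_spectrum, ld_rho = ld_rho,
                 gene_count = gene_count, cis_window = cis_window,
                 weights_per_gene = weights_per_gene, h2_target = h2_target,
                 architecture = architecture, control = control),
            class = "simulation_config")
}

#' Build the generative/estimation kernels for a simulation config
#'
#' Genotypes (and, for the genome-transcriptome model, an imputed
#' transcriptome) are simulated once per study; the genomic-partitioning
#' model assigns SNP j to region (j mod 3), interleaving regions along the
#' chromosome so region kernels share LD-induced similarity as functional
#' annotations do.
#'
#' @param cfg a [simulation_config()].
#' @return list with `kernels`, `roots`, `crosses`, `genotypes`, and (for
#'   the genome-transcriptome model) `expression`.
#' @keywords internal
simulation_kernels <- function(cfg) {
  G <- simulate_genotypes(cfg$n, cfg$m, cfg$maf_spectrum, cfg$ld_rho,
                          seed = cfg$base_seed)
  kernels <- list()
  expression <- NULL
  if (cfg$model == "genome_transcriptome") {
    arch <- cfg$architecture
    if (is.null(arch$ld_scores) && arch$gamma != 0)
      arch$ld_scores <- compute_ld_scores(G, window_snps = 50)
    kernels$genome <- build_weighted_grm(G, arch, label = "genome")
    expression <- simulate_imputed_transcriptome(
      G, cfg$gene_count, cfg$cis_window, cfg$weights_per_gene, cfg$h2_target,
      seed = cfg$base_seed + 500000L)
    kernels$transcriptome <- build_trm(expression)
  } else {
    region <- (seq_len(cfg$m) - 1L) %% 3L
    labs <- c("regulatory", "DHS", "other")
    for (i in 1:3)
      kernels[[labs[i]]] <- build_grm(subset_genotypes(G, snps = which(region == i - 1L)),
                                      label = labs[i])
  }
  roots <- lapply(kernels, cholesky_root)
  crosses <- build_crosses(cfg$spec, kernels)
  list(kernels = kernels, roots = roots, crosses = crosses, genotypes = G,
       expression = expression)
}

#' Replicate study: type-I error, bias, and GREML comparison
#'
#' Simulates `cfg$replicates` phenotype replicates on one synthetic kernel
#' set (kernels built once, phenotypes redrawn per replicate, mirroring a
#' fixed genotyped cohort), fits GREML (all covariances zero) and the
#' free-covariance model per replicate, and runs the likelihood-ratio test
#' between them. The free-covariance fit warm-starts from the GREML
#' estimates. Non-converging replicates are recorded and excluded from
#' summaries, with the exclusion count reported.
#'
#' @param cfg a [simulation_config()].
#' @param alpha LRT significance level for the rejection-rate summary
#'   (default 0.05).
#' @param progress print a dot every 25 replicates.
#' @return object of class `replicate_study`: `records` (one row per
#'   replicate: seeds, truth, both methods' estimates, LRT p, convergence),
#'   `summary` (per-parameter mean/SD/bias/MC-SE for each method, rejection
#'   fraction, exclusion count), and `cfg`.
#' @export
run_replicate_study <- function(cfg, alpha = 0.05, progress = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  sk <- simulation_kernels(cfg)
  spec_core <- cfg$spec
  spec_null <- model_spec(spec_core$components, list())
  design_core <- core_design(spec_core, sk$kernels, sk$crosses)
  design_null <- core_design(spec_null, sk$kernels)
  theta_true <- params_to_theta(cfg$true_params)
  nm_core <- param_names(spec_core)
  nm_null <- param_names(spec_null)
  df_lrt <- length(spec_core$free_covariances)

  rows <- vector("list", cfg$replicates)
  # warm start: each replicate's GREML fit starts from the previous
  # replicate's optimum (the REML optimum does not depend on the start);
  # the free-covariance fit starts from the replicate's own GREML estimates
  warm <- NULL
  for (r in seq_len(cfg$replicates)) {
    seed_r <- cfg$base_seed + r
    effects <- simulate_effects(sk$roots[spec_core$components], cfg$effect_cov,
                                seed = seed_r)
    y <- simulate_phenotypes(effects, cfg$resid_var, seed = seed_r + 1000000L)
    fit0 <- if (is.null(warm)) fit_reml(design_null, y, control = cfg$control)
            else fit_reml(design_null, y, init = warm,
                          control = within_control(cfg$control, n_em = 0))
    if (!fit0$converged && !is.null(warm))
      fit0 <- fit_reml(design_null, y, control = cfg$control)
    if (fit0$converged) warm <- fit0$params
    init_core <- variance_params(fit0$params$var,
                                 rep(0, df_lrt), fit0$params$resid,
                                 spec = spec_core)
    fit1 <- fit_reml(design_core, y, init = init_core,
                     control = within_control(cfg$control, n_em = 0))
    p_lrt <- if (fit0$converged && fit1$converged)
      lrt(fit1, fit0, df = df_lrt)$pvalue else NA_real_
    est <- stats::setNames(as.list(fit1$theta), paste0("core.", nm_core))
    est0 <- stats::setNames(as.list(fit0$theta), paste0("greml.", nm_null))
    rows[[r]] <- c(list(replicate = r, seed = seed_r, lrt_p = p_lrt,
                        converged_core = fit1$converged,
                        converged_greml = fit0$converged),
                   est, est0)
    if (progress && r %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  records <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, check.names = FALSE)))

  ok <- records$converged_core & records$converged_greml
  n_ok <- sum(ok)
  core_cols <- paste0("core.", nm_core)
  greml_cols <- paste0("greml.", nm_null)
  summarize <- function(cols, truth) {
    est <- as.matrix(records[ok, cols, drop = FALSE])
    data.frame(parameter = sub("^(core|greml)\\.", "", cols),
               truth = truth,
               mean = colMeans(est),
               sd = apply(est, 2, stats::sd),
               bias = colMeans(est) - truth,
               mc_se = apply(est, 2, stats::sd) / sqrt(n_ok),
               row.names = NULL)
  }
  truth_null <- c(theta_true[seq_along(spec_core$components)],
                  theta_true[length(theta_true)])
  summary <- list(
    core = summarize(core_cols, theta_true),
    greml = summarize(greml_cols, truth_null),
    rejection_rate = mean(records$lrt_p[ok] < alpha),
    alpha = alpha,
    n_replicates = cfg$replicates,
    n_converged = n_ok,
    n_excluded = cfg$replicates - n_ok
  )
  structure(list(records = records, summary = summary, cfg = cfg),
            class = "replicate_study")
}

within_control <- function(control, ...) {
  upd <- list(...)
  control[names(upd)] <- upd
  control
}

#' @export
print.replicate_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf("replicate_study (%s): %d replicates (%d excluded)\n",
              x$cfg$model, s$n_replicates, s$n_excluded))
  cat(sprintf("LRT rejection rate at alpha=%.2f: %.4f\n",
              s$alpha, s$rejection_rate))
  cat("free-covariance model estimates:\n")
  print(s$core, digits = 4)
  cat("GREML estimates:\n")
  print(s$greml, digits = 4)
  invisible(x)
}
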