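#' Relationship kernel container
#'
#' An n x n symmetric positive semidefinite similarity matrix with sample ids
#' and a component label ("genome", "transcriptome", "regulatory", ...).
#' Validity checks: symmetry (relative 1e-10), PSD up to numerical noise
#' (smallest eigenvalue >= -1e-8 x mean diagonal), and -- for standardized
#' kernels -- a mean diagonal near 1. The mean-diagonal check is a warning,
#' not a correction: under the (x - 2f)/sqrt(2f(1-f)) standardization the mean
#' diagonal equals 1 only in Hardy-Weinberg expectation, so the default
#' tolerance is loose.
#'
#' @param values n x n numeric matrix.
#' @param sample_ids sample identifiers (default rownames or S1..Sn).
#' @param label component name.
#' @param check logical; run validity checks (default TRUE).
#' @param diag_tol tolerance for the mean-diagonal-is-1 warning (default 0.05;
#'   set to `Inf` to disable for non-standardized kernels).
#' @return object of class `kernel_matrix` with `values`, `sample_ids`, `label`.
#' @export
kernel_matrix <- function(values, sample_ids = NULL, label = "kernel",
                          check = TRUE, diag_tol = 0.05) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  if (check) {
    if (n != ncol(values)) stop("kernel must be square")
    sc <- max(abs(values))
    if (sc == 0) stop("kernel is identically zero")
    if (max(abs(values - t(values))) > 1e-10 * sc)
      stop("kernel '", label, "' is not symmetric (relative tolerance 1e-10)")
    values <- (values + t(values)) / 2
    md <- mean(diag(values))
    ev_min <- min(eigen(values, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8 * md)
      stop(sprintf("kernel '%s' is not PSD: smallest eigenvalue %.3e (mean diag %.3f)",
                   label, ev_min, md))
    if (is.finite(diag_tol) && abs(md - 1) > diag_tol)
      warning(sprintf("kernel '%s': mean diagonal %.4f departs from 1 beyond %.3g",
                      label, md, diag_tol))
  }
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, sample_ids = sample_ids, label = label),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix '%s': %d x %d, mean diag %.4f\n",
              x$label, nrow(x$values), ncol(x$values), mean(diag(x$values))))
  invisible(x)
}

#' Genomic relationship matrix (GRM)
#'
#' Builds A = W W'/m from column-standardized genotypes, where column j of W
#' is (x_j - 2 f_j) / sqrt(2 f_j (1 - f_j)). Entries measure pairwise genetic
#' similarity; the mean diagonal is close to 1 when genotype counts are near
#' Hardy-Weinberg proportions.
#'
#' @param G a [genotype_matrix()]; no monomorphic SNPs allowed.
#' @param label kernel label (default "genome").
#' @return a [kernel_matrix()].
#' @export
build_grm <- function(G, label = "genome") {
  stopifnot(inherits(G, "genotype_matrix"))
  if (nrow(G$dosages) < 2) stop("need at least 2 samples to build a GRM")
  W <- standardize_genotypes(G)
  K <- tcrossprod(W) / ncol(W)
  kernel_matrix(K, sample_ids = G$sample_ids, label = label)
}

#' MAF/LD architecture parameters
#'
#' Per-SNP effect-variance weights v_i = w_i^gamma [f_i (1 - f_i)]^(1 + alpha)
#' where f_i is the minor allele frequency, w_i >= 1 an LD score, alpha the
#' MAF exponent and gamma the LD exponent. alpha = -1, gamma = 0 is the
#' equal-contribution (GCTA) architecture; alpha = -0.25 is the LDAK default.
#' The weight applies to effects on MAF-standardized genotypes, so v_i is the
#' expected share of genetic variance contributed by SNP i (up to scale).
#'
#' @param alpha MAF exponent.
#' @param gamma LD exponent.
#' @param ld_scores per-SNP LD scores, all >= 1; default 1 (no LD weighting).
#' @return object of class `architecture_params`.
#' @export
architecture_params <- function(alpha = -1, gamma = 0, ld_scores = NULL) {
  if (!is.null(ld_scores) && any(ld_scores < 1))
    stop("LD scores must be >= 1 (self r^2 included)")
  structure(list(alpha = alpha, gamma = gamma, ld_scores = ld_scores),
            class = "architecture_params")
}

#' Per-SNP architecture weights
#' @param arch an [architecture_params()].
#' @param maf per-SNP minor allele frequencies.
#' @return positive finite weight vector v.
#' @keywords internal
architecture_weights <- function(arch, maf) {
  w <- arch$ld_scores
  if (is.null(w)) w <- rep(1, length(maf))
  if (length(w) != length(maf)) stop("ld_scores not aligned to SNPs")
  v <- w^arch$gamma * (maf * (1 - maf))^(1 + arch$alpha)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("architecture weights must be finite and positive")
  v
}

#' Architecture-weighted genomic relationship matrix
#'
#' Builds K = W diag(v) W' / sum(v) on MAF-standardized genotypes W with
#' per-SNP weights v_i = w_i^gamma [f_i(1-f_i)]^(1+alpha), so the phenotypic
#' covariance implied by SNP effects with var(beta_i) proportional to v_i on
#' standardized genotypes is proportional to K. With alpha = -1, gamma = 0
#' all weights are equal and the result is exactly [build_grm()].
#'
#' @param G a [genotype_matrix()].
#' @param arch an [architecture_params()] (ld_scores aligned to `G$snp_ids`).
#' @param label kernel label.
#' @param normalize `"weights"` (divide by sum(v); exact reduction to the
#'   plain GRM at the equal-weight architecture) or `"trace"` (rescale so the
#'   mean diagonal is exactly 1).
#' @return a [kernel_matrix()].
#' @export
build_weighted_grm <- function(G, arch, label = "genome",
                               normalize = c("weights", "trace")) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(arch, "architecture_params"))
  normalize <- match.arg(normalize)
  v <- architecture_weights(arch, G$maf)
  W <- standardize_genotypes(G)
  K <- tcrossprod(sweep(W, 2, sqrt(v), "*")) / sum(v)
  if (normalize == "trace") K <- K / mean(diag(K))
  kernel_matrix(K, sample_ids = G$sample_ids, label = label)
}

#' Transcriptomic relationship matrix (TRM)
#'
#' Builds T = Q Q'/p from column-standardized expression values. Because the
#' standardization uses the realized (divisor-n) standard deviation, the mean
#' diagonal is exactly 1.
#'
#' @param E an [expression_matrix()].
#' @param label kernel label (default "transcriptome").
#' @return a [kernel_matrix()].
#' @export
build_trm <- function(E, label = "transcriptome") {
  stopifnot(inherits(E, "expression_matrix"))
  Q <- E$values
  kernel_matrix(tcrossprod(Q) / ncol(Q), sample_ids = E$sample_ids,
                label = label, diag_tol = 1e-6)
}

#' Windowed LD scores
#'
#' w_i = 1 + sum of squared Pearson correlations r^2 between SNP i and every
#' other SNP within `window_snps` positions on either side (position order,
#' not base pairs). Degenerate window 0 gives all scores exactly 1.
#'
#' @param G a [genotype_matrix()].
#' @param window_snps nonnegative window half-width in SNP positions
#'   (default 100).
#' @return numeric vector of per-SNP LD scores, each >= 1.
#' @export
compute_ld_scores <- function(G, window_snps = 100) {
  stopifnot(inherits(G, "genotype_matrix"), window_snps >= 0)
  m <- ncol(G$dosages)
  w <- rep(1, m)
  if (window_snps == 0 || m < 2) return(w)
  X <- scale(G$dosages)  # sample-sd scale; r^2 is scale-free
  ord <- order(G$positions)
  pos <- G$positions[ord]
  X <- X[, ord, drop = FALSE]
  w_ord <- rep(1, m)
  for (i in seq_len(m)) {
    lo <- i
    while (lo > 1 && pos[i] - pos[lo - 1] <= window_snps) lo <- lo - 1
    hi <- i
    while (hi < m && pos[hi + 1] - pos[i] <= window_snps) hi <- hi + 1
    nb <- setdiff(lo:hi, i)
    if (length(nb))
      w_ord[i] <- 1 + sum(stats::cor(X[, i], X[, nb, drop = FALSE])^2)
  }
  w[ord] <- w_ord
  w
}

#' Cholesky root of a kernel
#'
#' Lower-triangular L with L L' = K + jitter * I. Jitter starts at 0 and, on
#' factorization failure only, escalates through 1e-10, 1e-8, 1e-6, 1e-4
#' times the mean diagonal; any nonzero jitter is reported via a message and
#' recorded in the result.
#'
#' @param K a [kernel_matrix()].
#' @return object of class `kernel_root` with lower-triangular `values`,
#'   `jitter_used`, `source_label`, `sample_ids`.
#' @export
cholesky_root <- function(K) {
  stopifnot(inherits(K, "kernel_matrix"))
  md <- mean(diag(K$values))
  ladder <- c(0, 1e-10, 1e-8, 1e-6, 1e-4) * md
  n <- nrow(K$values)
  for (j in ladder) {
    R <- tryCatch(chol(K$values + diag(j, n)), error = function(e) NULL)
    if (!is.null(R)) {
      if (j > 0)
        message(sprintf("cholesky_root('%s'): jitter %.3e added", K$label, j))
      return(structure(list(values = t(R), jitter_used = j,
                            source_label = K$label, sample_ids = K$sample_ids),
                       class = "kernel_root"))
    }
  }
  ev <- min(eigen(K$values, symmetric = TRUE, only.values = TRUE)$values)
  stop(sprintf("Cholesky failed for '%s' at maximum jitter %.3e; smallest eigenvalue %.3e",
               K$label, max(ladder), ev))
}

#' @export
print.kernel_root <- function(x, ...) {
  cat(sprintf("kernel_root of '%s': %d x %d lower-triangular, jitter %.1e\n",
              x$source_label, nrow(x$values), ncol(x$values), x$jitter_used))
  invisible(x)
}

#' Symmetrized cross-kernel between two components
#'
#' B_ij = L_i L_j' + (L_i L_j')', the design matrix that carries the
#' covariance parameter between the random effects of components i and j in
#' the phenotypic covariance. Exactly symmetric by construction; crossing a
#' root with itself gives 2 K.
#'
#' @param Li,Lj [cholesky_root()] objects on the same samples, same order.
#' @return object of class `cross_kernel` with `values` and `pair`.
#' @export
cross_term <- function(Li, Lj) {
  stopifnot(inherits(Li, "kernel_root"), inherits(Lj, "kernel_root"))
  if (!identical(Li$sample_ids, Lj$sample_ids))
    stop("kernel roots are not on the same sample ordering")
  M <- tcrossprod(Li$values, Lj$values)
  structure(list(values = M + t(M), pair = c(Li$source_label, Lj$source_label),
                 sample_ids = Li$sample_ids),
            class = "cross_kernel")
}

#' @export
print.cross_kernel <- function(x, ...) {
  cat(sprintf("cross_kernel (%s, %s): %d x %d\n",
              x$pair[1], x$pair[2], nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Correlation between off-diagonal kernel entries
#'
#' Pearson correlation over the strictly-lower-triangle entries of two
#' kernels on the same samples; a simple similarity summary between kernels.
#'
#' @param Ki,Kj [kernel_matrix()] objects, same samples, same order.
#' @return scalar in [-1, 1].
#' @export
kernel_offdiag_correlation <- function(Ki, Kj) {
  stopifnot(inherits(Ki, "kernel_matrix"), inherits(Kj, "kernel_matrix"))
  if (!identical(Ki$sample_ids, Kj$sample_ids))
    stop("kernels are not on the same sample set/order")
  lt <- lower.tri(Ki$values)
  stats::cor(Ki$values[lt], Kj$values[lt])
}
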