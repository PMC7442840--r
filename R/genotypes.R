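#' Genotype matrix container
#'
#' Wraps an n x m matrix of allele dosages in [0, 2] together with sample and
#' SNP identifiers. Missing dosages are imputed to the column mean 2f before
#' anything downstream sees them, so kernel construction always operates on a
#' complete matrix. Minor allele frequencies are recomputed from the dosages.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns, values in
#'   [0, 2]; `NA` allowed (mean-imputed).
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to rownames or `S1..Sn`.
#' @param snp_ids character vector of unique SNP identifiers; defaults to
#'   colnames or `snp1..snpm`.
#' @param positions optional integer base-pair positions (used for LD windows
#'   and PLINK export); defaults to the column index.
#' @param chromosomes optional chromosome codes per SNP (default 1).
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `sample_ids`, `snp_ids`, `positions`, `chromosomes`, `maf`.
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, snp_ids = NULL,
                            positions = NULL, chromosomes = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (n < 1L || m < 1L) stop("genotype matrix must have at least 1 sample and 1 SNP")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  if (is.null(snp_ids)) {
    snp_ids <- colnames(dosages)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids")
  if (length(sample_ids) != n) stop("sample_ids length mismatch")
  if (length(snp_ids) != m) stop("snp_ids length mismatch")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  # mean-impute missing dosages (equals 2f under the realized frequency)
  if (anyNA(dosages)) {
    cm <- colMeans(dosages, na.rm = TRUE)
    idx <- which(is.na(dosages), arr.ind = TRUE)
    dosages[idx] <- cm[idx[, 2]]
  }
  freq <- colMeans(dosages) / 2
  if (is.null(positions)) positions <- seq_len(m)
  if (is.null(chromosomes)) chromosomes <- rep(1L, m)
  dimnames(dosages) <- list(sample_ids, snp_ids)
  structure(
    list(dosages = dosages, sample_ids = sample_ids, snp_ids = snp_ids,
         positions = as.integer(positions), chromosomes = chromosomes,
         maf = pmin(freq, 1 - freq), freq = freq),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs; MAF range [%.4f, %.4f]\n",
              nrow(x$dosages), ncol(x$dosages), min(x$maf), max(x$maf)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param G a [genotype_matrix()].
#' @param samples sample indices or ids to keep (default all).
#' @param snps SNP indices or ids to keep (default all).
#' @return a `genotype_matrix` on the selected rows/columns, with allele
#'   frequencies recomputed.
#' @export
subset_genotypes <- function(G, samples = NULL, snps = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(G$sample_ids) else
    if (is.character(samples)) match(samples, G$sample_ids) else samples
  vi <- if (is.null(snps)) seq_along(G$snp_ids) else
    if (is.character(snps)) match(snps, G$snp_ids) else snps
  if (anyNA(si)) stop("unknown sample ids in subset")
  if (anyNA(vi)) stop("unknown SNP ids in subset")
  genotype_matrix(G$dosages[si, vi, drop = FALSE],
                  sample_ids = G$sample_ids[si], snp_ids = G$snp_ids[vi],
                  positions = G$positions[vi], chromosomes = G$chromosomes[vi])
}

#' Column-standardized genotype matrix W
#'
#' Standardizes each SNP column as (x - 2f) / sqrt(2 f (1 - f)) with f the
#' realized allele frequency, the scaling under which W W'/m is the genomic
#' relationship matrix.
#'
#' @param G a [genotype_matrix()].
#' @return n x m numeric matrix.
#' @keywords internal
standardize_genotypes <- function(G) {
  f <- G$freq
  if (any(f <= 0 | f >= 1)) {
    bad <- G$snp_ids[which(f <= 0 | f >= 1)]
    stop("monomorphic SNP(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  sweep(sweep(G$dosages, 2, 2 * f, "-"), 2, sqrt(2 * f * (1 - f)), "/")
}

#' Expression matrix container
#'
#' Holds an n x p matrix of (imputed) expression levels. Columns are
#' standardized to mean 0 and population (divisor-n) variance 1 before kernel
#' construction; constant columns carry no information and are dropped with a
#' message. Gene-by-tissue combinations are treated as distinct columns.
#'
#' @param values numeric matrix, samples in rows, genes (or gene_tissue
#'   labels) in columns.
#' @param sample_ids,gene_ids identifiers; default to dimnames.
#' @return An object of class `expression_matrix` with standardized `values`,
#'   `sample_ids`, `gene_ids`, and `dropped` (ids of constant columns).
#' @export
expression_matrix <- function(values, sample_ids = NULL, gene_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyNA(values)) stop("expression matrix contains missing values")
  mu <- colMeans(values)
  sd_pop <- sqrt(colMeans(sweep(values, 2, mu, "-")^2))
  constant <- sd_pop < 1e-12
  dropped <- gene_ids[constant]
  if (all(constant)) stop("all expression columns are constant")
  if (any(constant)) {
    message(sprintf("dropping %d constant expression column(s)", sum(constant)))
    values <- values[, !constant, drop = FALSE]
    mu <- mu[!constant]; sd_pop <- sd_pop[!constant]
    gene_ids <- gene_ids[!constant]
  }
  values <- sweep(sweep(values, 2, mu, "-"), 2, sd_pop, "/")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 gene_ids = gene_ids, dropped = dropped),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d genes (%d constant dropped)\n",
              nrow(x$values), ncol(x$values), length(x$dropped)))
  invisible(x)
}
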