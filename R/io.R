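#' SNP quality control
#'
#' Filters SNPs on minor allele frequency, call rate, and Hardy-Weinberg
#' equilibrium (chi-square test on rounded genotype counts), in that report
#' order; a SNP failing several filters is reported once with every reason.
#' Operates on a raw dosage matrix (NA = missing) so call rate is observable;
#' the surviving SNPs are returned as a [genotype_matrix()] (mean-imputed).
#'
#' @param dosages n x m numeric matrix with NA for missing calls, or a
#'   [genotype_matrix()] (then call rate is 1 everywhere).
#' @param maf_min MAF threshold (default 0.01; SNPs strictly below are
#'   removed).
#' @param call_rate_min call-rate threshold (default 0.95).
#' @param hwe_p_min HWE p-value threshold (default 1e-4).
#' @param sample_ids,snp_ids,positions passed through to [genotype_matrix()].
#' @return list with `genotypes` (retained SNPs) and `report` (data.frame of
#'   excluded SNPs and comma-separated reasons).
#' @export
qc_genotypes <- function(dosages, maf_min = 0.01, call_rate_min = 0.95,
                         hwe_p_min = 1e-4, sample_ids = NULL, snp_ids = NULL,
                         positions = NULL) {
  if (inherits(dosages, "genotype_matrix")) {
    G <- dosages
    dosages <- G$dosages
    sample_ids <- G$sample_ids; snp_ids <- G$snp_ids; positions <- G$positions
  }
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(snp_ids)) snp_ids <- colnames(dosages)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  if (!(maf_min >= 0 && maf_min < 0.5) || !(call_rate_min >= 0 && call_rate_min <= 1) ||
      !(hwe_p_min >= 0 && hwe_p_min < 1))
    stop("QC thresholds out of range")
  call_rate <- colMeans(!is.na(dosages))
  f <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  hwe_p <- vapply(seq_len(m), function(j) {
    g <- round(dosages[!is.na(dosages[, j]), j])
    counts <- tabulate(g + 1L, nbins = 3L)
    nn <- sum(counts)
    fj <- (2 * counts[3] + counts[2]) / (2 * nn)
    if (fj <= 0 || fj >= 1) return(1)
    expct <- nn * c((1 - fj)^2, 2 * fj * (1 - fj), fj^2)
    x2 <- sum((counts - expct)^2 / expct)
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
  }, 0)
  reasons <- lapply(seq_len(m), function(j) {
    r <- character(0)
    if (maf[j] < maf_min) r <- c(r, "MAF")
    if (call_rate[j] < call_rate_min) r <- c(r, "call_rate")
    if (hwe_p[j] < hwe_p_min) r <- c(r, "HWE")
    r
  })
  drop <- lengths(reasons) > 0
  report <- data.frame(snp = snp_ids[drop],
                       reason = vapply(reasons[drop], paste, "", collapse = ","),
                       maf = maf[drop], call_rate = call_rate[drop],
                       hwe_p = hwe_p[drop])
  keep <- which(!drop)
  if (!length(keep)) stop("no SNPs survive QC")
  G <- genotype_matrix(dosages[, keep, drop = FALSE],
                       sample_ids = sample_ids, snp_ids = snp_ids[keep],
                       positions = if (!is.null(positions)) positions[keep])
  list(genotypes = G, report = report)
}

#' Phenotype preprocessing: covariate adjustment, standardization, trimming
#'
#' Applies, in exactly this order: (1) ordinary-least-squares adjustment for
#' the declared covariates (with intercept); (2) standardization of the
#' residuals to mean 0 and SD 1; (3) removal of observations outside +-3 SD
#' of the mean. Dropped samples are to be removed downstream everywhere
#' (kernels, genotypes) so everything stays aligned.
#'
#' @param table data.frame with a sample id column, the phenotype, and
#'   covariate columns.
#' @param phenotype name of the phenotype column.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param id name of the sample id column (default first column).
#' @param sd_limit trimming bound in SDs (default 3).
#' @return list with `phenotype` (named numeric vector of retained samples),
#'   `dropped` (ids removed by trimming), `report`.
#' @export
preprocess_phenotype <- function(table, phenotype, covariates = character(0),
                                 id = names(table)[1], sd_limit = 3) {
  stopifnot(is.data.frame(table))
  ids <- as.character(table[[id]])
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  y <- table[[phenotype]]
  complete <- stats::complete.cases(table[, c(phenotype, covariates), drop = FALSE])
  if (length(covariates)) {
    if (nrow(table) <= length(covariates) + 2)
      stop("too few samples for covariate adjustment")
    form <- stats::reformulate(covariates, response = phenotype)
    fitlm <- stats::lm(form, data = table[complete, , drop = FALSE])
    res <- stats::residuals(fitlm)
  } else {
    res <- y[complete] - mean(y[complete])
  }
  res <- drop(scale(res))
  keep <- abs(res) <= sd_limit
  out <- stats::setNames(res[keep], ids[complete][keep])
  list(phenotype = out,
       dropped = ids[complete][!keep],
       report = list(n_input = nrow(table), n_incomplete = sum(!complete),
                     n_trimmed = sum(!keep), sd_limit = sd_limit,
                     covariates = covariates))
}

#' Rank-based inverse normal transform
#'
#' value_i = qnorm((rank_i - 3/8) / (n + 1/4)) with Blom's offset; ties get
#' the mean rank.
#'
#' @param values numeric vector, length >= 3.
#' @return transformed vector (names preserved).
#' @export
inverse_normal_transform <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  r <- rank(values, ties.method = "average")
  out <- stats::qnorm((r - 3 / 8) / (length(values) + 1 / 4))
  names(out) <- names(values)
  out
}

#' Write a kernel in GCTA GRM binary triplet format
#'
#' Writes `<prefix>.grm.bin` (float32 lower triangle including the diagonal,
#' row-major over pairs (i, j <= i)), `<prefix>.grm.N.bin` (float32 SNP
#' counts per pair), and `<prefix>.grm.id` (family and individual id
#' columns, tab-separated).
#'
#' @param K a [kernel_matrix()].
#' @param prefix file path prefix.
#' @param n_snps SNP count recorded per pair (default 1).
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(K, prefix, n_snps = 1) {
  stopifnot(inherits(K, "kernel_matrix"))
  n <- nrow(K$values)
  idx <- which(row(K$values) >= col(K$values))
  idx <- idx[order(row(K$values)[idx], col(K$values)[idx])]
  vals <- K$values[idx]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(n_snps), length(vals)), con, size = 4,
           endian = "little")
  close(con)
  utils::write.table(data.frame(K$sample_ids, K$sample_ids),
                     paste0(prefix, ".grm.id"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read a GCTA GRM binary triplet
#'
#' @param prefix file path prefix (expects `.grm.bin`, `.grm.N.bin`,
#'   `.grm.id`).
#' @param label kernel label.
#' @param check run kernel validity checks (default FALSE: float32 storage
#'   and external GRMs need not satisfy the standardized-kernel invariants).
#' @return a [kernel_matrix()]; attribute `"n_snps"` carries the per-pair
#'   SNP counts.
#' @export
read_grm <- function(prefix, label = "genome", check = FALSE) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           colClasses = "character")[[2]]
  n <- length(ids)
  np <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  vals <- readBin(con, "numeric", n = np, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "rb")
  nsnp <- readBin(con, "numeric", n = np, size = 4, endian = "little")
  close(con)
  K <- matrix(0, n, n)
  K[upper.tri(K, diag = TRUE)] <- vals  # column-major upper == row-major lower
  K <- K + t(K) - diag(diag(K))
  out <- kernel_matrix(K, sample_ids = ids, label = label, check = check,
                       diag_tol = Inf)
  attr(out, "n_snps") <- nsnp
  out
}

# PLINK .bed 2-bit codes (SNP-major): 00 = hom first allele (dosage 2),
# 10 = het (1), 11 = hom second allele (0), 01 = missing.
plink_code <- c(`2` = 0L, `1` = 2L, `0` = 3L)
plink_decode <- c(2, NA, 1, 0)  # index by code + 1

#' Write genotypes as a PLINK BED/BIM/FAM triplet
#'
#' SNP-major bed mode (magic bytes 0x6c, 0x1b, 0x01). Dosages are rounded to
#' hard calls; the stored allele count refers to the A1 allele.
#'
#' @param G a [genotype_matrix()].
#' @param prefix file path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$dosages)
  m <- ncol(G$dosages)
  hard <- round(G$dosages)
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  npad <- ceiling(n / 4) * 4
  for (j in seq_len(m)) {
    codes <- plink_code[as.character(hard[, j])]
    codes <- c(codes, rep(0L, npad - n))
    q <- matrix(codes, nrow = 4)
    bytes <- q[1, ] + q[2, ] * 4L + q[3, ] * 16L + q[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  close(con)
  utils::write.table(
    data.frame(G$chromosomes, G$snp_ids, 0L, G$positions, "A", "G"),
    paste0(prefix, ".bim"), sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(G$sample_ids, G$sample_ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read a PLINK BED/BIM/FAM triplet
#'
#' Honors the SNP-major magic bytes; missing calls become NA and are
#' mean-imputed by the [genotype_matrix()] constructor.
#'
#' @param prefix file path prefix.
#' @return a [genotype_matrix()] with ids and positions from the BIM/FAM.
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), colClasses = "character")
  bim <- utils::read.table(paste0(prefix, ".bim"), colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  magic <- readBin(con, "raw", n = 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK bed file")
  bpv <- ceiling(n / 4)
  D <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    bytes <- as.integer(readBin(con, "raw", n = bpv))
    codes <- c(rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                     (bytes %/% 16L) %% 4L, bytes %/% 64L))
    D[, j] <- plink_decode[codes[seq_len(n)] + 1L]
  }
  close(con)
  genotype_matrix(D, sample_ids = fam[[2]], snp_ids = bim[[2]],
                  positions = as.integer(bim[[4]]),
                  chromosomes = bim[[1]])
}

#' Read a phenotype/covariate TSV
#'
#' Tab-separated, header row, first column the sample id, '.' for missing.
#'
#' @param path file path.
#' @return data.frame with character ids and numeric columns.
#' @export
read_phenotype_tsv <- function(path) {
  tab <- utils::read.delim(path, na.strings = c("NA", "."),
                           colClasses = "character", check.names = FALSE)
  for (j in seq_along(tab)[-1]) tab[[j]] <- as.numeric(tab[[j]])
  tab
}

#' Read an expression TSV (sample id column, gene columns)
#' @param path file path.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  tab <- read_phenotype_tsv(path)
  expression_matrix(as.matrix(tab[, -1, drop = FALSE]),
                    sample_ids = as.character(tab[[1]]),
                    gene_ids = names(tab)[-1])
}

#' Align data structures on their common samples
#'
#' Intersects sample id sets (order taken from the first argument) and
#' reports what every source dropped; modules downstream assume pre-aligned
#' inputs, so alignment happens once, here.
#'
#' @param ... named sample id character vectors.
#' @return list with `ids` (common, in first-source order) and `dropped`
#'   (named list of ids each source loses).
#' @export
align_samples <- function(...) {
  sets <- list(...)
  if (length(sets) < 2) stop("need at least two id sets")
  common <- Reduce(intersect, sets)
  if (!length(common)) stop("no samples in common")
  ids <- sets[[1]][sets[[1]] %in% common]
  dropped <- lapply(sets, function(s) setdiff(s, common))
  message(sprintf("sample alignment: %d common; dropped %s", length(ids),
                  paste(lengths(dropped), collapse = "/")))
  list(ids = ids, dropped = dropped)
}

#' Write a fit report (TSV + JSON twin)
#'
#' @param fit a [fit_reml()] result.
#' @param prefix output path prefix (writes `<prefix>.tsv` and
#'   `<prefix>.json`).
#' @param meta optional named list merged into the JSON (config hash, seed).
#' @return `prefix`, invisibly.
#' @export
write_fit_report <- function(fit, prefix, meta = list()) {
  stopifnot(inherits(fit, "reml_fit"))
  se <- if (!is.null(fit$param_cov)) sqrt(pmax(diag(fit$param_cov), 0))
        else rep(NA_real_, length(fit$theta))
  tab <- data.frame(parameter = names(fit$theta),
                    estimate = unname(fit$theta), se = unname(se))
  utils::write.table(tab, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  payload <- c(list(estimates = as.list(fit$theta), se = as.list(se),
                    loglik = fit$loglik, iterations = fit$iterations,
                    converged = fit$converged, n = fit$n,
                    events = fit$events), meta)
  jsonlite::write_json(payload, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a key-value run configuration
#'
#' One `key = value` (or `key<TAB>value`) pair per line; `#` comments and
#' blank lines ignored. Values are numeric when they parse as numbers,
#' comma-split vectors otherwise.
#'
#' @param path file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=\t]", fixed = FALSE)[[1]]
    if (length(kv) < 2) stop("bad config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else parts
  }
  out
}
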