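#' Likelihood-ratio test between nested REML fits
#'
#' statistic = 2 (logL_alt - logL_null), compared to a chi-square with df
#' equal to the number of freed parameters (1 for a single covariance term).
#' A negative statistic beyond numerical tolerance indicates an optimizer
#' failure on the alternative model and is flagged, not silently clipped.
#'
#' @param fit_alt,fit_null converged [fit_reml()] results, null nested in
#'   alternative.
#' @param df degrees of freedom; defaults to the difference in parameter
#'   counts.
#' @return object of class `test_result` with `kind`, `statistic`, `df`,
#'   `pvalue`, `null_model`, `alt_model`.
#' @export
lrt <- function(fit_alt, fit_null, df = NULL) {
  stopifnot(inherits(fit_alt, "reml_fit"), inherits(fit_null, "reml_fit"))
  if (is.null(df)) df <- length(fit_alt$theta) - length(fit_null$theta)
  if (df < 1) stop("alternative model must free at least one parameter")
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (stat < -1e-6)
    warning(sprintf("logL(alt) < logL(null) by %.3e: optimizer failure on the alternative model", -stat / 2))
  stat <- max(stat, 0)
  structure(list(kind = "LRT", statistic = stat, df = df,
                 pvalue = stats::pchisq(stat, df = df, lower.tail = FALSE),
                 null_model = "null", alt_model = "alt"),
            class = "test_result")
}

#' Wald test for a single parameter
#'
#' statistic = (estimate / se)^2 against chi-square(1); two-sided.
#'
#' @param estimate parameter estimate.
#' @param se its standard error (> 0).
#' @return a `test_result`.
#' @export
wald_test <- function(estimate, se) {
  if (!is.finite(se) || se <= 0) stop("se must be positive")
  stat <- (estimate / se)^2
  structure(list(kind = "Wald", statistic = stat, df = 1,
                 pvalue = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 null_model = "parameter = 0", alt_model = "free parameter"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4f, df %d, p = %.4g\n",
              x$kind, x$statistic, x$df, x$pvalue))
  invisible(x)
}

#' Total phenotypic variance implied by the parameters
#'
#' sigma^2_y = sum_i sigma^2_i + 2 sum_(i<j) sigma_ij + sigma^2_e; every free
#' covariance enters twice because each cross-kernel contributes B_ij = 2 K
#' at unit similarity.
#'
#' @param params a [variance_params()].
#' @return scalar.
#' @export
total_phenotypic_variance <- function(params) {
  stopifnot(inherits(params, "variance_params"))
  sum(params$var) + 2 * sum(params$cov) + params$resid
}

# weights of sigma^2_y as a linear combination of theta (1 on variances and
# residual, 2 on covariances)
sigma_y_weights <- function(spec) {
  c(rep(1, length(spec$components)), rep(2, length(spec$free_covariances)), 1)
}

#' Heritability (variance proportion) of a component with delta-method SE
#'
#' value = sigma^2_i / sigma^2_y. The sampling variance follows the delta
#' method: var(h^2) = h^4 [ var(s_i)/s_i^2 - 2 cov(s_i, s_y)/(s_i s_y)
#' + var(s_y)/s_y^2 ] with s_i = sigma^2_i, s_y = sigma^2_y, where var(s_y)
#' and cov(s_i, s_y) follow from sigma^2_y being linear in the parameters
#' (weight 2 on covariances) and the inverse average-information matrix.
#'
#' @param fit a converged [fit_reml()].
#' @param component_label which component (use `"residual"` for the residual
#'   proportion).
#' @return object of class `derived_estimate` with `name`, `value`, `se`
#'   (NA with a flag if the parameter covariance is unavailable).
#' @export
heritability <- function(fit, component_label) {
  stopifnot(inherits(fit, "reml_fit"))
  spec <- fit$spec
  nm <- if (component_label == "residual") "var:residual"
        else paste0("var:", component_label)
  if (!nm %in% names(fit$theta)) stop("unknown component '", component_label, "'")
  s_i <- fit$theta[[nm]]
  s_y <- total_phenotypic_variance(fit$params)
  h2 <- s_i / s_y
  if (is.null(fit$param_cov)) {
    warning("parameter covariance unavailable; SE undefined")
    se <- NA_real_
  } else {
    a <- sigma_y_weights(spec)
    C <- fit$param_cov
    i <- match(nm, names(fit$theta))
    var_si <- C[i, i]
    var_sy <- drop(a %*% C %*% a)
    cov_si_sy <- drop(C[i, ] %*% a)
    v <- h2^2 * (var_si / s_i^2 - 2 * cov_si_sy / (s_i * s_y) + var_sy / s_y^2)
    se <- sqrt(max(v, 0))
  }
  structure(list(name = paste0("h2:", component_label), value = h2, se = se,
                 components = nm),
            class = "derived_estimate")
}

#' Correlation between two random effects with delta-method SE
#'
#' r_ij = sigma_ij / sqrt(sigma^2_i sigma^2_j). The sampling variance is
#' var(r) = r^2 [ var(s_i)/(4 s_i^2) + var(s_j)/(4 s_j^2) + var(c)/c^2
#' + cov(s_i, s_j)/(2 s_i s_j) - cov(s_i, c)/(s_i c) - cov(s_j, c)/(s_j c) ]
#' with c = sigma_ij, using the six cells of the inverse average-information
#' matrix. Values outside [-1, 1] can occur through estimation noise and are
#' flagged, not truncated.
#'
#' @param fit a converged [fit_reml()].
#' @param pair character vector of the two component labels.
#' @return a `derived_estimate` (with `out_of_range` flag).
#' @export
effect_correlation <- function(fit, pair) {
  stopifnot(inherits(fit, "reml_fit"), length(pair) == 2)
  pair <- sort(as.character(pair))
  cn <- paste0("cov:", paste(pair, collapse = ":"))
  vn <- paste0("var:", pair)
  if (!cn %in% names(fit$theta)) stop("pair has no free covariance in this fit")
  s_i <- fit$theta[[vn[1]]]; s_j <- fit$theta[[vn[2]]]; cc <- fit$theta[[cn]]
  floor_v <- 1e-5 * total_phenotypic_variance(fit$params)
  if (s_i <= floor_v || s_j <= floor_v)
    stop("a variance estimate is at its floor; correlation undefined")
  r <- cc / sqrt(s_i * s_j)
  se <- NA_real_
  if (!is.null(fit$param_cov)) {
    C <- fit$param_cov[c(vn, cn), c(vn, cn)]
    v <- r^2 * (C[1, 1] / (4 * s_i^2) + C[2, 2] / (4 * s_j^2) + C[3, 3] / cc^2 +
                C[1, 2] / (2 * s_i * s_j) - C[1, 3] / (s_i * cc) -
                C[2, 3] / (s_j * cc))
    se <- sqrt(max(v, 0))
  } else warning("parameter covariance unavailable; SE undefined")
  structure(list(name = paste0("r:", paste(pair, collapse = ":")), value = r,
                 se = se, out_of_range = abs(r) > 1,
                 components = c(vn, cn)),
            class = "derived_estimate")
}

#' @export
print.derived_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f (se %.4f)%s\n", x$name, x$value, x$se,
              if (isTRUE(x$out_of_range)) "  [outside [-1,1]: estimation noise]" else ""))
  invisible(x)
}

#' Proportions of total genetic variance by region
#'
#' proportion_i = (sigma^2_i + sum_j sigma_ij) / (sum_i sigma^2_i +
#' 2 sum_(i<j) sigma_ij): each covariance is split evenly between its two
#' regions, so the proportions always sum to 1. The SNP-count shares, when
#' supplied, give the expected proportions under an equal-contribution
#' architecture.
#'
#' @param fit a converged [fit_reml()].
#' @param region_labels components to include (default: all).
#' @param snp_counts optional named SNP counts per region for the expected
#'   baseline.
#' @return data.frame with region, variance, covariance share, proportion,
#'   and (optionally) the SNP-share baseline.
#' @export
genetic_variance_proportions <- function(fit, region_labels = NULL,
                                         snp_counts = NULL) {
  stopifnot(inherits(fit, "reml_fit"))
  spec <- fit$spec
  if (is.null(region_labels)) region_labels <- spec$components
  v <- fit$params$var[region_labels]
  cshare <- stats::setNames(numeric(length(region_labels)), region_labels)
  for (j in seq_along(spec$free_covariances)) {
    p <- spec$free_covariances[[j]]
    if (all(p %in% region_labels)) {
      cshare[p[1]] <- cshare[p[1]] + fit$params$cov[j]
      cshare[p[2]] <- cshare[p[2]] + fit$params$cov[j]
    }
  }
  total <- sum(v) + sum(cshare)
  if (total <= 0) stop("total genetic variance is not positive")
  out <- data.frame(region = region_labels, variance = unname(v),
                    covariance_share = unname(cshare),
                    proportion = unname((v + cshare) / total))
  if (!is.null(snp_counts))
    out$snp_share <- unname(snp_counts[region_labels] / sum(snp_counts))
  out
}

#' Likelihood ranking over candidate genetic architectures
#'
#' Fits the same phenotype under each candidate kernel set (typically one
#' per (alpha, gamma) architecture) and ranks candidates by restricted
#' log-likelihood, ties broken by fewer parameters. Likelihood differences
#' across architectures diagnose misspecification.
#'
#' @param y phenotype vector.
#' @param candidates named list; each element a list with `spec`
#'   (a [model_spec()]) and `kernels` (named kernel list), optionally
#'   `crosses` and `X`.
#' @param control a [reml_control()].
#' @return data.frame ranked by logL (fits attached as attribute `"fits"`).
#' @export
architecture_grid <- function(y, candidates, control = reml_control()) {
  if (!length(candidates)) stop("no candidates")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model", seq_along(candidates))
  fits <- lapply(candidates, function(cand)
    fit_reml(cand$spec, y, kernels = cand$kernels, crosses = cand$crosses,
             X = cand$X, control = control))
  tab <- data.frame(
    model = names(candidates),
    loglik = vapply(fits, function(f) f$loglik, 0),
    n_params = vapply(fits, function(f) length(f$theta), 0L),
    converged = vapply(fits, function(f) f$converged, TRUE)
  )
  ord <- order(-tab$loglik, tab$n_params, tab$model)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Bonferroni adjustment over a declared test family
#'
#' Pure post-processing: multiplies p-values by the family size (capped at
#' 1). The family is user-declared, never inferred.
#'
#' @param pvalues numeric vector of p-values in one family.
#' @param family_size family size (default `length(pvalues)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(pvalues, family_size = length(pvalues)) {
  pmin(1, pvalues * family_size)
}
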