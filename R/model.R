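#' Model specification for multi-kernel variance partitioning
#'
#' Declares which relationship kernels enter the model, which covariance
#' terms between random effects are free parameters, and the fixed-effect
#' design. The residual component (identity kernel) is always present. With
#' `free_covariances = list()` the model is plain GREML; freeing every pair
#' gives the full covariance-between-random-effects model.
#'
#' @param components ordered character vector of kernel labels.
#' @param free_covariances list of length-2 character vectors, each naming an
#'   unordered pair of distinct components whose effect covariance is a free
#'   parameter. `"all"` frees every pair.
#' @param X fixed-effect design matrix of full column rank, or NULL for
#'   intercept-only.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(components, free_covariances = list(), X = NULL) {
  components <- as.character(components)
  if (anyDuplicated(components)) stop("duplicate component labels")
  if (identical(free_covariances, "all")) {
    free_covariances <- utils::combn(components, 2, simplify = FALSE)
    if (length(components) < 2) free_covariances <- list()
  }
  pairs <- lapply(free_covariances, function(p) {
    p <- as.character(p)
    if (length(p) != 2 || p[1] == p[2] || !all(p %in% components))
      stop("each free covariance must name two distinct listed components")
    sort(p)
  })
  if (anyDuplicated(vapply(pairs, paste, "", collapse = ":")))
    stop("duplicate covariance pairs")
  structure(list(components = components, free_covariances = pairs, X = X),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: %d component(s) [%s]; %d free covariance pair(s)%s\n",
              length(x$components), paste(x$components, collapse = ", "),
              length(x$free_covariances),
              if (length(x$free_covariances))
                paste0(" {", paste(vapply(x$free_covariances, paste, "",
                                          collapse = "-"), collapse = ", "), "}")
              else ""))
  invisible(x)
}

#' Variance/covariance parameter set
#'
#' Orders the parameters as the model spec does: component variances, then
#' free covariances (sign-unrestricted), then the residual variance.
#'
#' @param var named numeric vector of component variances (>= 0).
#' @param cov numeric vector of covariances, one per free pair (may be empty).
#' @param resid residual variance (> 0).
#' @param spec optional [model_spec()] for consistency checking.
#' @return object of class `variance_params`.
#' @export
variance_params <- function(var, cov = numeric(0), resid, spec = NULL) {
  if (any(var < 0)) stop("component variances must be nonnegative")
  if (resid <= 0) stop("residual variance must be positive")
  if (!is.null(spec)) {
    if (length(var) != length(spec$components) ||
        length(cov) != length(spec$free_covariances))
      stop("parameter counts do not match the model spec")
    if (is.null(names(var))) names(var) <- spec$components
    if (length(cov) && is.null(names(cov)))
      names(cov) <- vapply(spec$free_covariances, paste, "", collapse = ":")
  }
  structure(list(var = var, cov = cov, resid = resid),
            class = "variance_params")
}

#' Flatten variance parameters to the canonical ordering
#' @param params a [variance_params()].
#' @return numeric vector c(variances, covariances, residual).
#' @keywords internal
params_to_theta <- function(params) {
  c(params$var, params$cov, params$resid)
}

#' Inverse of [params_to_theta()]
#' @keywords internal
theta_to_params <- function(theta, spec) {
  k <- length(spec$components)
  p <- length(spec$free_covariances)
  variance_params(var = stats::setNames(theta[seq_len(k)], spec$components),
                  cov = if (p) stats::setNames(theta[k + seq_len(p)],
                          vapply(spec$free_covariances, paste, "", collapse = ":"))
                        else numeric(0),
                  resid = theta[k + p + 1], spec = spec)
}

#' Canonical parameter names for a model spec
#' @keywords internal
param_names <- function(spec) {
  c(paste0("var:", spec$components),
    if (length(spec$free_covariances))
      paste0("cov:", vapply(spec$free_covariances, paste, "", collapse = ":")),
    "var:residual")
}

#' Assemble the model-implied phenotypic covariance V
#'
#' V = sum_i K_i sigma^2_i + sum_(i,j) B_ij sigma_ij + I sigma^2_e, where the
#' B_ij are symmetrized Cholesky-root cross-kernels carrying the covariance
#' parameters.
#'
#' @param spec a [model_spec()].
#' @param params a [variance_params()] ordered as the spec.
#' @param kernels named list of [kernel_matrix()] objects covering
#'   `spec$components`, all sample-aligned.
#' @param crosses named list of [cross_kernel()] objects, one per free pair,
#'   names `"i:j"` with i, j sorted; computed from the kernels if NULL.
#' @return n x n symmetric covariance matrix.
#' @export
assemble_V <- function(spec, params, kernels, crosses = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(params, "variance_params"))
  if (!all(spec$components %in% names(kernels)))
    stop("kernels missing for: ",
         paste(setdiff(spec$components, names(kernels)), collapse = ", "))
  ids <- kernels[[spec$components[1]]]$sample_ids
  for (lab in spec$components)
    if (!identical(kernels[[lab]]$sample_ids, ids))
      stop("kernel '", lab, "' sample order mismatch")
  n <- length(ids)
  if (is.null(crosses) && length(spec$free_covariances))
    crosses <- build_crosses(spec, kernels)
  V <- diag(params$resid, n)
  for (i in seq_along(spec$components))
    V <- V + kernels[[spec$components[i]]]$values * params$var[i]
  for (j in seq_along(spec$free_covariances)) {
    key <- paste(spec$free_covariances[[j]], collapse = ":")
    B <- crosses[[key]]
    if (is.null(B)) stop("missing cross kernel for pair ", key)
    if (!identical(B$sample_ids, ids)) stop("cross kernel sample order mismatch")
    V <- V + B$values * params$cov[j]
  }
  V
}

#' Cross-kernels for every free pair of a model spec
#'
#' Takes one Cholesky root per component involved in a free pair and forms
#' the symmetrized cross-products. Expensive relative to a single fit, so
#' replicate drivers call it once and reuse the result.
#'
#' @param spec a [model_spec()].
#' @param kernels named list of [kernel_matrix()] objects.
#' @return named list of [cross_kernel()] objects, names `"i:j"` sorted.
#' @export
build_crosses <- function(spec, kernels) {
  labs <- unique(unlist(spec$free_covariances))
  roots <- lapply(labs, function(l) cholesky_root(kernels[[l]]))
  names(roots) <- labs
  out <- lapply(spec$free_covariances, function(p)
    cross_term(roots[[p[1]]], roots[[p[2]]]))
  names(out) <- vapply(spec$free_covariances, paste, "", collapse = ":")
  out
}
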