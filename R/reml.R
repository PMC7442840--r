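#' REML fitting control parameters
#'
#' @param tol_loglik convergence tolerance on the restricted log-likelihood
#'   change between accepted iterations (default 1e-6).
#' @param tol_param convergence tolerance on the largest parameter change
#'   (default 1e-6).
#' @param max_iter maximum iterations (default 100).
#' @param n_em number of initial EM iterations on the variance parameters
#'   (covariances held) before switching to average-information updates;
#'   EM is globally stable, AI fast near the optimum (default 3).
#' @param max_halving maximum step-halvings before falling back to an EM
#'   step (default 10).
#' @param var_floor_frac variance floor as a fraction of the phenotypic
#'   variance (default 1e-6); floor events are recorded.
#' @param verbose print per-iteration log-likelihoods.
#' @return list of class `reml_control`.
#' @export
reml_control <- function(tol_loglik = 1e-6, tol_param = 1e-6, max_iter = 100,
                         n_em = 3, max_halving = 10, var_floor_frac = 1e-6,
                         verbose = FALSE) {
  structure(list(tol_loglik = tol_loglik, tol_param = tol_param,
                 max_iter = max_iter, n_em = n_em, max_halving = max_halving,
                 var_floor_frac = var_floor_frac, verbose = verbose),
            class = "reml_control")
}

#' Precomputed fitting design for a model spec
#'
#' Collects everything a fit needs that does not depend on the phenotype:
#' the ordered list of covariance derivative matrices dV (component kernels,
#' cross-kernels, identity for the residual) and the fixed-effect design.
#' Replicate drivers build this once and fit many phenotype vectors on it.
#'
#' @param spec a [model_spec()].
#' @param kernels named list of [kernel_matrix()] objects.
#' @param crosses optional named list of [cross_kernel()] objects (`"i:j"`
#'   names, sorted); built from the kernels when NULL and needed.
#' @param X fixed-effect design matrix; NULL means intercept-only.
#' @return object of class `core_design`.
#' @export
core_design <- function(spec, kernels, crosses = NULL, X = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  ids <- kernels[[spec$components[1]]]$sample_ids
  n <- length(ids)
  for (lab in spec$components) {
    if (is.null(kernels[[lab]])) stop("missing kernel '", lab, "'")
    if (!identical(kernels[[lab]]$sample_ids, ids))
      stop("kernel '", lab, "' sample order mismatch")
  }
  if (is.null(crosses) && length(spec$free_covariances))
    crosses <- build_crosses(spec, kernels)
  if (is.null(X)) X <- if (!is.null(spec$X)) spec$X else matrix(1, n, 1)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X row count does not match kernels")
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
  if (ncol(X) > n - 1) stop("X has too many columns for n")
  dV <- vector("list", length(spec$components) + length(spec$free_covariances) + 1)
  for (i in seq_along(spec$components))
    dV[[i]] <- kernels[[spec$components[i]]]$values
  for (j in seq_along(spec$free_covariances)) {
    key <- paste(spec$free_covariances[[j]], collapse = ":")
    if (is.null(crosses[[key]])) stop("missing cross kernel for pair ", key)
    dV[[length(spec$components) + j]] <- crosses[[key]]$values
  }
  dV[[length(dV)]] <- NULL  # identity marker for the residual
  length(dV) <- length(spec$components) + length(spec$free_covariances) + 1
  structure(list(spec = spec, dV = dV, X = X, n = n, sample_ids = ids,
                 names = param_names(spec)),
            class = "core_design")
}

# dV helpers: NULL encodes the identity matrix (residual derivative)
dv_trace <- function(P, dv) if (is.null(dv)) sum(diag(P)) else sum(P * dv)
dv_mult <- function(dv, x) if (is.null(dv)) x else dv %*% x

assemble_V_theta <- function(design, theta) {
  V <- diag(theta[length(theta)], design$n)
  for (r in seq_len(length(theta) - 1)) V <- V + design$dV[[r]] * theta[r]
  V
}

# Restricted log-likelihood pieces from an upper Cholesky factor R of V.
# Returns logL = -1/2 [ln|V| + ln|X'V^-1 X| + y'Py] plus the solves reused
# by the fitter.
loglik_from_chol <- function(R, X, y) {
  ldetV <- 2 * sum(log(diag(R)))
  Viy <- backsolve(R, backsolve(R, y, transpose = TRUE))
  ViX <- backsolve(R, backsolve(R, X, transpose = TRUE))
  XtViX <- crossprod(X, ViX)
  cX <- chol(XtViX)
  ldetX <- 2 * sum(log(diag(cX)))
  XtViy <- crossprod(X, Viy)
  beta <- backsolve(cX, backsolve(cX, XtViy, transpose = TRUE))
  yPy <- sum(y * Viy) - sum(XtViy * beta)
  list(logL = -0.5 * (ldetV + ldetX + yPy), Viy = Viy, ViX = ViX,
       XtViX_chol = cX, beta = beta)
}

#' Restricted log-likelihood of a linear mixed model
#'
#' logL = -1/2 [ln|V| + ln|X'V^-1 X| + y'Py] with P the REML projection
#' matrix; evaluated through one Cholesky factorization of V (V itself is
#' never inverted explicitly).
#'
#' @param V n x n positive-definite covariance matrix.
#' @param X fixed-effect design of full column rank.
#' @param y phenotype vector.
#' @return scalar restricted log-likelihood (constant terms omitted).
#' @export
restricted_loglik <- function(V, X, y) {
  X <- as.matrix(X)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf("V is not positive definite (smallest eigenvalue %.3e)", ev))
  }
  loglik_from_chol(R, X, y)$logL
}

#' REML projection matrix
#'
#' P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1; symmetric, annihilates X, and
#' satisfies P V P = P. Materializes an n x n inverse, so intended for the
#' fitter's per-iteration derivatives and for small-n diagnostics.
#'
#' @inheritParams restricted_loglik
#' @return n x n symmetric projection matrix.
#' @export
projection_matrix <- function(V, X) {
  X <- as.matrix(X)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf("V is not positive definite (smallest eigenvalue %.3e)", ev))
  }
  Vinv <- chol2inv(R)
  ViX <- Vinv %*% X
  P <- Vinv - ViX %*% solve(crossprod(X, ViX), t(ViX))
  (P + t(P)) / 2
}

#' REML score vector and average-information matrix
#'
#' For each parameter r with derivative matrix dV_r, the score is
#' grad_r = -1/2 [tr(P dV_r) - y'P dV_r P y] and the average-information
#' entries are AI_rs = 1/2 y'P dV_r P dV_s P y. The derivative list is
#' ordered as the parameters: component kernels, cross-kernels, identity.
#'
#' @param P projection matrix from [projection_matrix()].
#' @param y phenotype vector.
#' @param dV_list list of derivative matrices; a NULL element encodes the
#'   identity matrix.
#' @return list with `gradient`, `ai` (symmetric), and the intermediate
#'   `traces` and `quads` (tr(P dV_r) and y'P dV_r P y) used by EM updates.
#' @export
score_and_ai <- function(P, y, dV_list) {
  q <- length(dV_list)
  Py <- drop(P %*% y)
  W <- matrix(0, length(y), q)
  traces <- quads <- numeric(q)
  for (r in seq_len(q)) {
    traces[r] <- dv_trace(P, dV_list[[r]])
    W[, r] <- dv_mult(dV_list[[r]], Py)
    quads[r] <- sum(Py * W[, r])
  }
  AI <- 0.5 * crossprod(W, P %*% W)
  AI <- (AI + t(AI)) / 2
  list(gradient = -0.5 * (traces - quads), ai = AI,
       traces = traces, quads = quads)
}

#' Fit a multi-kernel mixed model by AI-REML
#'
#' Maximizes the restricted likelihood over component variances, free effect
#' covariances, and the residual variance. The first `n_em` iterations use EM
#' updates on the variances (globally stable); later iterations take Newton
#' steps preconditioned by the average-information matrix, with step-halving
#' whenever a proposal loses positive-definiteness of V or decreases the
#' likelihood, and an EM fallback when halving is exhausted or AI is
#' singular. Variances are floored at `var_floor_frac * var(y)`; covariances
#' are unconstrained in sign, feasibility being enforced through positive
#' definiteness of V.
#'
#' @param spec a [model_spec()], or a [core_design()] in which case
#'   `kernels`/`crosses`/`X` are ignored.
#' @param y phenotype vector (sample-aligned with the kernels).
#' @param kernels named list of [kernel_matrix()] objects.
#' @param crosses optional precomputed cross-kernels.
#' @param X fixed-effect design; NULL for intercept-only.
#' @param init optional [variance_params()] starting values; the default
#'   splits var(y) evenly across components and residual, covariances 0.
#' @param control a [reml_control()].
#' @return object of class `reml_fit` with elements `params`
#'   ([variance_params()]), `theta` (named vector), `loglik`, `ai_matrix`,
#'   `param_cov` (inverse AI; NULL if singular), `gradient`, `iterations`,
#'   `converged`, `history`, `events`, `ai_singular`, `n`, `spec`, `beta`
#'   (GLS fixed effects at convergence).
#' @export
fit_reml <- function(spec, y, kernels = NULL, crosses = NULL, X = NULL,
                     init = NULL, control = reml_control()) {
  design <- if (inherits(spec, "core_design")) spec
            else core_design(spec, kernels, crosses, X)
  spec <- design$spec
  y <- as.numeric(y)
  n <- design$n
  if (length(y) != n) stop("phenotype length does not match kernels")
  q <- length(design$dV)
  k <- length(spec$components)
  np <- length(spec$free_covariances)
  if (n < q + ncol(design$X) + 1)
    stop("too few samples for the parameter count")
  vy <- stats::var(y)
  floor_v <- control$var_floor_frac * vy
  theta <- if (!is.null(init)) params_to_theta(init)
           else c(rep(vy / (k + 1), k), rep(0, np), vy / (k + 1))
  var_idx <- c(seq_len(k), q)          # floored, EM-updated
  cov_idx <- if (np) k + seq_len(np) else integer(0)
  events <- character(0)
  history <- numeric(0)

  chol_V <- function(th) {
    V <- assemble_V_theta(design, th)
    tryCatch(chol(V), error = function(e) NULL)
  }
  R <- chol_V(theta)
  if (is.null(R)) stop("initial V is not positive definite")
  ll <- loglik_from_chol(R, design$X, y)
  logL <- ll$logL
  history <- logL
  converged <- FALSE
  ai_singular <- FALSE
  sa <- NULL
  iter <- 0

  em_delta <- function(sa, th) {
    # EM-style update on variance-type parameters; covariances held
    d <- numeric(q)
    d[var_idx] <- th[var_idx]^2 * (sa$quads[var_idx] - sa$traces[var_idx]) / n
    d
  }

  for (iter in seq_len(control$max_iter)) {
    Vinv <- chol2inv(R)
    ViX <- Vinv %*% design$X
    P <- Vinv - ViX %*% solve(crossprod(design$X, ViX), t(ViX))
    P <- (P + t(P)) / 2
    sa <- score_and_ai(P, y, design$dV)

    if (iter <= control$n_em) {
      delta <- em_delta(sa, theta)
    } else {
      delta <- tryCatch(solve(sa$ai, sa$gradient), error = function(e) NULL)
      if (is.null(delta) || !all(is.finite(delta))) {
        ai_singular <- TRUE
        events <- c(events, sprintf("iter %d: AI singular, EM fallback", iter))
        delta <- em_delta(sa, theta)
      }
    }

    accepted <- FALSE
    for (h in 0:control$max_halving) {
      cand <- theta + delta / 2^h
      flo <- cand[var_idx] < floor_v
      if (any(flo)) {
        cand[var_idx][flo] <- floor_v
        events <- c(events, sprintf("iter %d: variance floored (%s)", iter,
                                    paste(design$names[var_idx][flo], collapse = ", ")))
      }
      Rc <- chol_V(cand)
      if (is.null(Rc)) next
      llc <- loglik_from_chol(Rc, design$X, y)
      if (llc$logL >= logL - 1e-10) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted && iter > control$n_em) {
      # Newton direction failed at every scale: take the safe EM step
      delta <- em_delta(sa, theta)
      cand <- theta + delta
      cand[var_idx] <- pmax(cand[var_idx], floor_v)
      Rc <- chol_V(cand)
      if (!is.null(Rc)) {
        llc <- loglik_from_chol(Rc, design$X, y)
        accepted <- llc$logL >= logL - 1e-10
        if (accepted)
          events <- c(events, sprintf("iter %d: EM fallback step", iter))
      }
    }
    if (!accepted) {
      events <- c(events, sprintf("iter %d: no acceptable step", iter))
      break
    }
    dtheta <- max(abs(cand - theta))
    dlogL <- llc$logL - logL
    theta <- cand; R <- Rc; ll <- llc; logL <- llc$logL
    history <- c(history, logL)
    if (control$verbose)
      message(sprintf("iter %3d logL %.8f", iter, logL))
    if (abs(dlogL) < control$tol_loglik && dtheta < control$tol_param &&
        iter > control$n_em) {
      converged <- TRUE
      break
    }
  }

  # final derivatives at the accepted parameters
  Vinv <- chol2inv(R)
  ViX <- Vinv %*% design$X
  P <- Vinv - ViX %*% solve(crossprod(design$X, ViX), t(ViX))
  P <- (P + t(P)) / 2
  sa <- score_and_ai(P, y, design$dV)
  param_cov <- tryCatch(solve(sa$ai), error = function(e) NULL)
  if (is.null(param_cov)) ai_singular <- TRUE
  theta <- stats::setNames(theta, design$names)
  rownames(sa$ai) <- colnames(sa$ai) <- design$names
  if (!is.null(param_cov))
    rownames(param_cov) <- colnames(param_cov) <- design$names

  structure(list(params = theta_to_params(unname(theta), spec), theta = theta,
                 loglik = logL, ai_matrix = sa$ai, param_cov = param_cov,
                 gradient = sa$gradient, iterations = iter,
                 converged = converged, history = history, events = events,
                 ai_singular = ai_singular, n = n, spec = spec,
                 beta = drop(ll$beta)),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit: n = %d, logL = %.4f, %d iteration(s), %s\n",
              x$n, x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  se <- if (!is.null(x$param_cov)) sqrt(pmax(diag(x$param_cov), 0)) else
    rep(NA_real_, length(x$theta))
  print(data.frame(estimate = unname(x$theta), se = unname(se),
                   row.names = names(x$theta)))
  if (x$ai_singular) cat("warning: AI matrix singular (non-identifiable?)\n")
  invisible(x)
}

#' Drop nonsignificant covariance terms from a model
#'
#' Removes every free covariance pair whose Wald p-value (one degree of
#' freedom, two-sided) exceeds `alpha_drop`. The caller refits the reduced
#' spec and may compare it to the full model with a likelihood-ratio test.
#'
#' @param spec a [model_spec()].
#' @param fit the converged [fit_reml()] result on that spec.
#' @param alpha_drop retention threshold (default 0.05).
#' @return a new [model_spec()] with the surviving pairs.
#' @export
reduce_model <- function(spec, fit, alpha_drop = 0.05) {
  stopifnot(inherits(spec, "model_spec"), inherits(fit, "reml_fit"))
  if (!fit$converged) stop("fit did not converge; refusing to reduce")
  if (!length(spec$free_covariances)) return(spec)
  if (is.null(fit$param_cov)) stop("parameter covariance unavailable (singular AI)")
  keep <- vapply(seq_along(spec$free_covariances), function(j) {
    nm <- paste0("cov:", paste(spec$free_covariances[[j]], collapse = ":"))
    est <- fit$theta[[nm]]
    se <- sqrt(fit$param_cov[nm, nm])
    p <- stats::pchisq((est / se)^2, df = 1, lower.tail = FALSE)
    p <= alpha_drop
  }, logical(1))
  model_spec(spec$components, spec$free_covariances[keep], X = spec$X)
}
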