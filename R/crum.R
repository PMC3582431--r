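# Binary classification relevance units machine (CRUM).
#
# The model is a kernel logistic classifier over a fixed, small set of
# relevance units: P(C+ | x) = sigmoid( sum_i w_i k(x, u_i) + b ). The units
# are prototypes obtained by unsupervised clustering, not selected training
# points, so the design matrix Phi (Phi_nm = k(x_n, u_m)) is fixed before
# the weights are learned. Weights are maximum a posteriori under log loss
# with a Gaussian prior of precision alpha on the weight block (the bias is
# unpenalized); alpha itself is set by the MacKay evidence fixed point, so
# the error/complexity trade-off needs no cross-validation.

#' Construct a binary relevance units classifier directly
#'
#' Mostly useful for tests and for deserialization; models are normally
#' produced by [train_binary_crum()].
#'
#' @param units M x d matrix of relevance units (rows are prototypes).
#' @param weights numeric vector of length M.
#' @param bias single numeric intercept.
#' @param kernel a [kernel_spec()].
#' @param alpha positive regularization precision attached to the model
#'   (recorded for inspection; not used at prediction time).
#' @return Object of class `binary_crum`.
#' @export
binary_crum <- function(units, weights, bias, kernel, alpha = 1.0) {
  units <- as_feature_matrix(units)
  weights <- as.numeric(weights)
  if (nrow(units) < 1L) stop("at least one relevance unit is required")
  if (length(weights) != nrow(units)) {
    stop("number of weights must equal number of relevance units")
  }
  if (!inherits(kernel, "kernel_spec")) stop("kernel must be a kernel_spec")
  structure(
    list(
      units = units,
      weights = weights,
      bias = as.numeric(bias)[1L],
      kernel = kernel,
      alpha = as.numeric(alpha)[1L],
      feature_dim = ncol(units)
    ),
    class = "binary_crum"
  )
}

#' @export
print.binary_crum <- function(x, ...) {
  cat(
    "Binary relevance units classifier:", nrow(x$units), "units,",
    "d =", x$feature_dim, ", gamma =", signif(x$kernel$gamma, 4),
    ", alpha =", signif(x$alpha, 4), "\n"
  )
  invisible(x)
}

#' Posterior probability of the positive class
#'
#' Evaluates the sigmoid kernel expansion of a binary relevance units
#' classifier. The return value is clamped strictly inside (0, 1) so that
#' downstream log-space decoding never sees an exact 0 or 1.
#'
#' @param model a `binary_crum`.
#' @param x numeric vector of length `feature_dim`, or a matrix with that
#'   many columns (one prediction per row).
#' @return Numeric vector of posterior probabilities in (0, 1).
#' @export
predict_binary <- function(model, x) {
  stopifnot(inherits(model, "binary_crum"))
  X <- as_feature_matrix(x, d = model$feature_dim)
  eta <- drop(kernel_matrix(X, model$units, model$kernel$gamma) %*% model$weights) +
    model$bias
  clip01(stats::plogis(eta))
}

# Penalized negative log-likelihood, its gradient and Hessian for the
# kernel logistic fit. beta = c(w, b); only w is penalized.
crum_objective <- function(beta, Phi, t, alpha) {
  eta <- drop(Phi %*% beta)
  # log(1 + exp(eta)) - t*eta, computed stably
  ll <- sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - t * eta)
  M <- length(beta) - 1L
  ll + alpha / 2 * sum(beta[seq_len(M)]^2)
}

crum_gradient <- function(beta, Phi, t, alpha) {
  p <- stats::plogis(drop(Phi %*% beta))
  g <- drop(crossprod(Phi, p - t))
  M <- length(beta) - 1L
  g[seq_len(M)] <- g[seq_len(M)] + alpha * beta[seq_len(M)]
  g
}

# Damped Newton (IRLS with step halving) at fixed alpha. Returns the
# solution, the per-iteration objective trace and the final gradient.
crum_newton <- function(beta, Phi, t, alpha, tol = 1e-8, max_iter = 100L) {
  M <- ncol(Phi) - 1L
  ridge <- c(rep(alpha, M), 0)
  obj <- crum_objective(beta, Phi, t, alpha)
  trace <- obj
  for (iter in seq_len(max_iter)) {
    g <- crum_gradient(beta, Phi, t, alpha)
    if (max(abs(g)) <= tol) break
    p <- stats::plogis(drop(Phi %*% beta))
    w_irls <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(Phi * w_irls, Phi) + diag(ridge, nrow = M + 1L)
    step <- tryCatch(
      solve(H, g),
      error = function(e) {
        stop(
          "inner Newton solve failed (singular or ill-conditioned Hessian): ",
          conditionMessage(e)
        )
      }
    )
    # step halving: accept only non-increasing objective
    lambda <- 1
    repeat {
      cand <- beta - lambda * step
      cand_obj <- crum_objective(cand, Phi, t, alpha)
      if (cand_obj <= obj + 1e-12 || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    if (cand_obj > obj + 1e-12) break # no descent direction left
    beta <- cand
    obj <- cand_obj
    trace <- c(trace, obj)
  }
  g <- crum_gradient(beta, Phi, t, alpha)
  list(beta = beta, objective = trace, grad_max = max(abs(g)))
}

#' Train a binary relevance units classifier
#'
#' Fits the weights and bias of the sigmoid kernel expansion by penalized
#' maximum likelihood (log loss plus a Gaussian prior of precision `alpha`
#' on the weights; the bias is unpenalized), using damped Newton/IRLS on the
#' fixed kernel design over the supplied relevance units. Between weight
#' solves, `alpha` is re-estimated by the MacKay evidence fixed point
#' \eqn{\alpha \leftarrow \gamma_{\mathrm{eff}} / \|w\|^2}, where
#' \eqn{\gamma_{\mathrm{eff}} = \sum_j \lambda_j / (\lambda_j + \alpha)} and
#' \eqn{\lambda_j} are the eigenvalues of the unpenalized-loss Hessian
#' restricted to the weight block. The alternation stops when the relative
#' change in `alpha` drops below `alpha_tol` and is entirely deterministic.
#'
#' @param positive,negative numeric matrices of positive- and negative-class
#'   training rows (same number of columns).
#' @param units M x d matrix of relevance units, typically K-means centers
#'   from [kmeans_centers()] or [select_complexity()].
#' @param kernel a [kernel_spec()].
#' @param max_outer maximum number of alpha-update cycles.
#' @param tol convergence tolerance on the gradient max-norm of the inner
#'   Newton solve.
#' @param alpha_init initial regularization precision.
#' @param alpha_tol relative-change stopping tolerance for the alpha
#'   alternation.
#' @return A `binary_crum` whose `fit` element records the objective trace of
#'   every inner solve, the final gradient max-norm, the number of outer
#'   iterations and a convergence flag.
#' @export
train_binary_crum <- function(positive, negative, units, kernel,
                              max_outer = 100L, tol = 1e-8,
                              alpha_init = 1.0, alpha_tol = 1e-3) {
  positive <- as_feature_matrix(positive)
  negative <- as_feature_matrix(negative)
  if (nrow(positive) < 1L || nrow(negative) < 1L) {
    stop("both classes must contribute at least one training row")
  }
  if (nrow(positive) == 1L || nrow(negative) == 1L) {
    warning("a class has a single training point; the fit may be degenerate")
  }
  if (ncol(positive) != ncol(negative)) stop("class feature dimensions differ")
  units <- as_feature_matrix(units, d = ncol(positive))
  stopifnot(inherits(kernel, "kernel_spec"))

  X <- rbind(positive, negative)
  t <- c(rep(1, nrow(positive)), rep(0, nrow(negative)))
  M <- nrow(units)
  Phi <- cbind(kernel_matrix(X, units, kernel$gamma), 1)

  alpha <- alpha_init
  beta <- rep(0, M + 1L)
  traces <- list()
  outer_used <- 0L
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    outer_used <- outer
    fit <- crum_newton(beta, Phi, t, alpha, tol = tol)
    beta <- fit$beta
    traces[[outer]] <- fit$objective

    # evidence fixed point for alpha
    w <- beta[seq_len(M)]
    p <- stats::plogis(drop(Phi %*% beta))
    w_irls <- pmax(p * (1 - p), 1e-12)
    H0 <- crossprod(Phi[, seq_len(M), drop = FALSE] * w_irls,
                    Phi[, seq_len(M), drop = FALSE])
    lambda <- eigen(H0, symmetric = TRUE, only.values = TRUE)$values
    lambda[lambda < 0] <- 0
    gamma_eff <- sum(lambda / (lambda + alpha))
    alpha_new <- gamma_eff / max(sum(w^2), 1e-12)
    alpha_new <- min(max(alpha_new, 1e-10), 1e10)
    rel <- abs(alpha_new - alpha) / max(alpha, 1e-12)
    alpha <- alpha_new
    if (rel < alpha_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(
      "alpha alternation did not converge in ", max_outer,
      " outer iterations; returning best iterate"
    )
  }
  # final re-solve so the returned weights are stationary at the final alpha
  fit <- crum_newton(beta, Phi, t, alpha, tol = tol)
  beta <- fit$beta
  traces[[length(traces) + 1L]] <- fit$objective

  model <- binary_crum(
    units = units,
    weights = beta[seq_len(M)],
    bias = beta[M + 1L],
    kernel = kernel,
    alpha = alpha
  )
  model$fit <- list(
    objective_traces = traces,
    grad_max = fit$grad_max,
    outer_iterations = outer_used,
    converged = converged,
    tol = tol
  )
  model
}
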