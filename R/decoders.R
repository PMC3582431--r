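# Decoders: aggregate the L binary posteriors g_i(x) into a multiclass
# decision (hard nearest-codeword) or a posterior over the K classes
# (naive log-product decoding, generalized Bradley-Terry model).

check_outputs <- function(code, g) {
  if (length(g) != ncol(code)) {
    stop("binary output vector length must equal the number of code columns")
  }
  if (any(!is.finite(g)) || any(g < 0) || any(g > 1)) {
    stop("binary outputs must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Hard nearest-codeword decoding
#'
#' Binarizes the L binary outputs at `cutoff` and returns the class whose
#' code row has the smallest modified Hamming distance ([code_distance()])
#' to the binarized vector; ties go to the smallest class index.
#'
#' @param code a [coding_matrix()].
#' @param g numeric vector of L binary-classifier outputs in `[0, 1]`
#'   (already-hard 0/1 outputs are fine).
#' @param cutoff binarization threshold in (0, 1).
#' @return The winning class index (integer), with the row distances
#'   attached as attribute `"distances"`.
#' @export
decode_hard <- function(code, g, cutoff = 0.5) {
  stopifnot(inherits(code, "coding_matrix"))
  check_outputs(code, g)
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  z <- as.integer(g >= cutoff)
  d <- vapply(seq_len(nrow(code)), function(k) code_distance(code[k, ], z), numeric(1))
  structure(which.min(d), distances = d) # which.min takes the first minimum
}

#' Naive linear-time posterior decoding
#'
#' Under the assumption that the L binary classifiers err independently, the
#' posterior of class k is proportional to the product over the problems
#' that involve class k of \eqn{g_i^{M_{ki}} (1-g_i)^{1-M_{ki}}}, Delta
#' entries being skipped. The product is accumulated in log space and
#' normalized by a max-subtracted softmax; outputs are clipped to
#' `[eps, 1-eps]` before the logs. Work grows linearly in L.
#'
#' @inheritParams decode_hard
#' @param eps clipping bound for the binary outputs.
#' @return Numeric posterior vector of length K summing to 1, with the
#'   number of elementary accumulation operations attached as attribute
#'   `"ops"`.
#' @export
decode_naive <- function(code, g, eps = 1e-12) {
  stopifnot(inherits(code, "coding_matrix"))
  check_outputs(code, g)
  g <- clip01(g, eps)
  pos <- ifelse(is.na(code), 0, code)       # weight on log g_i
  neg <- ifelse(is.na(code), 0, 1 - code)   # weight on log(1 - g_i)
  score <- drop(pos %*% log(g) + neg %*% log1p(-g))
  score <- score - max(score)
  p <- exp(score)
  s <- sum(p)
  if (!is.finite(s) || s <= 0) stop("all class scores vanished in naive decoding")
  structure(p / s, ops = sum(!is.na(code)) + nrow(code))
}

#' Assemble a generalized Bradley-Terry decoding problem
#'
#' Collects, for each column of the coding matrix, the positive class set
#' \eqn{I_i^+}, the negative class set \eqn{I_i^-}, the per-problem weight
#' \eqn{N_i} (number of training instances the problem saw) and the observed
#' binary output \eqn{\hat r_i}.
#'
#' @param code a [coding_matrix()].
#' @param g numeric vector of L binary outputs in `[0, 1]`.
#' @param weights positive per-problem weights `N_i`; defaults to 1 for all.
#' @return Object of class `gbt_problem`.
#' @export
gbt_problem <- function(code, g, weights = NULL) {
  stopifnot(inherits(code, "coding_matrix"))
  check_outputs(code, g)
  L <- ncol(code)
  if (is.null(weights)) weights <- rep(1, L)
  if (length(weights) != L || any(weights <= 0)) {
    stop("weights must be ", L, " positive numbers")
  }
  positive_sets <- lapply(seq_len(L), function(i) which(code[, i] == 1L))
  negative_sets <- lapply(seq_len(L), function(i) which(code[, i] == 0L))
  structure(
    list(
      K = nrow(code),
      positive_sets = positive_sets,
      negative_sets = negative_sets,
      weights = as.numeric(weights),
      observations = as.numeric(g)
    ),
    class = "gbt_problem"
  )
}

# Membership indicator matrices (K x L) for vectorized sweeps.
gbt_indicators <- function(problem) {
  K <- problem$K
  L <- length(problem$positive_sets)
  Apos <- matrix(0, K, L)
  Aneg <- matrix(0, K, L)
  for (i in seq_len(L)) {
    Apos[problem$positive_sets[[i]], i] <- 1
    Aneg[problem$negative_sets[[i]], i] <- 1
  }
  list(Apos = Apos, Aneg = Aneg)
}

# Weighted negative log-likelihood of the GBT model at p.
gbt_objective <- function(problem, p, ind, qfloor = 1e-12) {
  qpos <- pmax(drop(crossprod(ind$Apos, p)), qfloor)
  qneg <- pmax(drop(crossprod(ind$Aneg, p)), qfloor)
  q <- pmax(qpos + qneg, qfloor)
  r <- problem$observations
  -sum(problem$weights * (r * log(qpos / q) + (1 - r) * log(qneg / q)))
}

#' Generalized Bradley-Terry posterior decoding
#'
#' Estimates the class posterior p by minimizing the weighted negative
#' log-likelihood that matches each observed binary output \eqn{\hat r_i} to
#' the probability ratio \eqn{q_i^+ / q_i} of summed class posteriors (a
#' weighted Kullback-Leibler divergence). Starting from the uniform vector,
#' each sweep applies the multiplicative update
#' \deqn{p_k \leftarrow p_k \cdot
#'   \frac{\sum_{i: k \in I_i^+} N_i \hat r_i / q_i^+ +
#'         \sum_{i: k \in I_i^-} N_i (1-\hat r_i) / q_i^-}
#'        {\sum_{i: k \in I_i} N_i / q_i}}
#' and renormalizes; the q sums are recomputed each sweep and floored at
#' `qfloor`. Iteration stops when the largest per-class change falls below
#' `tol` or after `max_iter` sweeps. Non-convergence is reported, not an
#' error: under a general decomposition the iteration need not converge.
#'
#' @param problem a [gbt_problem()].
#' @param max_iter maximum number of sweeps.
#' @param tol convergence tolerance on `max |p_new - p_old|`.
#' @param qfloor lower floor applied to the q sums.
#' @return List with `posterior` (length-K vector summing to 1),
#'   `iterations`, `converged` and the per-sweep `objective` trace
#'   (including the starting value).
#' @export
decode_gbt <- function(problem, max_iter = 1000L, tol = 1e-8, qfloor = 1e-12) {
  stopifnot(inherits(problem, "gbt_problem"))
  K <- problem$K
  ind <- gbt_indicators(problem)
  N <- problem$weights
  r <- problem$observations
  p <- rep(1 / K, K)
  objective <- gbt_objective(problem, p, ind, qfloor)
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    qpos <- pmax(drop(crossprod(ind$Apos, p)), qfloor)
    qneg <- pmax(drop(crossprod(ind$Aneg, p)), qfloor)
    q <- pmax(qpos + qneg, qfloor)
    num <- drop(ind$Apos %*% (N * r / qpos) + ind$Aneg %*% (N * (1 - r) / qneg))
    den <- drop((ind$Apos + ind$Aneg) %*% (N / q))
    p_new <- p * num / pmax(den, qfloor)
    s <- sum(p_new)
    if (!is.finite(s) || s <= 0 || any(!is.finite(p_new))) {
      stop("generalized Bradley-Terry update produced a non-finite posterior")
    }
    p_new <- p_new / s
    delta <- max(abs(p_new - p))
    p <- p_new
    iterations <- it
    objective <- c(objective, gbt_objective(problem, p, ind, qfloor))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(
    posterior = p,
    iterations = iterations,
    converged = converged,
    objective = objective
  )
}
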