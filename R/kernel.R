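#' Kernel specification
#'
#' Describes the kernel used by a binary relevance units classifier. Only the
#' Gaussian (radial basis) kernel is supported; the `kind` field exists as a
#' hook for future kernels.
#'
#' @param gamma positive kernel width \eqn{\gamma} of
#'   \eqn{k(x, u) = \exp(-\gamma \|x - u\|^2)}.
#' @param kind kernel family; only `"gaussian"` is implemented.
#' @return An object of class `kernel_spec`.
#' @seealso [compute_gamma()] for the cluster-distance heuristic that sets
#'   `gamma` automatically.
#' @export
kernel_spec <- function(gamma, kind = "gaussian") {
  kind <- match.arg(kind, "gaussian")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    stop("gamma must be a single positive number")
  }
  structure(list(kind = kind, gamma = as.numeric(gamma)), class = "kernel_spec")
}

#' Gaussian kernel between two vectors
#'
#' \eqn{k(x, u) = \exp(-\gamma \|x - u\|^2)}, which lies in \eqn{(0, 1]} and
#' equals 1 exactly when `x == u`.
#'
#' @param x,u numeric vectors of equal length.
#' @param gamma positive kernel width.
#' @return A single number in `(0, 1]`.
#' @examples
#' gaussian_kernel(c(0, 0), c(2, 0), 0.125) # exp(-0.5)
#' @export
gaussian_kernel <- function(x, u, gamma) {
  if (length(x) != length(u)) stop("x and u must have the same dimension")
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be positive")
  exp(-gamma * sum((x - u)^2))
}

#' Gaussian kernel matrix
#'
#' Computes the N x M matrix of kernel evaluations between the rows of `X`
#' and the rows of `U` (typically the relevance units).
#'
#' @param X numeric matrix (N x d).
#' @param U numeric matrix (M x d).
#' @param gamma positive kernel width.
#' @return N x M numeric matrix.
#' @export
kernel_matrix <- function(X, U, gamma) {
  X <- as_feature_matrix(X)
  U <- as_feature_matrix(U)
  if (ncol(X) != ncol(U)) stop("X and U must have the same dimension")
  d2 <- outer(rowSums(X^2), rowSums(U^2), "+") - 2 * tcrossprod(X, U)
  d2[d2 < 0] <- 0 # guard tiny negative round-off
  exp(-gamma * d2)
}
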