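# Selection of the number of relevance units M and the kernel width gamma.
#
# The unlabeled training features are clustered with K-means for each
# candidate M; an AIC computed from a hard-assignment isotropic Gaussian
# mixture reading of the clustering picks M, and the kernel width follows
# the heuristic gamma = 1 / (2 d_max^2) with d_max the maximum pairwise
# distance between the selected cluster centers. The same M, centers and
# gamma are shared by every binary classifier of one multiclass model.

#' Seeded K-means clustering
#'
#' Runs Lloyd's algorithm (via [stats::kmeans()]) from `restarts` seeded
#' initializations, each starting at `M` distinct data rows sampled
#' uniformly, and keeps the solution with the smallest within-cluster sum of
#' squares. Deterministic given `seed`.
#'
#' @param features numeric matrix (N x d).
#' @param M number of clusters, `1 <= M <= N`.
#' @param seed integer seed.
#' @param restarts number of random initializations.
#' @return Object of class `clustering_result`: `centers` (M x d),
#'   `assignments` (length N) and `sse`.
#' @export
kmeans_centers <- function(features, M, seed = 1L, restarts = 5L) {
  features <- as_feature_matrix(features)
  N <- nrow(features)
  if (M < 1L || M > N) stop("M must lie in 1..N (N = ", N, ")")
  uniq <- unique(features)
  if (nrow(uniq) < M) {
    stop("fewer than M distinct rows; reduce M (distinct rows: ", nrow(uniq), ")")
  }
  if (M == 1L) {
    centers <- matrix(colMeans(features), nrow = 1)
    sse <- sum(sweep(features, 2, centers[1L, ])^2)
    return(structure(
      list(centers = centers, assignments = rep(1L, N), sse = sse),
      class = "clustering_result"
    ))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- NULL
      for (try in 1:25) { # resample on empty-cluster failures
        init <- uniq[sample.int(nrow(uniq), M), , drop = FALSE]
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(
            features,
            centers = init, iter.max = 100L, algorithm = "Lloyd"
          )),
          error = function(e) NULL
        )
        if (!is.null(fit)) break
      }
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop("K-means failed for all restarts (M = ", M, ")")
  structure(
    list(
      centers = unname(best$centers),
      assignments = as.integer(best$cluster),
      sse = best$tot.withinss
    ),
    class = "clustering_result"
  )
}

#' AIC of a clustering under a hard-assignment Gaussian mixture reading
#'
#' The clustering is interpreted as an isotropic Gaussian mixture with hard
#' assignments, shared variance \eqn{\sigma^2 = SSE/(Nd)} and mixing
#' proportions \eqn{n_m/N}. Then
#' \eqn{\log L = \sum_m n_m \log(n_m/N) - (Nd/2)(\log(2\pi\sigma^2) + 1)}
#' and \eqn{AIC = 2P - 2\log L} with \eqn{P = Md + (M-1) + 1} free
#' parameters (centers, mixing proportions, variance).
#'
#' @param result a `clustering_result` produced from `features`.
#' @param features the clustered feature matrix.
#' @return The AIC value (smaller is better).
#' @export
clustering_aic <- function(result, features) {
  stopifnot(inherits(result, "clustering_result"))
  features <- as_feature_matrix(features)
  N <- nrow(features)
  d <- ncol(features)
  M <- nrow(result$centers)
  if (length(result$assignments) != N) {
    stop("clustering result does not match the feature matrix")
  }
  if (result$sse <= 0) {
    stop("degenerate clustering variance (SSE = 0); cap the M grid below N")
  }
  sigma2 <- result$sse / (N * d)
  n_m <- tabulate(result$assignments, nbins = M)
  n_m <- n_m[n_m > 0]
  logL <- sum(n_m * log(n_m / N)) - (N * d / 2) * (log(2 * pi * sigma2) + 1)
  P <- M * d + (M - 1) + 1
  2 * P - 2 * logL
}

#' Default doubling grid of candidate cluster counts
#'
#' `{2, 4, 8, ...}` capped at `min(512, floor(N/2))`.
#'
#' @param N number of training instances.
#' @return Integer vector of candidate M values.
#' @export
default_m_grid <- function(N) {
  cap <- min(512L, N %/% 2L)
  if (cap < 2L) stop("too few instances for the default complexity grid")
  grid <- as.integer(2^(1:9))
  grid[grid <= cap]
}

#' Select the number of relevance units by AIC
#'
#' Clusters the features for each candidate `M` and returns the grid member
#' minimizing [clustering_aic()]; ties go to the smallest `M`.
#'
#' @param features numeric matrix.
#' @param M_grid integer vector of candidate cluster counts.
#' @param seed integer seed shared by all clusterings.
#' @param restarts K-means restarts per candidate.
#' @return List with the selected `M`, its `clustering` and the `aic` values
#'   aligned with `M_grid`.
#' @export
select_complexity <- function(features, M_grid, seed = 1L, restarts = 5L) {
  features <- as_feature_matrix(features)
  M_grid <- as.integer(M_grid)
  if (length(M_grid) < 1L) stop("M_grid must be non-empty")
  if (any(M_grid > nrow(features))) stop("M_grid contains values above N")
  fits <- lapply(M_grid, function(M) {
    kmeans_centers(features, M, seed = seed, restarts = restarts)
  })
  aic <- vapply(fits, clustering_aic, numeric(1), features = features)
  ord <- order(aic, M_grid) # ties -> smallest M
  best <- ord[1L]
  list(M = M_grid[best], clustering = fits[[best]], aic = aic, M_grid = M_grid)
}

#' Kernel width from cluster-center spread
#'
#' \eqn{\gamma = 1 / (2 d_{max}^2)} with \eqn{d_{max}} the maximum pairwise
#' Euclidean distance between cluster centers. Invariant to center ordering
#' and rigid translation.
#'
#' @param centers matrix of cluster centers (rows), at least two of them
#'   distinct.
#' @return Positive kernel width.
#' @examples
#' compute_gamma(rbind(c(0, 0), c(2, 0))) # 1/8
#' @export
compute_gamma <- function(centers) {
  centers <- as_feature_matrix(centers)
  if (nrow(centers) < 2L) stop("at least two cluster centers are required")
  d_max <- max(stats::dist(centers))
  if (d_max <= 0) stop("all centers coincide; kernel width undefined")
  1 / (2 * d_max^2)
}
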