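# Multiclass orchestration: decompose the K-class problem along the columns
# of a coding matrix, train one binary relevance units classifier per
# column (all sharing the relevance units and kernel width selected once
# from the pooled unlabeled features), and decode predictions with the
# naive, generalized Bradley-Terry or hard decoder.

resolve_code <- function(code, K) {
  if (inherits(code, "coding_matrix")) {
    if (nrow(code) != K) {
      stop("coding matrix has ", nrow(code), " rows but the data has ", K, " classes")
    }
    return(code)
  }
  switch(match.arg(code, c("ap", "ovr")),
    ap = ap_matrix(K),
    ovr = ovr_matrix(K)
  )
}

#' Train a multiclass relevance units machine
#'
#' Selects the shared relevance units and kernel width from the pooled
#' unlabeled features (K-means + AIC unless overridden), then trains one
#' binary classifier per column of the coding matrix: classes coded 1 form
#' the positive set, classes coded 0 the negative set, and Delta classes are
#' omitted from that problem. Fully deterministic given `seed`.
#'
#' @param data a [labeled_dataset()]; `data$class_names` order fixes the
#'   coding-matrix row order.
#' @param code a [coding_matrix()], or `"ap"` / `"ovr"` to build the
#'   all-pairs or one-versus-rest decomposition for the data's class count.
#' @param M number of relevance units, or `"auto"` to pick by AIC over the
#'   [default_m_grid()].
#' @param gamma kernel width, or `"auto"` for the cluster-distance heuristic
#'   [compute_gamma()].
#' @param seed integer seed controlling clustering initialization.
#' @param standardize z-score each feature column (parameters stored in the
#'   model). Use `FALSE` for features that are already normalized, e.g.
#'   k-mer frequency blocks.
#' @param restarts K-means restarts.
#' @param max_outer,tol passed to [train_binary_crum()].
#' @param verbose print per-column training summaries.
#' @return Object of class `mcrum`.
#' @export
train_mcrum <- function(data, code = "ap", M = "auto", gamma = "auto",
                        seed = 1L, standardize = TRUE, restarts = 5L,
                        max_outer = 100L, tol = 1e-8, verbose = FALSE) {
  stopifnot(inherits(data, "labeled_dataset"))
  K <- length(data$class_names)
  code <- resolve_code(code, K)
  X <- data$features

  std <- NULL
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale, "/")
    std <- list(center = unname(center), scale = unname(scale))
  }

  if (identical(M, "auto")) {
    sel <- select_complexity(X, default_m_grid(nrow(X)), seed = seed, restarts = restarts)
    M <- sel$M
    clustering <- sel$clustering
  } else {
    M <- as.integer(M)
    clustering <- kmeans_centers(X, M, seed = seed, restarts = restarts)
  }
  units <- clustering$centers
  if (identical(gamma, "auto")) gamma <- compute_gamma(units)
  kern <- kernel_spec(gamma)

  class_idx <- match(data$labels, data$class_names)
  L <- ncol(code)
  classifiers <- vector("list", L)
  train_counts <- integer(L)
  for (i in seq_len(L)) {
    pos_classes <- which(code[, i] == 1L)
    neg_classes <- which(code[, i] == 0L)
    pos_rows <- which(class_idx %in% pos_classes)
    neg_rows <- which(class_idx %in% neg_classes)
    if (length(pos_rows) == 0L || length(neg_rows) == 0L) {
      stop(
        "column ", i, " has an empty ",
        if (length(pos_rows) == 0L) "positive" else "negative",
        " partition in the training data"
      )
    }
    classifiers[[i]] <- train_binary_crum(
      X[pos_rows, , drop = FALSE], X[neg_rows, , drop = FALSE],
      units = units, kernel = kern, max_outer = max_outer, tol = tol
    )
    train_counts[i] <- length(pos_rows) + length(neg_rows)
    if (verbose) {
      message(sprintf(
        "column %d: N_i = %d, outer iterations = %d, alpha = %.4g",
        i, train_counts[i], classifiers[[i]]$fit$outer_iterations,
        classifiers[[i]]$alpha
      ))
    }
  }

  structure(
    list(
      code = code,
      classifiers = classifiers,
      class_names = data$class_names,
      train_counts = train_counts,
      standardization = std,
      metadata = list(
        seed = as.integer(seed),
        M = M,
        gamma = kern$gamma,
        feature_dim = ncol(data$features)
      )
    ),
    class = "mcrum"
  )
}

#' @export
print.mcrum <- function(x, ...) {
  cat(
    "Multiclass relevance units machine:", length(x$class_names), "classes,",
    ncol(x$code), "binary classifiers, M =", x$metadata$M,
    ", gamma =", signif(x$metadata$gamma, 4), "\n"
  )
  cat("Classes:", paste(x$class_names, collapse = ", "), "\n")
  invisible(x)
}

apply_standardization <- function(model, X) {
  if (is.null(model$standardization)) return(X)
  sweep(sweep(X, 2, model$standardization$center), 2, model$standardization$scale, "/")
}

# L binary posteriors for each row of X (N x L matrix).
binary_outputs <- function(model, X) {
  G <- vapply(model$classifiers, predict_binary, numeric(nrow(X)), x = X)
  matrix(G, nrow = nrow(X))
}

#' Predict with a multiclass relevance units machine
#'
#' Evaluates the L binary posteriors, decodes them with the chosen decoder,
#' and assigns each instance its argmax class — unless that class's
#' posterior falls below `threshold`, in which case the instance is labeled
#' [UNCLASSIFIED]. Hard decoding yields no posterior and therefore admits no
#' rejection threshold.
#'
#' @param model an `mcrum` model.
#' @param x numeric vector (one instance) or matrix (one instance per row)
#'   on the original feature scale.
#' @param decoder `"naive"`, `"gbt"` or `"hard"`.
#' @param threshold rejection threshold in `[0, 1)`; 0 disables rejection.
#' @return List with `posterior` (N x K matrix, or `NULL` for hard
#'   decoding), `label` (character vector), `threshold` and `decoder`.
#' @export
predict_mcrum <- function(model, x, decoder = c("naive", "gbt", "hard"),
                          threshold = 0) {
  stopifnot(inherits(model, "mcrum"))
  decoder <- match.arg(decoder)
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)")
  if (decoder == "hard" && threshold > 0) {
    stop("hard decoding yields no posterior; a rejection threshold cannot be applied")
  }
  X <- as_feature_matrix(x, d = model$metadata$feature_dim)
  Xs <- apply_standardization(model, X)
  G <- binary_outputs(model, Xs)
  K <- length(model$class_names)

  if (decoder == "hard") {
    idx <- vapply(seq_len(nrow(G)), function(n) {
      as.integer(decode_hard(model$code, G[n, ]))
    }, integer(1))
    return(list(
      posterior = NULL, label = model$class_names[idx],
      threshold = threshold, decoder = decoder
    ))
  }

  P <- matrix(NA_real_, nrow(G), K, dimnames = list(NULL, model$class_names))
  for (n in seq_len(nrow(G))) {
    P[n, ] <- if (decoder == "naive") {
      as.numeric(decode_naive(model$code, G[n, ]))
    } else {
      decode_gbt(gbt_problem(model$code, G[n, ], weights = model$train_counts))$posterior
    }
  }
  idx <- max.col(P, ties.method = "first")
  label <- model$class_names[idx]
  label[P[cbind(seq_len(nrow(P)), idx)] < threshold] <- UNCLASSIFIED
  list(posterior = P, label = label, threshold = threshold, decoder = decoder)
}

MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize a multiclass model to JSON
#'
#' Numbers are written at full precision, so `save -> load -> save` is
#' byte-identical and a reloaded model predicts identically.
#'
#' @param model an `mcrum` model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_mcrum <- function(model, path) {
  stopifnot(inherits(model, "mcrum"))
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    class_names = model$class_names,
    code = code_to_strings(model$code),
    train_counts = model$train_counts,
    standardization = model$standardization,
    metadata = model$metadata,
    classifiers = lapply(model$classifiers, function(cl) {
      list(
        units = cl$units,
        weights = cl$weights,
        bias = cl$bias,
        kernel = list(kind = cl$kernel$kind, gamma = cl$kernel$gamma),
        alpha = cl$alpha,
        feature_dim = cl$feature_dim
      )
    })
  )
  # 17 significant digits round-trips IEEE doubles exactly
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a multiclass model from JSON
#'
#' @param path path to a file written by [save_mcrum()].
#' @return An `mcrum` model.
#' @export
load_mcrum <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(
      path,
      simplifyVector = TRUE, simplifyMatrix = TRUE, simplifyDataFrame = FALSE
    ),
    error = function(e) stop("not a readable model file: ", conditionMessage(e))
  )
  if (is.null(obj$schema_version)) {
    stop("model file lacks a schema_version field; not an mcrum model")
  }
  if (!identical(obj$schema_version, MODEL_SCHEMA_VERSION)) {
    stop(
      "model schema version ", obj$schema_version,
      " is not supported (expected ", MODEL_SCHEMA_VERSION, ")"
    )
  }
  classifiers <- lapply(obj$classifiers, function(cl) {
    units <- cl$units
    if (is.list(units)) units <- do.call(rbind, units)
    binary_crum(
      units = matrix(as.numeric(units), ncol = cl$feature_dim),
      weights = cl$weights,
      bias = cl$bias,
      kernel = kernel_spec(cl$kernel$gamma, cl$kernel$kind),
      alpha = cl$alpha
    )
  })
  std <- obj$standardization
  if (!is.null(std)) std <- list(center = std$center, scale = std$scale)
  structure(
    list(
      code = strings_to_code(obj$code),
      classifiers = classifiers,
      class_names = obj$class_names,
      train_counts = as.integer(obj$train_counts),
      standardization = std,
      metadata = list(
        seed = as.integer(obj$metadata$seed),
        M = as.integer(obj$metadata$M),
        gamma = as.numeric(obj$metadata$gamma),
        feature_dim = as.integer(obj$metadata$feature_dim)
      )
    ),
    class = "mcrum"
  )
}
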