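# Internal helpers shared across the package.

#' Label used for rejected (below-threshold) predictions
#'
#' Predictions whose maximum class posterior falls below the rejection
#' threshold receive this label.
#' @export
UNCLASSIFIED <- "UNCLASSIFIED"

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Stable 31-bit hash of a character string, used to derive per-record seeds.
string_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

as_feature_matrix <- function(x, d = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(d) && ncol(x) != d) {
    stop("feature dimension mismatch: expected ", d, ", got ", ncol(x))
  }
  x
}

clip01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Assemble a labeled dataset
#'
#' Bundles a numeric feature matrix with aligned class labels, the container
#' consumed by [train_mcrum()] and the evaluation helpers.
#'
#' @param features numeric matrix, one row per instance.
#' @param labels vector of class labels, one per row of `features`.
#' @param class_names optional ordered vector of the distinct classes; its
#'   order fixes the row order of any coding matrix used downstream.
#'   Defaults to the sorted unique labels.
#' @return An object of class `labeled_dataset` with elements `features`,
#'   `labels` (character) and `class_names`.
#' @export
labeled_dataset <- function(features, labels, class_names = NULL) {
  features <- as_feature_matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels disagree in length")
  }
  if (nrow(features) < 1L) stop("dataset must contain at least one instance")
  if (is.null(class_names)) class_names <- sort(unique(labels))
  class_names <- as.character(class_names)
  if (anyDuplicated(class_names)) stop("class_names must be distinct")
  if (!all(labels %in% class_names)) {
    stop("labels contain classes absent from class_names")
  }
  structure(
    list(features = features, labels = labels, class_names = class_names),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(
    "Labeled dataset:", nrow(x$features), "instances,",
    ncol(x$features), "features,", length(x$class_names), "classes\n"
  )
  print(table(factor(x$labels, levels = x$class_names)))
  invisible(x)
}

#' Read a labeled dataset from delimited text
#'
#' The file must have a header row; all columns but the last are numeric
#' features and the final column holds the class label.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param sep field separator.
#' @inheritParams labeled_dataset
#' @return A [labeled_dataset()].
#' @export
read_labeled_dataset <- function(path, sep = "\t", class_names = NULL) {
  df <- utils::read.table(
    path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE,
    check.names = FALSE
  )
  if (ncol(df) < 2L) stop("expected at least one feature column plus a label column")
  labels <- as.character(df[[ncol(df)]])
  features <- as.matrix(df[, -ncol(df), drop = FALSE])
  if (!is.numeric(features)) stop("non-numeric feature column in ", path)
  labeled_dataset(features, labels, class_names = class_names)
}

#' Write a labeled dataset to delimited text
#'
#' @param data a [labeled_dataset()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_labeled_dataset <- function(data, path, sep = "\t") {
  stopifnot(inherits(data, "labeled_dataset"))
  df <- as.data.frame(data$features)
  if (is.null(colnames(data$features))) {
    names(df) <- paste0("f", seq_len(ncol(data$features)))
  }
  df$label <- data$labels
  utils::write.table(
    df, path,
    sep = sep, quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
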