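# Coding matrices for error-correcting output codes.
#
# A K x L coding matrix assigns each of the K classes a codeword over the
# symbols {1, 0, Delta}: column i defines binary problem i, with 1 marking
# the positive classes, 0 the negative classes and Delta the classes omitted
# from that problem's training set. Delta is represented as NA in the
# numeric entries and as "D" in serialized form.

code_row_key <- function(m) apply(m, 1, function(r) paste(ifelse(is.na(r), "D", r), collapse = ""))
code_col_key <- function(m) apply(m, 2, function(r) paste(ifelse(is.na(r), "D", r), collapse = ""))

#' Construct and validate a coding matrix
#'
#' @param entries numeric/integer K x L matrix over `{0, 1, NA}`; `NA`
#'   denotes the omission symbol (Delta).
#' @return Object of class `coding_matrix` (the validated integer matrix).
#' @details A valid coding matrix must satisfy three constraints: all rows
#'   and all columns are unique; no row is entirely Delta; every column
#'   contains at least one 1 and at least one 0.
#' @export
coding_matrix <- function(entries) {
  m <- as.matrix(entries)
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L, NA_integer_))) {
    stop("coding matrix entries must be 0, 1 or NA (Delta)")
  }
  if (nrow(m) < 2L) stop("a coding matrix needs at least two classes (rows)")
  validate_coding_matrix(m)
  structure(m, class = c("coding_matrix", "matrix"))
}

#' Check the three coding-matrix validity constraints
#'
#' @param m matrix over `{0, 1, NA}`.
#' @param quietly if `TRUE`, return `FALSE` instead of erroring on an
#'   invalid matrix.
#' @return `TRUE` if valid; otherwise an error (or `FALSE` with
#'   `quietly = TRUE`).
#' @export
validate_coding_matrix <- function(m, quietly = FALSE) {
  fail <- function(msg) {
    if (quietly) return(FALSE)
    stop(msg)
  }
  if (anyDuplicated(code_row_key(m))) return(fail("coding matrix rows are not unique"))
  if (anyDuplicated(code_col_key(m))) return(fail("coding matrix columns are not unique"))
  if (any(rowSums(!is.na(m)) == 0L)) return(fail("a row is entirely Delta"))
  ones <- colSums(m == 1L, na.rm = TRUE)
  zeros <- colSums(m == 0L, na.rm = TRUE)
  if (any(ones == 0L | zeros == 0L)) {
    return(fail("every column needs at least one 1 and one 0"))
  }
  TRUE
}

#' @export
print.coding_matrix <- function(x, ...) {
  cat("Coding matrix:", nrow(x), "classes x", ncol(x), "binary problems\n")
  disp <- ifelse(is.na(x), "D", as.character(x))
  dimnames(disp) <- list(
    paste0("class", seq_len(nrow(x))),
    paste0("g", seq_len(ncol(x)))
  )
  print(disp, quote = FALSE)
  invisible(x)
}

#' One-versus-rest coding matrix
#'
#' The K x K identity pattern: problem k has class k positive and all other
#' classes negative; no class is ever omitted.
#'
#' @param K number of classes, at least 2.
#' @return A `coding_matrix`.
#' @export
ovr_matrix <- function(K) {
  if (K < 2L) stop("K must be at least 2")
  coding_matrix(diag(1L, K))
}

#' All-pairs (one-versus-one) coding matrix
#'
#' One column per unordered class pair `(i, j)` with `i < j` in lexicographic
#' order: row `i` is positive, row `j` negative, every other row omitted.
#' K(K-1)/2 columns in total.
#'
#' @param K number of classes, at least 2.
#' @return A `coding_matrix`.
#' @export
ap_matrix <- function(K) {
  if (K < 2L) stop("K must be at least 2")
  pairs <- utils::combn(K, 2L)
  m <- matrix(NA_integer_, nrow = K, ncol = ncol(pairs))
  for (l in seq_len(ncol(pairs))) {
    m[pairs[1L, l], l] <- 1L
    m[pairs[2L, l], l] <- 0L
  }
  coding_matrix(m)
}

#' Modified Hamming distance between code rows
#'
#' Position costs: 0 when both symbols agree and neither is Delta; 1 when
#' they disagree and neither is Delta; 1/2 whenever either symbol is Delta
#' (including Delta vs Delta).
#'
#' @param y,z numeric vectors over `{0, 1, NA}` of equal length.
#' @return Non-negative distance.
#' @examples
#' code_distance(c(1, 1, NA), c(1, 0, 0)) # 1.5
#' @export
code_distance <- function(y, z) {
  if (length(y) != length(z)) stop("code rows must have equal length")
  any_delta <- is.na(y) | is.na(z)
  cost <- ifelse(any_delta, 0.5, as.numeric(y != z))
  sum(cost)
}

# Pairwise row distances -> the minimum, used to rank random candidates.
min_row_distance <- function(m) {
  K <- nrow(m)
  dmin <- Inf
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      dmin <- min(dmin, code_distance(m[i, ], m[j, ]))
    }
  }
  dmin
}

sample_code_column <- function(K, kind) {
  if (kind == "dense") {
    sample(c(0L, 1L), K, replace = TRUE)
  } else {
    sample(c(NA_integer_, 0L, 1L), K, replace = TRUE, prob = c(0.5, 0.25, 0.25))
  }
}

# One valid random candidate: columns are drawn and re-drawn until each has
# both symbols and is not a duplicate; row constraints trigger a full
# restart. Errors when the retry budget is exhausted (e.g. L too small for
# unique rows).
sample_code_candidate <- function(K, L, kind, max_restarts = 200L,
                                  max_col_tries = 200L) {
  for (restart in seq_len(max_restarts)) {
    m <- matrix(NA_integer_, nrow = K, ncol = L)
    ok <- TRUE
    for (l in seq_len(L)) {
      placed <- FALSE
      for (try in seq_len(max_col_tries)) {
        col <- sample_code_column(K, kind)
        if (!any(col == 1L, na.rm = TRUE) || !any(col == 0L, na.rm = TRUE)) next
        key <- paste(ifelse(is.na(col), "D", col), collapse = "")
        if (l > 1L && key %in% code_col_key(m[, seq_len(l - 1L), drop = FALSE])) next
        m[, l] <- col
        placed <- TRUE
        break
      }
      if (!placed) {
        ok <- FALSE
        break
      }
    }
    if (ok && validate_coding_matrix(m, quietly = TRUE)) return(m)
  }
  stop(
    "could not generate a valid random ", kind, " coding matrix with K = ",
    K, ", L = ", L, " within the retry budget; increase L"
  )
}

#' Random dense or sparse coding matrix
#'
#' Generates `n_candidates` valid random matrices (dense: entries uniform
#' over `{0, 1}`; sparse: Delta with probability 1/2, 0 and 1 each 1/4) and
#' returns the candidate whose minimum pairwise row distance under
#' [code_distance()] is largest, ties going to the first generated.
#' Deterministic given `seed`.
#'
#' @param K number of classes.
#' @param L number of binary problems (columns); `ceiling(log2(K))` or more
#'   is recommended so rows can be unique.
#' @param kind `"dense"` or `"sparse"`.
#' @param n_candidates size of the candidate pool.
#' @param seed integer seed.
#' @return A `coding_matrix`.
#' @export
random_code_matrix <- function(K, L, kind = c("dense", "sparse"),
                               n_candidates = 100L, seed = 1L) {
  kind <- match.arg(kind)
  if (K < 2L) stop("K must be at least 2")
  if (n_candidates < 1L) stop("n_candidates must be positive")
  best <- NULL
  best_d <- -Inf
  with_seed(seed, {
    for (c in seq_len(n_candidates)) {
      cand <- sample_code_candidate(K, L, kind)
      d <- min_row_distance(cand)
      if (d > best_d) { # strict: ties keep the first generated
        best <- cand
        best_d <- d
      }
    }
  })
  coding_matrix(best)
}

# Serialization helpers: {1, 0, NA} <-> {"1", "0", "D"} string rows.
code_to_strings <- function(code) {
  apply(code, 1, function(r) paste(ifelse(is.na(r), "D", r), collapse = ""))
}

strings_to_code <- function(rows) {
  m <- do.call(rbind, lapply(rows, function(r) {
    syms <- strsplit(r, "")[[1L]]
    if (!all(syms %in% c("0", "1", "D"))) stop("invalid code symbol in '", r, "'")
    match(syms, c("0", "1")) - 1L # "D" -> NA without coercion noise
  }))
  coding_matrix(m)
}
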