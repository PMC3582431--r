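# Seeded synthetic-data generators. Every generator is a pure function of
# its seed and parameters, so all tests and examples run without any
# external download.

#' Isotropic Gaussian class blobs
#'
#' Samples `n_per_class` points around each center with independent
#' N(0, sigma^2) noise per coordinate.
#'
#' @param centers K x d matrix of class centers (one row per class).
#' @param n_per_class points per class.
#' @param sigma within-class standard deviation.
#' @param seed integer seed.
#' @param class_names optional class labels (default `class1..classK`).
#' @return A [labeled_dataset()].
#' @export
gaussian_blobs <- function(centers, n_per_class = 100L, sigma = 1,
                           seed = 1L, class_names = NULL) {
  centers <- as_feature_matrix(centers)
  if (sigma <= 0) stop("sigma must be positive")
  K <- nrow(centers)
  d <- ncol(centers)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(K))
  X <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(K), function(k) {
      matrix(stats::rnorm(n_per_class * d, sd = sigma), ncol = d) +
        matrix(centers[k, ], n_per_class, d, byrow = TRUE)
    }))
  })
  labeled_dataset(X, rep(class_names, each = n_per_class), class_names = class_names)
}

#' Consistency-constructed generalized Bradley-Terry observations
#'
#' Given a known strictly positive class posterior `p_true` and a coding
#' matrix, builds the binary observations \eqn{\hat r_i = q_i^+ / q_i} that
#' the decomposition would produce if the model held exactly. Decoding such
#' a problem must recover `p_true`, which makes this the recovery oracle for
#' [decode_gbt()].
#'
#' @param p_true strictly positive probability vector over the K classes.
#' @param code a [coding_matrix()] with K rows.
#' @param weights optional per-problem weights `N_i` (default 1).
#' @return A [gbt_problem()] whose observations satisfy the model exactly.
#' @export
consistent_gbt_observations <- function(p_true, code, weights = NULL) {
  stopifnot(inherits(code, "coding_matrix"))
  p_true <- as.numeric(p_true)
  if (length(p_true) != nrow(code)) stop("p_true length must match code rows")
  if (any(p_true <= 0)) stop("p_true must be strictly positive")
  p_true <- p_true / sum(p_true)
  r <- vapply(seq_len(ncol(code)), function(i) {
    qpos <- sum(p_true[which(code[, i] == 1L)])
    qneg <- sum(p_true[which(code[, i] == 0L)])
    if (qpos + qneg <= 0) stop("column ", i, " has zero total mass under p_true")
    qpos / (qpos + qneg)
  }, numeric(1))
  gbt_problem(code, r, weights = weights)
}

# Class-specific first-order Markov model over A, C, G, U: uniform when
# bias_strength = 0, increasingly distinct transition tables as it grows.
class_markov_model <- function(bias_strength) {
  z_init <- stats::rnorm(4)
  z_trans <- matrix(stats::rnorm(16), 4, 4)
  init <- exp(bias_strength * z_init)
  init <- init / sum(init)
  trans <- exp(bias_strength * z_trans)
  trans <- trans / rowSums(trans)
  list(init = init, trans = trans)
}

#' Composition-biased random RNA sequences
#'
#' Each class draws sequences from its own randomly perturbed first-order
#' (dinucleotide) Markov chain over `{A, C, G, U}`, so k > 1 features carry
#' class signal. `bias_strength = 0` makes all classes identical (no
#' signal); larger values make them increasingly separable.
#'
#' @param K number of classes.
#' @param n_per_class sequences per class.
#' @param length_range integer pair; each sequence length is drawn uniformly
#'   from this range (in nt, minimum 5 so every k-block populates).
#' @param bias_strength non-negative scale of the class-specific
#'   perturbation.
#' @param seed integer seed.
#' @param class_names optional class labels.
#' @return List with `records` (data frame: `id`, `sequence`, `length`) and
#'   `labels`.
#' @export
synthetic_sequences <- function(K = 3L, n_per_class = 50L,
                                length_range = c(15L, 40L),
                                bias_strength = 1, seed = 1L,
                                class_names = NULL) {
  if (length_range[1L] < 5L) stop("minimum sequence length must be at least 5")
  if (bias_strength < 0) stop("bias_strength must be non-negative")
  if (is.null(class_names)) class_names <- paste0("class", seq_len(K))
  with_seed(seed, {
    models <- lapply(seq_len(K), function(k) class_markov_model(bias_strength))
    seqs <- character(0)
    labels <- character(0)
    ids <- character(0)
    for (k in seq_len(K)) {
      for (n in seq_len(n_per_class)) {
        len <- sample(seq(length_range[1L], length_range[2L]), 1L)
        s <- integer(len)
        s[1L] <- sample.int(4L, 1L, prob = models[[k]]$init)
        for (pos in seq_len(len - 1L)) {
          s[pos + 1L] <- sample.int(4L, 1L, prob = models[[k]]$trans[s[pos], ])
        }
        seqs <- c(seqs, paste(KMER_ALPHABET[s], collapse = ""))
        labels <- c(labels, class_names[k])
        ids <- c(ids, sprintf("%s_seq%03d", class_names[k], n))
      }
    }
    list(
      records = data.frame(
        id = ids, sequence = seqs, length = nchar(seqs),
        stringsAsFactors = FALSE
      ),
      labels = labels
    )
  })
}
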