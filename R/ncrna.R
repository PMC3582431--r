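# Sequence handling for the small non-coding RNA application: FASTA I/O,
# sampling of 20-nt fragments from long background sequences, and per-k
# normalized k-mer frequency features (k = 1..5, 1364 dimensions).
#
# Mature miRNAs (~15-33 nt) and piRNAs (~16-40 nt) lack strong secondary
# structure, so classification rests on sequence composition alone; k-mer
# frequencies are the feature representation. Background ("other") ncRNAs
# are typically much longer, so a random 20-nt fragment — a length both a
# miRNA and a piRNA could have — stands in for each.

KMER_ALPHABET <- c("A", "C", "G", "U")

canonicalize_rna <- function(s) chartr("Tt", "Uu", toupper(s))

#' Read RNA/DNA sequences from FASTA
#'
#' Sequences are uppercased and T is mapped to U. Records containing
#' characters outside `{A, C, G, U, N}` are skipped with a warning.
#'
#' @param path path to a FASTA file.
#' @return A data frame with columns `id`, `sequence` and `length`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("could not parse FASTA file: ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("no records found in ", path)
  seqs <- canonicalize_rna(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  ok <- grepl("^[ACGUN]+$", seqs)
  if (any(!ok)) {
    warning(
      sum(!ok), " record(s) with characters outside {A,C,G,U,N} skipped: ",
      paste(utils::head(ids[!ok], 5L), collapse = ", ")
    )
  }
  if (!any(ok)) stop("no parseable records in ", path)
  data.frame(
    id = ids[ok], sequence = unname(seqs[ok]),
    length = nchar(seqs[ok]), stringsAsFactors = FALSE
  )
}

#' Write sequence records to FASTA
#'
#' @param records data frame with columns `id` and `sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Sample a fixed-length fragment from each sequence
#'
#' Sequences no longer than `length` are returned unchanged; longer ones are
#' replaced by a uniformly random contiguous fragment of exactly `length`
#' nt. The fragment start is a deterministic function of `seed` and the
#' record id, so results do not depend on record order.
#'
#' @param records data frame with columns `id` and `sequence`.
#' @param length fragment length in nt (default 20).
#' @param seed integer seed.
#' @return The records with fragmented sequences and updated `length`.
#' @export
sample_fragment <- function(records, length = 20L, seed = 1L) {
  if (length < 1L) stop("fragment length must be at least 1")
  out <- records
  for (r in seq_len(nrow(out))) {
    s <- out$sequence[r]
    n <- nchar(s)
    if (n > length) {
      start <- with_seed((seed + string_hash(out$id[r])) %% 2147483647, {
        sample.int(n - length + 1L, 1L)
      })
      out$sequence[r] <- substr(s, start, start + length - 1L)
    }
  }
  out$length <- nchar(out$sequence)
  out
}

#' Per-k normalized k-mer frequency features
#'
#' For each k in `1..k_max`, all length-k windows over `{A, C, G, U}` are
#' counted (windows containing N are skipped) and the counts are divided by
#' the number of counted windows, so each k-block is a probability vector —
#' or all zeros if a sequence has no valid window of that length. Blocks are
#' concatenated in k order, each lexicographically ordered with A < C < G <
#' U; for `k_max = 5` the result has 4 + 16 + 64 + 256 + 1024 = 1364
#' columns.
#'
#' @param sequences character vector of canonicalized RNA sequences (use
#'   [read_fasta()] or [canonicalize_rna] conventions: uppercase, U not T).
#' @param k_max largest k-mer length.
#' @return Numeric matrix, one row per sequence.
#' @export
kmer_features <- function(sequences, k_max = 5L) {
  sequences <- canonicalize_rna(sequences)
  if (any(!grepl("^[ACGUN]+$", sequences))) {
    stop("sequences must contain only A, C, G, U, N after canonicalization")
  }
  set <- Biostrings::RNAStringSet(sequences)
  blocks <- lapply(seq_len(k_max), function(k) {
    counts <- Biostrings::oligonucleotideFrequency(set, width = k)
    valid <- rowSums(counts)
    if (k == 1L && any(valid == 0)) {
      stop("sequence(s) with no valid 1-mer window (all N): ",
           paste(utils::head(which(valid == 0), 5L), collapse = ", "))
    }
    norm <- counts / ifelse(valid > 0, valid, 1)
    norm[valid == 0, ] <- 0
    colnames(norm) <- paste0("k", k, "_", colnames(counts))
    norm
  })
  do.call(cbind, blocks)
}

#' Featurize a labeled sequence collection
#'
#' Applies fragment sampling to the background class(es), optionally
#' balances all classes down to the minority count, and converts each
#' sequence to its k-mer feature vector.
#'
#' @param records data frame with columns `id` and `sequence`.
#' @param labels class label per record.
#' @param fragment_length fragment length for the background class.
#' @param fragment_classes labels whose sequences longer than
#'   `fragment_length` are replaced by a random fragment (the background
#'   "other ncRNA" class); `NULL` fragments nothing. Short regulatory RNAs
#'   (miRNA, piRNA) are used whole.
#' @param balance if `TRUE`, downsample every class to the size of the
#'   smallest.
#' @param seed integer seed for fragmenting and balancing.
#' @param k_max largest k-mer length.
#' @return A [labeled_dataset()] of k-mer features.
#' @export
featurize_dataset <- function(records, labels, fragment_length = 20L,
                              fragment_classes = NULL, balance = FALSE,
                              seed = 1L, k_max = 5L) {
  labels <- as.character(labels)
  if (nrow(records) != length(labels)) stop("records and labels disagree in length")
  if (!is.null(fragment_classes)) {
    frag <- labels %in% fragment_classes
    if (any(frag)) {
      records[frag, ] <- sample_fragment(
        records[frag, , drop = FALSE],
        length = fragment_length, seed = seed
      )
    }
  }
  if (balance) {
    n_min <- min(table(labels))
    keep <- with_seed(seed, {
      unlist(lapply(split(seq_along(labels), labels), function(idx) {
        sort(sample(idx, n_min))
      }), use.names = FALSE)
    })
    keep <- sort(keep)
    records <- records[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(labels) == 0L || any(table(labels) == 0L)) {
    stop("a class is empty after filtering")
  }
  labeled_dataset(kmer_features(records$sequence, k_max = k_max), labels)
}
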