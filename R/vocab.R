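#' K-mer vocabulary
#'
#' Enumerates all `4^k` k-mers over the DNA alphabet in lexicographic order
#' (A < C < G < T). The vocabulary defines the feature ("word") space of the
#' topic model: column `i` of every bulk or frame count matrix corresponds to
#' `kmers[i]`.
#'
#' @param k k-mer length in nucleotides, between 1 and 8.
#' @return An object of class `kmer_vocabulary`: a list with elements `k`,
#'   `kmers` (character vector of length `4^k`) and `index` (named integer
#'   vector mapping each k-mer to its column).
#' @examples
#' v <- kmer_vocabulary(2)
#' v$kmers[1:4]
#' v$index["TT"]
#' @export
kmer_vocabulary <- function(k) {
  k <- .check_k(k)
  bases <- c("A", "C", "G", "T")
  kmers <- bases
  if (k > 1) {
    for (i in 2:k) kmers <- as.vector(t(outer(kmers, bases, paste0)))
  }
  index <- seq_along(kmers)
  names(index) <- kmers
  structure(list(k = k, kmers = kmers, index = index),
            class = "kmer_vocabulary")
}

#' @export
print.kmer_vocabulary <- function(x, ...) {
  cat(sprintf("k-mer vocabulary: k = %d, %d k-mers (%s ... %s)\n",
              x$k, length(x$kmers), x$kmers[1], x$kmers[length(x$kmers)]))
  invisible(x)
}

.check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k != as.integer(k) ||
      k < 1 || k > 8) {
    stop("'k' must be a single integer in [1, 8]", call. = FALSE)
  }
  as.integer(k)
}

# byte -> base code lookup (A=0, C=1, G=2, T=3, anything else NA)
.base_code <- local({
  x <- rep(NA_integer_, 256)
  x[utf8ToInt("A")] <- 0L
  x[utf8ToInt("C")] <- 1L
  x[utf8ToInt("G")] <- 2L
  x[utf8ToInt("T")] <- 3L
  x
})

# Vocabulary index (1-based) of the k-mer starting at every offset of `seq`;
# NA where the window contains a non-ACGT base. Length nchar(seq) - k + 1.
kmer_indices <- function(seq, k) {
  k <- .check_k(k)
  n <- nchar(seq)
  if (n < k) {
    stop(sprintf("sequence of length %d has no k-mer windows for k = %d",
                 n, k), call. = FALSE)
  }
  code <- .base_code[utf8ToInt(seq)]
  m <- n - k + 1L
  idx <- rep(0L, m)
  for (j in seq_len(k)) idx <- idx * 4L + code[j:(j + m - 1L)]
  idx + 1L
}
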