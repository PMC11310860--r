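#' Bernoulli Kullback-Leibler divergence
#'
#' KL divergence (in nats) between two Bernoulli distributions with success
#' probabilities `p` and `q`: the distinctiveness of observing a particular
#' k-mer with probability `p` under one topic versus `q` under another.
#' Probabilities are clamped to `[1e-12, 1 - 1e-12]` to guard against
#' round-off in serialized models.
#'
#' @param p,q probabilities (vectorized).
#' @return `p*log(p/q) + (1-p)*log((1-p)/(1-q))`, non-negative, zero iff
#'   `p == q`.
#' @examples
#' bernoulli_kl(0.5, 0.25)
#' bernoulli_kl(0.25, 0.5)  # asymmetric
#' @export
bernoulli_kl <- function(p, q) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  q <- pmin(pmax(q, eps), 1 - eps)
  p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))
}

#' Driving k-mers of each topic
#'
#' Identifies the features that most distinctively characterize each topic.
#' For feature `w` and topic `t`, distinctiveness is the minimum Bernoulli
#' KL divergence between `phi[t, w]` and `phi[t', w]` over all other topics
#' `t'` (the conservative aggregation: a feature is only as distinctive as
#' its closest competitor). Each feature is assigned to the topic where it
#' is most distinctive, and each topic reports its assigned features ranked
#' by descending distinctiveness, truncated to `top_n`. Ties are broken by
#' lexicographic feature id.
#'
#' @param model a fitted [seqlda()] model with at least 2 topics.
#' @param top_n features reported per topic.
#' @return A data.frame of class `driving_kmer_table` with columns `topic`,
#'   `rank`, `feature`, `distinctiveness` (nats).
#' @export
driving_features <- function(model, top_n = 10L) {
  stopifnot(inherits(model, "seqlda"))
  K <- model$n_topics
  if (K < 2)
    stop("driving features are undefined for a single-topic model",
         call. = FALSE)
  top_n <- as.integer(top_n)
  if (is.na(top_n) || top_n < 1) stop("'top_n' must be >= 1", call. = FALSE)
  phi <- model$phi
  V <- ncol(phi)
  d <- matrix(Inf, K, V)
  for (t in seq_len(K)) {
    for (o in seq_len(K)) {
      if (o == t) next
      d[t, ] <- pmin(d[t, ], bernoulli_kl(phi[t, ], phi[o, ]))
    }
  }
  assigned <- apply(d, 2, which.max)  # first topic wins exact ties
  out <- list()
  for (t in seq_len(K)) {
    w <- which(assigned == t)
    if (length(w) == 0) {
      out[[t]] <- data.frame(topic = integer(0), rank = integer(0),
                             feature = character(0),
                             distinctiveness = numeric(0))
      next
    }
    feats <- colnames(phi)[w]
    score <- d[t, w]
    ord <- order(-score, feats)
    keep <- utils::head(ord, top_n)
    out[[t]] <- data.frame(topic = t, rank = seq_along(keep),
                           feature = feats[keep],
                           distinctiveness = score[keep],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("driving_kmer_table", "data.frame")
  res
}

#' Long-format structure-plot data
#'
#' Flattens a membership matrix into the (sample, group, topic, proportion)
#' long table that any plotting layer can consume, optionally sorting
#' samples within each group by one topic's proportion (the usual
#' structure-plot ordering).
#'
#' @param memberships samples x topics membership matrix (rows sum to 1).
#' @param group per-sample labels; defaults to a single group.
#' @param sort_by topic id (column index or name) to sort by, or `NULL`.
#' @return A data.frame with one row per (sample, topic).
#' @export
export_structure_data <- function(memberships, group = NULL, sort_by = NULL) {
  theta <- as.matrix(memberships)
  if (is.null(rownames(theta)))
    rownames(theta) <- sprintf("sample%d", seq_len(nrow(theta)))
  if (is.null(colnames(theta)))
    colnames(theta) <- paste0("topic", seq_len(ncol(theta)))
  if (is.null(group)) group <- rep("all", nrow(theta))
  if (length(group) != nrow(theta))
    stop("'group' must have one entry per sample", call. = FALSE)
  ord <- seq_len(nrow(theta))
  if (!is.null(sort_by)) {
    if (is.character(sort_by)) sort_by <- match(sort_by, colnames(theta))
    if (is.na(sort_by) || sort_by < 1 || sort_by > ncol(theta))
      stop("unknown sort topic", call. = FALSE)
    ord <- order(match(group, unique(group)), -theta[, sort_by])
  }
  theta <- theta[ord, , drop = FALSE]
  group <- group[ord]
  data.frame(
    sample = rep(rownames(theta), each = ncol(theta)),
    group = rep(group, each = ncol(theta)),
    topic = rep(colnames(theta), times = nrow(theta)),
    proportion = as.vector(t(theta)),
    stringsAsFactors = FALSE)
}

#' Position weight matrix from anchored sequences
#'
#' Base frequencies per position over a region relative to each record's
#' anchor, for sequence-logo style summaries. N bases are excluded from
#' both numerator and denominator; every column sums to 1 over the counted
#' A/C/G/T.
#'
#' @param seqs sequence records with anchors.
#' @param region integer pair `c(start, end)`: half-open position range
#'   relative to the anchor.
#' @return A (end-start) x 4 matrix with columns A, C, G, T and rownames
#'   the positions.
#' @export
pwm_from_sequences <- function(seqs, region) {
  seqs <- as_seq_records(seqs)
  region <- .check_region(region)
  positions <- seq.int(region[1], region[2] - 1L)
  off <- outer(seqs$anchor, positions, "+")  # n_seqs x n_pos, 0-based
  if (any(off < 0) || any(off >= nchar(seqs$seq))) {
    stop("some sequences do not cover the requested region", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  pwm <- matrix(0, length(positions), 4,
                dimnames = list(as.character(positions), bases))
  chars <- strsplit(seqs$seq, "", fixed = TRUE)
  for (j in seq_along(positions)) {
    col <- vapply(seq_len(nrow(seqs)),
                  function(i) chars[[i]][off[i, j] + 1L], character(1))
    cnt <- table(factor(col, levels = bases))
    tot <- sum(cnt)
    if (tot == 0)
      stop(sprintf("zero ACGT coverage at position %d", positions[j]),
           call. = FALSE)
    pwm[j, ] <- as.numeric(cnt) / tot
  }
  pwm
}
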