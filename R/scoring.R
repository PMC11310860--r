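#' Log-likelihood of a sequence under one topic
#'
#' Scores how well a topic's k-mer distribution reproduces a sequence: the
#' sum of `log(phi[topic, w])` over every overlapping k-mer window `w` of
#' the sequence (the log of the product of per-window emission
#' probabilities). Windows containing non-ACGT bases are skipped. Returned
#' in log space (nats) only; exponentiating underflows for realistic
#' lengths.
#'
#' @param seq a single nucleotide string.
#' @param model a fitted [seqlda()] model over plain (bulk/frame) k-mer
#'   features.
#' @param topic topic index (or `topicN` name).
#' @param k k-mer length of the model's features.
#' @return The log-likelihood in nats.
#' @export
sequence_log_likelihood <- function(seq, model, topic, k) {
  stopifnot(inherits(model, "seqlda"))
  if (is.character(topic)) topic <- match(topic, rownames(model$phi))
  if (is.na(topic) || topic < 1 || topic > model$n_topics)
    stop("invalid topic", call. = FALSE)
  if (length(model$feature_ids) != 4^k ||
      any(nchar(model$feature_ids) != k)) {
    stop("model features are not plain k-mers of the given length",
         call. = FALSE)
  }
  idx <- kmer_indices(toupper(seq), k)
  idx <- idx[!is.na(idx)]
  sum(log(pmax(model$phi[topic, ], 1e-300))[idx])
}

#' Log-likelihood of a count vector under one topic
#'
#' Multinomial log-likelihood of a sample's k-mer counts under a topic's
#' feature distribution, up to the count-only combinatorial constant (which
#' is topic-independent and omitted): `sum(counts * log(phi[topic, ]))`.
#' Used to ask which topic best reproduces the k-mer composition at each
#' position of an alignment.
#'
#' @param counts a named count vector (one row of a [count_matrix()]).
#' @param model a fitted [seqlda()] model.
#' @param topic topic index or name.
#' @return The log-likelihood in nats (0 for an all-zero vector).
#' @export
position_log_likelihood <- function(counts, model, topic) {
  stopifnot(inherits(model, "seqlda"))
  if (is.character(topic)) topic <- match(topic, rownames(model$phi))
  if (is.na(topic) || topic < 1 || topic > model$n_topics)
    stop("invalid topic", call. = FALSE)
  counts <- if (inherits(counts, "count_matrix")) drop(.as_counts(counts))
            else counts
  if (is.null(names(counts)) || !all(names(counts) %in% model$feature_ids))
    stop("count vector features do not match the model", call. = FALSE)
  phi <- model$phi[topic, names(counts)]
  sum(counts * log(pmax(phi, 1e-300)))
}

#' Topic-to-label enrichment scores
#'
#' Associates topics with sample labels: the score of topic `t` for a label
#' is `log2` of the ratio between the average membership of `t` over that
#' label's samples and the average membership of `t` over all samples.
#' Positive scores mark topics enriched in a label.
#'
#' @param memberships samples x topics membership matrix.
#' @param labels per-sample class labels (every label needs >= 1 sample).
#' @return A topics x labels matrix of log2 enrichment scores (class
#'   `label_score_matrix`).
#' @export
topic_label_scores <- function(memberships, labels) {
  theta <- as.matrix(memberships)
  labels <- as.character(labels)
  if (length(labels) != nrow(theta))
    stop("'labels' must have one entry per sample", call. = FALSE)
  if (any(is.na(labels)))
    stop("labels contain NA", call. = FALSE)
  labs <- sort(unique(labels))
  overall <- colMeans(theta)
  scores <- vapply(labs, function(l) {
    rows <- labels == l
    log2(colMeans(theta[rows, , drop = FALSE]) / overall)
  }, numeric(ncol(theta)))
  if (is.null(colnames(theta)))
    rownames(scores) <- paste0("topic", seq_len(ncol(theta)))
  else rownames(scores) <- colnames(theta)
  class(scores) <- c("label_score_matrix", "matrix", "array")
  scores
}

#' Predict a label from one membership vector
#'
#' The second half of the two-step classifier: multiply the membership
#' vector by the topic-score matrix and pick the label with the highest
#' score. Exact ties go to the alphabetically first label (score columns
#' are kept in sorted label order).
#'
#' @param membership one row of a membership matrix (length = topics).
#' @param scores a [topic_label_scores()] matrix.
#' @return The predicted label (character).
#' @export
predict_label <- function(membership, scores) {
  membership <- as.numeric(membership)
  if (length(membership) != nrow(scores))
    stop("membership length does not match the score matrix", call. = FALSE)
  s <- as.numeric(membership %*% unclass(scores))
  colnames(scores)[which.max(s)]
}

#' Classify the reading frames of coding sequences
#'
#' Runs the frame classifier on each sequence: count k-mers in the three
#' reading frames, transform each frame's counts into topic memberships,
#' and predict a frame label for each. A sequence is fully correct when the
#' predicted triple is (1, 2, 3); the triples (2, 3, 1) and (3, 1, 2) are
#' cyclic shifts flagged as potential frame-shift events.
#'
#' @param seqs sequence records or a character vector of CDS sequences in
#'   annotated frame 1.
#' @param model a fitted [seqlda()] model over plain k-mer features.
#' @param scores a [topic_label_scores()] matrix with labels
#'   `frame1/frame2/frame3`.
#' @param k k-mer length.
#' @return A data.frame of class `frame_prediction` with columns `id`,
#'   `frame1`, `frame2`, `frame3` (predicted frame for each true frame),
#'   `all_correct`, `frameshift`.
#' @export
classify_reading_frames <- function(seqs, model, scores, k) {
  seqs <- as_seq_records(seqs)
  if (!all(c("frame1", "frame2", "frame3") %in% colnames(scores)))
    stop("'scores' must carry labels frame1, frame2, frame3", call. = FALSE)
  if (any(nchar(seqs$seq) < k + 2))
    stop("sequences must be at least k + 2 long to populate all frames",
         call. = FALSE)
  m <- build_kmer_matrix(seqs, mode = "frame", k = k)
  pred <- predict.seqlda(model, m, type = "label", scores = scores)
  pf <- matrix(as.integer(sub("^frame", "", pred)), ncol = 3, byrow = TRUE)
  all_correct <- pf[, 1] == 1L & pf[, 2] == 2L & pf[, 3] == 3L
  frameshift <- (pf[, 1] == 2L & pf[, 2] == 3L & pf[, 3] == 1L) |
                (pf[, 1] == 3L & pf[, 2] == 1L & pf[, 3] == 2L)
  out <- data.frame(id = seqs$id, frame1 = pf[, 1], frame2 = pf[, 2],
                    frame3 = pf[, 3], all_correct = all_correct,
                    frameshift = frameshift, stringsAsFactors = FALSE)
  class(out) <- c("frame_prediction", "data.frame")
  out
}

#' Extract the centered subsequence of a CDS
#'
#' Returns the `3 * n_codons`-long substring centered on the sequence
#' midpoint, with the start snapped down to the nearest codon boundary so
#' that the subsequence's frame 1 coincides with the parent's frame 1.
#'
#' @param seq a CDS string with length divisible by 3.
#' @param n_codons number of codons to keep (`3 * n_codons <= nchar(seq)`).
#' @return The subsequence (character).
#' @examples
#' centered_subsequence(strrep("ATG", 100), 30)
#' @export
centered_subsequence <- function(seq, n_codons) {
  L <- nchar(seq)
  if (L %% 3 != 0) stop("sequence length must be divisible by 3",
                        call. = FALSE)
  m <- 3L * as.integer(n_codons)
  if (is.na(m) || m < 3) stop("'n_codons' must be >= 1", call. = FALSE)
  if (m > L) stop("requested subsequence exceeds the sequence", call. = FALSE)
  start <- ((L - m) %/% 2L) %/% 3L * 3L  # 0-based, codon-aligned
  substr(seq, start + 1L, start + m)
}

#' Fit the two-step reading-frame classifier
#'
#' Convenience wrapper for the frame workflow: featurize training CDS in
#' frame mode (three frame-tagged samples per sequence), pool same-frame
#' samples into packs, fit an LDA model, and derive the topic-to-frame
#' score matrix from the training memberships.
#'
#' @param train sequence records or character vector of CDS in frame 1.
#' @param k k-mer length (hexamers by default).
#' @param pack sequences pooled per sample.
#' @param n_topics topics (one per frame by default).
#' @param seed integer seed (drives pooling and model initialization).
#' @param ... passed to [seqlda()].
#' @return A list of class `frame_classifier` with elements `model`,
#'   `scores`, `k`.
#' @export
fit_frame_classifier <- function(train, k = 6L, pack = 50L, n_topics = 3L,
                                 seed = 1L, ...) {
  m <- build_kmer_matrix(train, mode = "frame", k = k)
  pooled <- pool_samples(m, pack = pack, seed = seed)
  model <- seqlda(pooled, n_topics = n_topics, seed = seed, ...)
  scores <- topic_label_scores(model$theta, pooled$labels)
  structure(list(model = model, scores = scores, k = .check_k(k)),
            class = "frame_classifier")
}

#' @export
print.frame_classifier <- function(x, ...) {
  cat(sprintf("reading-frame classifier: k = %d, %d topics\n",
              x$k, x$model$n_topics))
  print(round(unclass(x$scores), 3))
  invisible(x)
}

#' @export
predict.frame_classifier <- function(object, newdata, ...) {
  classify_reading_frames(newdata, object$model, object$scores, object$k)
}
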