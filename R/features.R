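#' Count bulk k-mers in a sequence
#'
#' Counts every overlapping k-mer window of the sequence, regardless of
#' position. Windows containing a non-ACGT base are skipped entirely (they
#' contribute to neither numerator nor denominator anywhere in the package).
#'
#' @param seq a single nucleotide string.
#' @param k k-mer length.
#' @return A named integer vector over the full `4^k` vocabulary; its sum is
#'   the number of valid windows, at most `nchar(seq) - k + 1`.
#' @examples
#' v <- count_bulk_kmers("AGTTAT", 4)
#' v[v > 0]  # AGTT, GTTA, TTAT each once
#' @export
count_bulk_kmers <- function(seq, k) {
  idx <- kmer_indices(toupper(seq), k)
  vocab <- kmer_vocabulary(k)
  out <- tabulate(idx, nbins = length(vocab$kmers))
  names(out) <- vocab$kmers
  out
}

#' Count positional k-mers relative to an anchor
#'
#' Couples each k-mer with its start position relative to the alignment
#' anchor, producing features rendered `KMER_at_POS` (e.g. `CCAG_at_-4`).
#' Position `p` denotes the k-mer whose first base sits at 0-based sequence
#' offset `anchor + p`.
#'
#' @param seq a single nucleotide string.
#' @param k k-mer length.
#' @param region integer pair `c(start, end)`: the half-open range of k-mer
#'   start positions, relative to the anchor.
#' @param anchor 0-based offset of the alignment point within `seq`.
#' @return A named integer vector with one entry per (position, k-mer) pair,
#'   ordered position-major; each valid start position contributes one
#'   count.
#' @examples
#' v <- count_positional_kmers("AGTTAT", 4, c(1, 4), anchor = -1)
#' v[v > 0]  # AGTT_at_1, GTTA_at_2, TTAT_at_3
#' @export
count_positional_kmers <- function(seq, k, region, anchor = 0L) {
  seq <- toupper(seq)
  k <- .check_k(k)
  region <- .check_region(region)
  positions <- seq.int(region[1], region[2] - 1L)
  off <- anchor + positions            # 0-based k-mer start offsets
  if (any(off < 0L) || any(off + k > nchar(seq))) {
    stop(sprintf("region [%d, %d) with k = %d falls outside the sequence",
                 region[1], region[2], k), call. = FALSE)
  }
  idx <- kmer_indices(seq, k)
  vocab <- kmer_vocabulary(k)
  V <- length(vocab$kmers)
  out <- integer(length(positions) * V)
  names(out) <- positional_feature_ids(vocab$kmers, positions)
  hit <- idx[off + 1L]                 # vocab index at each position, NA skip
  ok <- !is.na(hit)
  slot <- (seq_along(positions)[ok] - 1L) * V + hit[ok]
  tab <- tabulate(slot, nbins = length(out))
  out[] <- tab
  out
}

positional_feature_ids <- function(kmers, positions) {
  as.vector(vapply(positions, function(p) paste0(kmers, "_at_", p),
                   character(length(kmers))))
}

.check_region <- function(region) {
  if (!is.numeric(region) || length(region) != 2 || any(is.na(region)) ||
      any(region != as.integer(region)) || region[2] <= region[1]) {
    stop("'region'/'positions' must be an integer pair c(start, end) with end > start",
         call. = FALSE)
  }
  as.integer(region)
}

#' Count k-mers by reading frame
#'
#' Assigns the k-mer starting at 0-based offset `i` of a coding sequence
#' (annotated frame 1 starting at its first base) to reading frame
#' `(i %% 3) + 1` and counts each frame separately. The three frame totals
#' sum to the bulk total.
#'
#' @param seq a single CDS string in annotated frame 1.
#' @param k k-mer length.
#' @return A 3 x `4^k` integer matrix with rownames `frame1..frame3`.
#' @examples
#' m <- count_frame_kmers("ATGGCA", 3)
#' m[, colSums(m) > 0]
#' @export
count_frame_kmers <- function(seq, k) {
  idx <- kmer_indices(toupper(seq), k)
  vocab <- kmer_vocabulary(k)
  V <- length(vocab$kmers)
  frame <- ((seq_along(idx) - 1L) %% 3L) + 1L
  out <- matrix(0L, 3L, V, dimnames = list(paste0("frame", 1:3), vocab$kmers))
  for (f in 1:3) {
    sub <- idx[frame == f]
    out[f, ] <- tabulate(sub[!is.na(sub)], nbins = V)
  }
  out
}

#' Build a positions-as-samples count matrix
#'
#' Implements the positions-as-samples featurization: sequences are aligned
#' at their anchors and, for each window start position `p` in `positions`,
#' one sample collects the counts of k-mers starting at any position in
#' `[p, p + window)` across all sequences. With all windows valid each row
#' sums to `window * n_seqs`.
#'
#' Sequences that do not cover the requested positions (plus `k - 1`
#' downstream bases) are rejected with a warning rather than silently
#' truncated.
#'
#' @param seqs sequence records (see [seq_records()]) with anchors set.
#' @param k k-mer length.
#' @param window sliding-window size in positions.
#' @param positions integer pair `c(start, end)`: half-open range of window
#'   start positions relative to the anchor.
#' @return A [count_matrix()] in mode `position_window` whose samples are
#'   window start positions (most upstream position of the window).
#' @export
build_position_sample_matrix <- function(seqs, k, window, positions) {
  seqs <- as_seq_records(seqs)
  k <- .check_k(k)
  window <- as.integer(window)
  if (is.na(window) || window < 1) stop("'window' must be >= 1", call. = FALSE)
  positions <- .check_region(positions)
  starts <- seq.int(positions[1], positions[2] - 1L)
  # k-mer start positions needed to cover every window
  kpos <- seq.int(positions[1], positions[2] + window - 2L)

  need_lo <- kpos[1]
  need_hi <- kpos[length(kpos)] + k    # one past last base used
  covered <- seqs$anchor + need_lo >= 0L & seqs$anchor + need_hi <= nchar(seqs$seq)
  if (!all(covered)) {
    warning(sprintf("rejecting %d sequence(s) too short for positions [%d, %d): %s",
                    sum(!covered), positions[1], positions[2],
                    paste(utils::head(seqs$id[!covered], 5), collapse = ", ")),
            call. = FALSE)
    seqs <- seqs[covered, , drop = FALSE]
  }
  if (nrow(seqs) == 0) stop("no sequence covers the requested positions",
                            call. = FALSE)
  vocab <- kmer_vocabulary(k)
  V <- length(vocab$kmers)
  # per-k-mer-start-position counts across sequences
  per_pos <- matrix(0L, length(kpos), V)
  idx_list <- lapply(seqs$seq, kmer_indices, k = k)
  for (j in seq_along(kpos)) {
    off <- seqs$anchor + kpos[j] + 1L  # 1-based window index per sequence
    hit <- mapply(function(ix, o) ix[o], idx_list, off)
    per_pos[j, ] <- tabulate(hit[!is.na(hit)], nbins = V)
  }
  counts <- matrix(0L, length(starts), V,
                   dimnames = list(as.character(starts), vocab$kmers))
  for (i in seq_along(starts)) {
    rows <- i:(i + window - 1L)
    counts[i, ] <- as.integer(colSums(per_pos[rows, , drop = FALSE]))
  }
  count_matrix(counts, mode = "position_window", k = k,
               meta = list(window = window, positions = positions,
                           n_seqs = nrow(seqs)))
}

#' Build a sequences-as-samples count matrix
#'
#' Featurizes each sequence record as one sample (three frame-tagged samples
#' in `frame` mode) using bulk, positional or frame counting.
#'
#' @param seqs sequence records or a character vector of sequences.
#' @param mode `"bulk"`, `"positional"` or `"frame"`.
#' @param k k-mer length.
#' @param region required for positional mode: half-open range of k-mer
#'   start positions relative to each record's anchor.
#' @return A [count_matrix()] carrying the records' labels (`frame` mode
#'   replaces them with `frame1..frame3`; sample ids become `id|frameN`).
#' @export
build_kmer_matrix <- function(seqs, mode = c("bulk", "positional", "frame"),
                              k, region = NULL) {
  seqs <- as_seq_records(seqs)
  mode <- match.arg(mode)
  k <- .check_k(k)
  labels <- if (all(is.na(seqs$label))) NULL else seqs$label
  vocab <- kmer_vocabulary(k)
  if (mode == "bulk") {
    counts <- t(vapply(seqs$seq, count_bulk_kmers, integer(4^k), k = k,
                       USE.NAMES = FALSE))
    dimnames(counts) <- list(seqs$id, vocab$kmers)
    return(count_matrix(counts, "bulk", k, labels = labels))
  }
  if (mode == "positional") {
    if (is.null(region)) stop("positional mode needs 'region'", call. = FALSE)
    region <- .check_region(region)
    counts <- t(mapply(function(s, a) {
      count_positional_kmers(s, k, region, anchor = a)
    }, seqs$seq, seqs$anchor))
    dimnames(counts) <- list(
      seqs$id,
      positional_feature_ids(vocab$kmers, seq.int(region[1], region[2] - 1L)))
    return(count_matrix(counts, "positional", k, labels = labels,
                        meta = list(region = region)))
  }
  # frame mode: 3 samples per sequence
  mats <- lapply(seqs$seq, count_frame_kmers, k = k)
  counts <- do.call(rbind, mats)
  rownames(counts) <- as.vector(vapply(seqs$id, function(i)
    paste0(i, "|frame", 1:3), character(3)))
  count_matrix(counts, "frame", k,
               labels = rep(paste0("frame", 1:3), nrow(seqs)))
}

#' Pool same-label samples into packs
#'
#' Groups samples of the same label into packs of `pack` and sums their
#' counts, raising the per-sample token total before model fitting (single
#' sequences have zero counts for most features, which starves the topic
#' model). Within each label the samples are shuffled with the given seed,
#' then grouped into consecutive packs; an incomplete final pack is dropped
#' so every output sample aggregates exactly `pack` inputs.
#'
#' @param m a [count_matrix()].
#' @param pack number of samples per pack, `>= 1`.
#' @param seed integer seed for the within-label shuffle.
#' @param labels per-sample labels; defaults to the matrix's own.
#' @return A [count_matrix()] with one row per pack, labelled by the pack's
#'   label and named `label_pack<i>`.
#' @export
pool_samples <- function(m, pack, seed = 1L, labels = NULL) {
  counts <- .as_counts(m)
  if (is.null(labels)) {
    labels <- if (inherits(m, "count_matrix")) m$labels else NULL
  }
  if (is.null(labels)) labels <- rep("all", nrow(counts))
  labels <- as.character(labels)
  if (length(labels) != nrow(counts))
    stop("'labels' must have one entry per sample", call. = FALSE)
  pack <- as.integer(pack)
  if (is.na(pack) || pack < 1) stop("'pack' must be >= 1", call. = FALSE)
  tab <- table(labels)
  short <- names(tab)[tab < pack]
  if (length(short) > 0) {
    stop(sprintf("pack = %d exceeds the sample count of label(s): %s",
                 pack, paste(short, collapse = ", ")), call. = FALSE)
  }
  set.seed(seed)
  out_rows <- list()
  out_labels <- character(0)
  for (lab in sort(unique(labels))) {
    rows <- which(labels == lab)
    rows <- rows[sample.int(length(rows))]
    n_pack <- length(rows) %/% pack
    grp <- rep(seq_len(n_pack), each = pack)
    rows <- rows[seq_len(n_pack * pack)]
    pooled <- rowsum(counts[rows, , drop = FALSE], group = grp, reorder = TRUE)
    rownames(pooled) <- sprintf("%s_pack%d", lab, seq_len(n_pack))
    out_rows[[lab]] <- pooled
    out_labels <- c(out_labels, rep(lab, n_pack))
  }
  pooled <- do.call(rbind, out_rows)
  km <- if (inherits(m, "count_matrix")) m$k else 1L
  md <- if (inherits(m, "count_matrix")) m$mode else "bulk"
  meta <- if (inherits(m, "count_matrix")) m$meta else list()
  meta$pack <- pack
  meta$pool_seed <- seed
  count_matrix(pooled, mode = md, k = km, labels = out_labels, meta = meta)
}
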