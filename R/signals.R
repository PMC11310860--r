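#' IUPAC containment match
#'
#' Tests whether an IUPAC degenerate pattern occurs as a contiguous
#' substring of a k-mer (containment semantics: a 6-mer "contains" the
#' branch-site core TNAC if the pattern matches at any offset). The
#' all-pyrimidine pattern YYYYYY matches exactly the k-mers made only of C
#' and T.
#'
#' @param kmer k-mer string (vectorized).
#' @param pattern IUPAC pattern, no longer than the k-mer.
#' @return Logical vector.
#' @examples
#' motif_match("GCTAAC", "TNAC")
#' motif_match(c("TTTTCC", "TTTATC"), "YYYYYY")
#' @export
motif_match <- function(kmer, pattern) {
  rx <- iupac_regex(pattern)
  if (any(nchar(pattern) > nchar(kmer)))
    stop("pattern longer than k-mer", call. = FALSE)
  grepl(rx, toupper(kmer))
}

.iupac <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% names(.iupac))
  if (any(bad))
    stop(sprintf("invalid IUPAC code(s): %s",
                 paste(unique(chars[bad]), collapse = ", ")), call. = FALSE)
  paste0(vapply(chars, function(ch) {
    ex <- .iupac[[ch]]
    if (nchar(ex) == 1) ex else paste0("[", ex, "]")
  }, character(1)), collapse = "")
}

#' Position-wise motif-fraction curve
#'
#' Computes, for each window start position relative to the anchor, the
#' fraction of k-mers (across all sequences and the `window` adjacent
#' positions) that contain the IUPAC pattern; this raw fraction is then
#' divided by `window * k` to give the reported per-position value. Both
#' values are returned, and the curve is computed per label when the
#' records carry labels.
#'
#' @param seqs anchored sequence records.
#' @param pattern IUPAC pattern (e.g. `TNAC` for the human branch site,
#'   `YYYYYY` for the polypyrimidine tract).
#' @param k k-mer length.
#' @param window sliding-window size in positions.
#' @param positions half-open range `c(start, end)` of window start
#'   positions relative to the anchor.
#' @return A data.frame of class `signal_curve` with columns `position`,
#'   `label`, `raw_fraction` (in `[0, 1]`), `normalized_fraction` (in
#'   `[0, 1/(window*k)]`), and attributes `pattern`, `k`, `window`.
#' @export
motif_fraction_curve <- function(seqs, pattern, k, window = 1L, positions) {
  seqs <- as_seq_records(seqs)
  k <- .check_k(k)
  rx <- iupac_regex(pattern)
  labels <- if (all(is.na(seqs$label))) rep("all", nrow(seqs)) else seqs$label
  out <- list()
  for (lab in unique(labels)) {
    m <- build_position_sample_matrix(seqs[labels == lab, , drop = FALSE],
                                      k = k, window = window,
                                      positions = positions)
    counts <- .as_counts(m)
    matches <- grepl(rx, colnames(counts))
    total <- rowSums(counts)
    hit <- rowSums(counts[, matches, drop = FALSE])
    raw <- ifelse(total > 0, hit / total, 0)
    out[[lab]] <- data.frame(
      position = as.integer(rownames(counts)),
      label = lab,
      raw_fraction = raw,
      normalized_fraction = raw / (window * k),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "pattern") <- pattern
  attr(res, "k") <- k
  attr(res, "window") <- as.integer(window)
  class(res) <- c("signal_curve", "data.frame")
  res
}
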