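#' Sequence records
#'
#' A light container for nucleotide sequences with optional per-sequence
#' class labels and alignment anchors. The anchor is the 0-based offset of
#' the alignment point within the sequence; positions handed to positional
#' featurizers are interpreted relative to it. For sequences aligned at a
#' 3' splice site the anchor sits just after the intron, so the terminal AG
#' occupies positions -2/-1.
#'
#' @param id character vector of unique sequence ids.
#' @param seq character vector of sequences over A/C/G/T/N (lowercase is
#'   uppercased on ingest).
#' @param label optional character vector of class labels.
#' @param anchor optional integer vector of 0-based anchor offsets, each in
#'   `[0, nchar(seq)]`. Defaults to 0 (positions counted from the sequence
#'   start).
#' @return A data.frame of class `seq_records` with columns `id`, `seq`,
#'   `label`, `anchor`.
#' @examples
#' seq_records(c("a", "b"), c("ACGTACGT", "TTTTACGT"), label = c("x", "y"))
#' @export
seq_records <- function(id, seq, label = NA_character_, anchor = NA_integer_) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  n <- length(id)
  if (length(seq) != n) stop("'id' and 'seq' lengths differ", call. = FALSE)
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate sequence ids: %s",
                 paste(unique(id[duplicated(id)]), collapse = ", ")),
         call. = FALSE)
  }
  label <- rep_len(as.character(label), n)
  anchor <- rep_len(as.integer(anchor), n)
  anchor[is.na(anchor)] <- 0L
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(sprintf("sequences contain characters outside ACGTN: %s",
                 paste(utils::head(id[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  out_of_range <- anchor < 0L | anchor > nchar(seq)
  if (any(out_of_range)) {
    stop(sprintf("anchors outside [0, length] for: %s",
                 paste(utils::head(id[out_of_range], 5), collapse = ", ")),
         call. = FALSE)
  }
  structure(data.frame(id = id, seq = seq, label = label, anchor = anchor,
                       stringsAsFactors = FALSE),
            class = c("seq_records", "data.frame"))
}

# Coerce character vectors / data.frames to seq_records.
as_seq_records <- function(x) {
  if (inherits(x, "seq_records")) return(x)
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("seq%d", seq_along(x))
    return(seq_records(ids, x))
  }
  if (is.data.frame(x) && all(c("id", "seq") %in% names(x))) {
    return(seq_records(x$id, x$seq,
                       label = if ("label" %in% names(x)) x$label else NA,
                       anchor = if ("anchor" %in% names(x)) x$anchor else NA))
  }
  stop("cannot interpret input as sequence records", call. = FALSE)
}

#' Count matrix
#'
#' The samples-by-features matrix of non-negative integer k-mer counts that
#' every model-fitting step consumes. `mode` records which featurization
#' produced it: `bulk` (plain k-mers), `positional` (`KMER_at_POS`
#' features), `frame` (plain k-mers, one sample per reading frame) or
#' `position_window` (plain k-mers, one sample per window start position).
#'
#' @param counts numeric matrix of non-negative integers with sample ids as
#'   rownames and feature ids as colnames.
#' @param mode one of `"bulk"`, `"positional"`, `"frame"`,
#'   `"position_window"`.
#' @param k k-mer length the features were built with.
#' @param labels optional per-sample class labels (length `nrow(counts)`).
#' @param meta optional list of extra provenance (window, positions, ...).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, mode, k, labels = NULL, meta = list()) {
  mode <- match.arg(mode, c("bulk", "positional", "frame", "position_window"))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' needs sample ids as rownames and feature ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("sample and feature ids must be unique", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(counts))
      stop("'labels' must have one entry per sample", call. = FALSE)
  }
  structure(list(counts = counts, mode = mode, k = .check_k(k),
                 labels = labels, meta = meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count matrix [%s]: %d samples x %d features (k = %d)\n",
              x$mode, nrow(x$counts), ncol(x$counts), x$k))
  if (!is.null(x$labels))
    cat(sprintf("  labels: %s\n",
                paste(names(table(x$labels)), table(x$labels),
                      sep = ":", collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
as.matrix.count_matrix <- function(x, ...) x$counts

# Accept a count_matrix or a bare matrix.
.as_counts <- function(m) {
  if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
}

sample_ids <- function(m) rownames(.as_counts(m))
feature_ids <- function(m) colnames(.as_counts(m))
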