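#' Find small open reading frames
#'
#' Scans the three sense-strand frames of a transcript (UTR or lncRNA) for
#' ATG..stop pairs with at least `min_codons` codons strictly between the
#' start and the stop codon. For each in-frame stop, the default policy
#' pairs it with the most upstream ATG after the previous in-frame stop
#' (the longest-ORF rule); `all_starts = TRUE` instead emits every
#' qualifying ATG for that stop.
#'
#' @param seq a nucleotide string over ACGTN.
#' @param min_codons minimum number of internal codons (default 25).
#' @param all_starts emit every qualifying ATG per stop rather than only
#'   the longest ORF.
#' @param parent_id id recorded for the parent sequence.
#' @return A data.frame of class `smorf_table`, sorted by `start`, with
#'   columns `parent_id`, `start`, `end` (0-based half-open on the parent),
#'   `frame_on_parent` (1-3), `n_internal_codons`, `seq`. Empty when
#'   nothing qualifies.
#' @examples
#' orf <- paste0("ATG", strrep("GCT", 25), "TAA")
#' find_smorfs(paste0("CCCC", orf, "GGGG"))
#' @export
find_smorfs <- function(seq, min_codons = 25L, all_starts = FALSE,
                        parent_id = "seq") {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence must be over ACGTN",
                                   call. = FALSE)
  min_codons <- as.integer(min_codons)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  res <- list()
  if (n >= 6) {
    codon_at <- function(i) substr(seq, i + 1L, i + 3L)  # 0-based offset
    for (f in 0:2) {
      offs <- seq.int(f, n - 3L, by = 3L)
      if (length(offs) < 2) next
      codons <- vapply(offs, codon_at, character(1))
      is_start <- codons == "ATG"
      is_stop <- codons %in% stops
      prev_stop <- 0L  # codon index (1-based) of previous in-frame stop
      for (s in which(is_stop)) {
        cand <- which(is_start[seq_len(s - 1L)])
        cand <- cand[cand > prev_stop]
        if (length(cand) > 0) {
          starts <- if (all_starts) cand else cand[1]
          for (a in starts) {
            internal <- s - a - 1L
            if (internal >= min_codons) {
              res[[length(res) + 1L]] <- data.frame(
                parent_id = parent_id,
                start = offs[a], end = offs[s] + 3L,
                frame_on_parent = f + 1L,
                n_internal_codons = internal,
                seq = substr(seq, offs[a] + 1L, offs[s] + 3L),
                stringsAsFactors = FALSE)
            }
          }
        }
        prev_stop <- s
      }
    }
  }
  out <- if (length(res) == 0) {
    data.frame(parent_id = character(0), start = integer(0),
               end = integer(0), frame_on_parent = integer(0),
               n_internal_codons = integer(0), seq = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, res)
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("smorf_table", "data.frame")
  out
}

#' Score a smORF's coding potential
#'
#' Treats the smORF sequence as reading frame 1 and runs the CDS-trained
#' frame classifier over its three frames; the smORF is flagged coding-like
#' exactly when all three frames are predicted correctly (the same
#' criterion used for annotated CDS).
#'
#' @param smorf one row of a [find_smorfs()] table (or any object with a
#'   `seq` field), or a plain character sequence.
#' @param model a fitted [seqlda()] model trained on frame-tagged CDS
#'   counts.
#' @param scores the matching [topic_label_scores()] matrix over
#'   `frame1/frame2/frame3`.
#' @param k k-mer length of the model.
#' @return A one-row `frame_prediction` data.frame with an extra
#'   `coding_like` column.
#' @export
score_smorf_coding <- function(smorf, model, scores, k) {
  s <- if (is.character(smorf)) smorf else smorf$seq
  id <- if (is.character(smorf)) "smorf" else as.character(smorf$parent_id)
  pred <- classify_reading_frames(seq_records(make.unique(id), s),
                                  model, scores, k)
  pred$coding_like <- pred$all_correct
  pred
}

#' Write smORFs as BED6-compatible TSV
#'
#' @param smorfs a [find_smorfs()] table with a `coding_like` column
#'   (absent values are written as NA).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_smorf_bed <- function(smorfs, path) {
  bed <- data.frame(
    chrom = smorfs$parent_id,
    start = smorfs$start,
    end = smorfs$end,
    name = sprintf("smORF_%s_%d_%d", smorfs$parent_id, smorfs$start,
                   smorfs$end),
    score = smorfs$n_internal_codons,
    strand = "+",
    coding_like = if ("coding_like" %in% names(smorfs)) smorfs$coding_like
                  else NA,
    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
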