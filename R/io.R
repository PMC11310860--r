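#' Read sequences from FASTA
#'
#' Reads a FASTA file into [seq_records()]. Sequences are uppercased on
#' ingest (with a notice when anything was lowercase); duplicate ids are
#' rejected. Only the first whitespace-delimited token of each header is
#' kept as the id.
#'
#' @param path FASTA file path.
#' @param labels optional path to a sidecar TSV (see [read_labels()]) whose
#'   anchors/labels are attached to the records.
#' @return A [seq_records()] data.frame.
#' @export
read_fasta <- function(path, labels = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (length(x) == 0) {
    recs <- seq_records(character(0), character(0))
  } else {
    raw <- readLines(path, warn = FALSE)
    if (any(grepl("[acgtn]", raw[!startsWith(raw, ">")])))
      message("lowercase bases uppercased on ingest")
    recs <- seq_records(ids, toupper(as.character(x)))
  }
  if (!is.null(labels)) {
    lab <- read_labels(labels, ids = recs$id)
    recs$anchor <- lab$anchor[match(recs$id, lab$id)]
    recs$label <- lab$label[match(recs$id, lab$id)]
  }
  recs
}

#' Write sequences to FASTA
#'
#' Writes records with line width normalized to 60 columns; a write/read
#' round trip reproduces ids and sequence content exactly.
#'
#' @param records a [seq_records()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- as_seq_records(records)
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Read a sidecar label/anchor TSV
#'
#' Reads a TSV with header columns `id` (required) and optional `anchor`
#' and `label`. When `ids` is supplied, every id must be resolvable and
#' missing ones are reported exhaustively. An absent anchor column
#' defaults anchors to the sequence start (0).
#'
#' @param path TSV path.
#' @param ids optional character vector of ids that must all be present.
#' @return A data.frame with columns `id`, `anchor`, `label`.
#' @export
read_labels <- function(path, ids = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"id" %in% names(tab)) stop("label TSV needs an 'id' column",
                                  call. = FALSE)
  if (anyDuplicated(tab$id))
    stop("duplicate ids in label TSV", call. = FALSE)
  out <- data.frame(
    id = tab$id,
    anchor = if ("anchor" %in% names(tab)) as.integer(tab$anchor) else 0L,
    label = if ("label" %in% names(tab)) tab$label else NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(ids)) {
    missing <- setdiff(ids, out$id)
    if (length(missing) > 0)
      stop(sprintf("ids missing from label TSV: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Write sequence records and sidecar TSV
#'
#' Writes FASTA plus the `id`/`anchor`/`label` sidecar consumed by
#' [read_fasta()].
#'
#' @param records a [seq_records()] data.frame.
#' @param fasta_path,tsv_path output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_records <- function(records, fasta_path, tsv_path) {
  records <- as_seq_records(records)
  write_fasta(records, fasta_path)
  utils::write.table(records[, c("id", "anchor", "label")], tsv_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Write a count matrix as TSV plus JSON sidecar
#'
#' The TSV has sample ids in the first column (`sample_id`) and feature ids
#' as the header; the `<path>.json` sidecar records mode, k, labels and any
#' extra provenance, so the matrix round-trips through [read_count_matrix()].
#'
#' @param m a [count_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(sample_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(mode = m$mode, k = m$k, labels = m$labels, meta = m$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path TSV path (with its `.json` sidecar alongside).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::fromJSON(side_path, simplifyVector = TRUE)
    count_matrix(counts, mode = side$mode, k = side$k,
                 labels = if (is.null(side$labels) ||
                              length(side$labels) == 0) NULL
                          else side$labels,
                 meta = as.list(side$meta))
  } else {
    count_matrix(counts, mode = "bulk", k = .guess_k(colnames(counts)))
  }
}

#' Write a run manifest
#'
#' Records the command, configuration, seed and input file hashes of a CLI
#' run as JSON, sufficient to reproduce its outputs bit-for-bit.
#'
#' @param path output JSON path.
#' @param command command/subcommand string.
#' @param config a list of parameters.
#' @param inputs character vector of input file paths (md5-hashed).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config = list(),
                               inputs = character(0)) {
  hashes <- if (length(inputs) > 0) {
    stats::setNames(as.character(tools::md5sum(inputs)), inputs)
  } else NULL
  payload <- list(command = command, config = config,
                  inputs = as.list(hashes))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}
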