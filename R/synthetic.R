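#' Simulate a topic-structured count corpus
#'
#' Draws a corpus from the LDA generative process with known parameters:
#' topic-feature rows from a symmetric Dirichlet, per-sample memberships
#' from a symmetric Dirichlet, and token counts from the resulting
#' per-sample multinomial. The true `phi` and `theta` are returned so
#' fitted models can be checked for parameter recovery.
#'
#' @param K number of topics.
#' @param V vocabulary size (`>= 2`).
#' @param n_samples number of samples.
#' @param tokens_per_sample tokens drawn per sample.
#' @param phi_concentration symmetric Dirichlet concentration of the
#'   topic-feature rows. The default 0.1 gives sparse, well-separated
#'   topics.
#' @param theta_concentration symmetric Dirichlet concentration of the
#'   memberships. The default 0.5 mixes topics within samples without
#'   collapsing to single-topic samples.
#' @param seed integer seed; identical seeds give identical corpora.
#' @return A list with `counts` (a bulk-mode [count_matrix()] with features
#'   `f0001..`), `phi` (K x V), `theta` (n_samples x K).
#' @export
simulate_topic_corpus <- function(K, V, n_samples, tokens_per_sample,
                                  phi_concentration = 0.1,
                                  theta_concentration = 0.5, seed = 1L) {
  K <- as.integer(K); V <- as.integer(V)
  if (is.na(K) || K < 1) stop("'K' must be >= 1", call. = FALSE)
  if (is.na(V) || V < 2) stop("'V' must be >= 2", call. = FALSE)
  if (phi_concentration <= 0 || theta_concentration <= 0)
    stop("concentrations must be positive", call. = FALSE)
  set.seed(seed)
  phi <- .rdirichlet(K, rep(phi_concentration, V))
  theta <- .rdirichlet(n_samples, rep(theta_concentration, K))
  probs <- theta %*% phi
  counts <- t(vapply(seq_len(n_samples), function(i) {
    as.integer(stats::rmultinom(1, tokens_per_sample, probs[i, ]))
  }, integer(V)))
  fids <- sprintf("f%04d", seq_len(V))
  dimnames(counts) <- list(sprintf("sample%d", seq_len(n_samples)), fids)
  dimnames(phi) <- list(paste0("topic", seq_len(K)), fids)
  dimnames(theta) <- list(rownames(counts), paste0("topic", seq_len(K)))
  list(counts = count_matrix(counts, mode = "bulk", k = 1L,
                             meta = list(simulated = TRUE, V = V)),
       phi = phi, theta = theta)
}

#' Simulate intron-like sequences anchored at a 3' splice site
#'
#' Generates labelled, anchored sequences emulating the upstream region of
#' an intron: i.i.d. background bases, an optional branch-site motif
#' (IUPAC codes instantiated uniformly at random per sequence) planted at a
#' fixed offset with given probability and jitter, an optional
#' pyrimidine-rich tract, and a terminal AG so the 3' splice-site
#' convention holds (the anchor sits at the end of the sequence and the AG
#' occupies positions -2/-1).
#'
#' @param n sequences per class.
#' @param length sequence length in nt.
#' @param classes a named list of class specifications, each a list with
#'   any of: `branch_offset` (motif start position relative to the anchor,
#'   e.g. -30), `branch_motif` (IUPAC string, default `"TNAC"`),
#'   `branch_prob` (planting probability, default 1), `jitter` (max
#'   uniform offset shift, default 0), `pyrimidine_region` (position pair
#'   `c(start, end)`, half-open), `pyrimidine_strength` (probability that
#'   a base in the region is C or T, default 0.85), `background` (length-4
#'   A/C/G/T weights, default uniform).
#' @param seed integer seed.
#' @return A [seq_records()] data.frame with labels and anchors set.
#' @export
simulate_anchored_introns <- function(n, length, classes, seed = 1L) {
  if (is.null(names(classes)) || any(names(classes) == ""))
    stop("'classes' must be a named list", call. = FALSE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  all_ids <- character(0); all_seqs <- character(0); all_labels <- character(0)
  for (cls in names(classes)) {
    sp <- classes[[cls]]
    bg <- sp$background %||% rep(0.25, 4)
    if (length(bg) != 4 || any(bg < 0) || sum(bg) == 0)
      stop("'background' must be 4 non-negative weights", call. = FALSE)
    bg <- bg / sum(bg)
    motif <- sp$branch_motif %||% "TNAC"
    branch_prob <- sp$branch_prob %||% 1
    jitter <- sp$jitter %||% 0L
    pyr_strength <- sp$pyrimidine_strength %||% 0.85
    # validate region overlap
    if (!is.null(sp$branch_offset)) {
      mlen <- nchar(motif)
      if (sp$branch_offset - jitter < -length ||
          sp$branch_offset + jitter + mlen > 0)
        stop("branch motif does not fit inside the sequence", call. = FALSE)
      if (!is.null(sp$pyrimidine_region)) {
        pr <- .check_region(sp$pyrimidine_region)
        if (sp$branch_offset + mlen + jitter > pr[1] &&
            sp$branch_offset - jitter < pr[2])
          stop("branch motif and pyrimidine region overlap", call. = FALSE)
      }
    }
    expand <- strsplit(.iupac, "", fixed = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(bases, length, replace = TRUE, prob = bg)
      if (!is.null(sp$pyrimidine_region)) {
        pr <- .check_region(sp$pyrimidine_region)
        pos <- seq.int(pr[1], pr[2] - 1L)
        pos <- pos[pos >= -length & pos <= -1L]
        idx <- length + pos + 1L
        pyr <- stats::runif(base::length(idx)) < pyr_strength
        s[idx[pyr]] <- sample(c("C", "T"), sum(pyr), replace = TRUE)
      }
      if (!is.null(sp$branch_offset) && stats::runif(1) < branch_prob) {
        off <- sp$branch_offset
        if (jitter > 0) off <- off + sample(seq.int(-jitter, jitter), 1)
        chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
        inst <- vapply(chars, function(ch) {
          choices <- expand[[ch]]
          choices[sample.int(base::length(choices), 1)]
        }, character(1))
        idx <- length + off + seq_along(inst)
        s[idx] <- inst
      }
      # terminal AG: 3'SS convention at -2/-1
      s[length - 1L] <- "A"
      s[length] <- "G"
      paste0(s, collapse = "")
    }, character(1))
    all_ids <- c(all_ids, sprintf("%s_%d", cls, seq_len(n)))
    all_seqs <- c(all_seqs, seqs)
    all_labels <- c(all_labels, rep(cls, n))
  }
  seq_records(all_ids, all_seqs, label = all_labels, anchor = length)
}

#' Simulate codon-usage-biased coding sequences
#'
#' Generates CDS in annotated frame 1: an ATG start, internal codons drawn
#' i.i.d. from a codon weight table with zero mass on stop codons, and a
#' final stop codon. The default table is Zipf-skewed over the 61 sense
#' codons (weight `1/rank` in lexicographic order), giving the strong codon
#' bias that makes reading-frame signal detectable at desk scale, analogous
#' to natural species codon bias.
#'
#' @param n number of sequences.
#' @param n_codons_range integer pair: min and max total codons (including
#'   the start and stop codons), minimum 30.
#' @param codon_weights optional named 64-entry non-negative weight table;
#'   must place zero weight on TAA/TAG/TGA.
#' @param seed integer seed.
#' @param prefix id prefix.
#' @return A [seq_records()] data.frame (label `cds`, anchor 0).
#' @export
simulate_cds <- function(n, n_codons_range = c(100L, 300L),
                         codon_weights = NULL, seed = 1L, prefix = "cds") {
  rng <- as.integer(n_codons_range)
  if (length(rng) != 2 || any(is.na(rng)) || rng[1] < 30 || rng[2] < rng[1])
    stop("'n_codons_range' must be c(min, max) with min >= 30", call. = FALSE)
  stops <- c("TAA", "TAG", "TGA")
  if (is.null(codon_weights)) codon_weights <- default_codon_weights()
  if (length(codon_weights) != 64 || is.null(names(codon_weights)))
    stop("'codon_weights' must be a named 64-entry vector", call. = FALSE)
  codon_weights <- codon_weights[sort(names(codon_weights))]
  if (!identical(names(codon_weights), kmer_vocabulary(3)$kmers))
    stop("'codon_weights' names must be the 64 codons", call. = FALSE)
  if (any(codon_weights < 0) || any(codon_weights[stops] > 0))
    stop("codon weights must be non-negative with zero mass on stop codons",
         call. = FALSE)
  sense <- codon_weights[setdiff(names(codon_weights), stops)]
  if (sum(sense) == 0) stop("degenerate codon weights", call. = FALSE)
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    total <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1) - 1L
    internal <- sample(names(sense), total - 2L, replace = TRUE,
                       prob = sense)
    paste0("ATG", paste0(internal, collapse = ""),
           sample(stops, 1))
  }, character(1))
  seq_records(sprintf("%s_%d", prefix, seq_len(n)), seqs, label = "cds",
              anchor = 0L)
}

#' Default synthetic codon weight table
#'
#' Zipf-like weights (`1/rank`) over the 61 sense codons in lexicographic
#' order, zero on the three stop codons.
#'
#' @return A named length-64 numeric vector.
#' @export
default_codon_weights <- function() {
  codons <- kmer_vocabulary(3)$kmers
  stops <- c("TAA", "TAG", "TGA")
  w <- numeric(64)
  names(w) <- codons
  sense <- setdiff(codons, stops)
  w[sense] <- 1 / seq_along(sense)
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
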