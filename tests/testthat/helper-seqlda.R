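# Independent brute-force oracles and small generators shared across tests.
# These deliberately avoid the package's vectorized code paths: counting via
# substr/regex, likelihoods via explicit loops, ORFs via pair enumeration.

rand_dna <- function(n, prob = rep(0.25, 4), alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

bf_count_kmers <- function(seq, k) {
  v <- kmer_vocabulary(k)$kmers
  out <- stats::setNames(integer(length(v)), v)
  n <- nchar(seq)
  if (n >= k) {
    for (i in seq_len(n - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (!grepl("[^ACGT]", w)) out[w] <- out[w] + 1L
    }
  }
  out
}

bf_sequence_ll <- function(seq, phi_row, k) {
  total <- 0
  for (i in seq_len(nchar(seq) - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (!grepl("[^ACGT]", w)) total <- total + log(phi_row[[w]])
  }
  total
}

# Explicit double-loop driving-feature oracle: min-over-others Bernoulli KL,
# first-wins argmax assignment, rank by descending score with lexicographic
# tie-break, truncate to top_n.
bf_driving <- function(phi, top_n) {
  K <- nrow(phi)
  V <- ncol(phi)
  kl <- function(p, q) {
    eps <- 1e-12
    p <- min(max(p, eps), 1 - eps)
    q <- min(max(q, eps), 1 - eps)
    p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))
  }
  d <- matrix(NA_real_, K, V)
  for (t in seq_len(K)) {
    for (w in seq_len(V)) {
      best <- Inf
      for (o in seq_len(K)) {
        if (o != t) best <- min(best, kl(phi[t, w], phi[o, w]))
      }
      d[t, w] <- best
    }
  }
  assigned <- integer(V)
  for (w in seq_len(V)) {
    best_t <- 1L
    for (t in seq_len(K)) if (d[t, w] > d[best_t, w]) best_t <- t
    assigned[w] <- best_t
  }
  rows <- list()
  for (t in seq_len(K)) {
    w <- which(assigned == t)
    feats <- colnames(phi)[w]
    score <- d[t, w]
    ord <- order(-score, feats)
    keep <- utils::head(ord, top_n)
    if (length(keep) > 0) {
      rows[[t]] <- data.frame(topic = t, rank = seq_along(keep),
                              feature = feats[keep],
                              distinctiveness = score[keep],
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Enumerate every in-frame (ATG, stop) pair with no stop strictly between,
# then apply the most-upstream-ATG-per-stop rule and the min-codon filter.
bf_find_orfs <- function(seq, min_codons = 25L, all_starts = FALSE) {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  hits <- list()
  for (a in 0:(n - 3)) {
    if (substr(seq, a + 1, a + 3) != "ATG") next
    if (a + 3 > n - 3) next
    for (s in seq(a + 3, n - 3, by = 3)) {
      codon <- substr(seq, s + 1, s + 3)
      if (codon %in% stops) {
        internal <- (s - a) / 3 - 1
        hits[[length(hits) + 1]] <- c(start = a, end = s + 3,
                                      internal = internal)
        break  # first in-frame stop terminates the ORF
      }
    }
  }
  if (length(hits) == 0) return(data.frame(start = integer(0),
                                           end = integer(0),
                                           internal = integer(0)))
  df <- as.data.frame(do.call(rbind, hits))
  if (!all_starts) {
    # most upstream ATG per stop
    df <- do.call(rbind, lapply(split(df, df$end),
                                function(g) g[which.min(g$start), ]))
  }
  df <- df[df$internal >= min_codons, , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

tv_dist <- function(a, b) 0.5 * sum(abs(a - b))

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
    }
  }
  out
}

# Best topic permutation by mean total-variation distance to the truth;
# returns list(perm, mean_tv, max_tv).
match_topics <- function(phi_hat, phi_true) {
  K <- nrow(phi_true)
  best <- NULL
  for (p in all_perms(K)) {
    tvs <- vapply(seq_len(K),
                  function(t) tv_dist(phi_hat[p[[t]], ], phi_true[t, ]),
                  numeric(1))
    if (is.null(best) || mean(tvs) < best$mean_tv) {
      best <- list(perm = unlist(p), mean_tv = mean(tvs), max_tv = max(tvs))
    }
  }
  best
}

rand_phi <- function(K, V, conc = 0.3, feature_ids = NULL) {
  x <- matrix(stats::rgamma(K * V, shape = conc), K, V)
  x <- x / rowSums(x)
  if (is.null(feature_ids)) feature_ids <- sprintf("f%04d", seq_len(V))
  dimnames(x) <- list(paste0("topic", seq_len(K)), feature_ids)
  x
}

# A seqlda-shaped model around a given phi, for scoring tests.
fake_model <- function(phi, alpha = 1 / nrow(phi)) {
  structure(list(n_topics = nrow(phi), phi = phi, theta = NULL,
                 alpha = alpha, eta = alpha,
                 feature_ids = colnames(phi), labels = NULL,
                 fit_info = list(seed = 0L)),
            class = "seqlda")
}
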