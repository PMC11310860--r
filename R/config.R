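#' Analysis configuration
#'
#' Bundles the tunable parameters shared across the pipeline: the k-mer
#' length, the sliding-window size used when positions are treated as
#' samples, the pack size (number of same-label sequences pooled into one
#' sample before model fitting), the number of topics, the random seed, and
#' the two Dirichlet priors of the topic model.
#'
#' Priors default to the symmetric `1/n_topics` used by mainstream batch
#' variational LDA implementations.
#'
#' @param k k-mer length (nt), integer in `[1, 8]`.
#' @param n_topics number of topics K, `>= 1`.
#' @param window sliding-window size in positions, `>= 1`.
#' @param pack sequences pooled per sample, `>= 1`.
#' @param seed integer random seed.
#' @param alpha document-topic Dirichlet prior, `> 0`.
#' @param eta topic-feature Dirichlet prior, `> 0`.
#' @return An object of class `analysis_config` (a named list).
#' @examples
#' analysis_config(k = 6, n_topics = 6, window = 5, pack = 250)
#' @export
analysis_config <- function(k, n_topics, window = 1L, pack = 1L,
                            seed = 1L, alpha = 1 / n_topics,
                            eta = 1 / n_topics) {
  k <- .check_k(k)
  .check_count <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
        x != as.integer(x) || x < min) {
      stop(sprintf("'%s' must be a single integer >= %d", name, min),
           call. = FALSE)
    }
    as.integer(x)
  }
  n_topics <- .check_count(n_topics, "n_topics")
  window <- .check_count(window, "window")
  pack <- .check_count(pack, "pack")
  seed <- .check_count(seed, "seed", min = -.Machine$integer.max)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  if (!is.numeric(eta) || length(eta) != 1 || is.na(eta) || eta <= 0)
    stop("'eta' must be a single positive number", call. = FALSE)
  structure(list(k = k, window = window, pack = pack, n_topics = n_topics,
                 seed = seed, alpha = as.numeric(alpha),
                 eta = as.numeric(eta)),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis configuration:\n")
  cat(sprintf("  k = %d, window = %d, pack = %d, n_topics = %d\n",
              x$k, x$window, x$pack, x$n_topics))
  cat(sprintf("  seed = %d, alpha = %g, eta = %g\n", x$seed, x$alpha, x$eta))
  invisible(x)
}
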