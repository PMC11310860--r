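#' Fit a latent Dirichlet allocation topic model to k-mer counts
#'
#' Fits the LDA mixture model to a samples-by-features count matrix by batch
#' variational Bayes with fixed-point updates. Each sample (a sequence, a
#' pack of sequences, or a position in an alignment) is modelled as a
#' mixture of `n_topics` topics; each topic is a probability distribution
#' over the k-mer features. The variational evidence lower bound (ELBO) is
#' recorded at every iteration and fitting stops when its relative change
#' drops below `tol` or after `max_iter` iterations.
#'
#' Fitting is deterministic given `seed` (which controls only the random
#' initialization of the topic-feature variational parameters). Topics are
#' exchangeable under the model, so before return they are re-ordered by
#' descending token-weighted corpus usage to give stable identities across
#' runs.
#'
#' @param counts a [count_matrix()] or plain non-negative integer matrix
#'   (samples x features, with dimnames).
#' @param n_topics number of topics K. May also come from `config`.
#' @param config optional [analysis_config()]; supplies `n_topics`, `alpha`,
#'   `eta` and `seed` unless overridden, and is snapshotted into the fitted
#'   object for provenance.
#' @param alpha document-topic Dirichlet prior; default `1/n_topics`.
#' @param eta topic-feature Dirichlet prior; default `1/n_topics`.
#' @param max_iter maximum variational EM iterations.
#' @param tol relative ELBO change at which to declare convergence.
#' @param seed integer seed for the topic initialization.
#' @param n_init number of random restarts; the fit with the best final
#'   evidence bound is kept. Batch variational LDA occasionally lands in a
#'   degenerate optimum with an unused topic; restarts make the returned
#'   fit robust to the initialization seed while remaining fully
#'   deterministic (candidate seeds are derived from `seed`).
#' @param verbose print the bound every iteration.
#' @return An object of class `seqlda`: a list with `phi` (K x V
#'   topic-feature probabilities, rows summing to 1), `theta` (training
#'   sample memberships, rows summing to 1), `alpha`, `eta`, `feature_ids`,
#'   `labels` (carried from `counts` if present) and `fit_info` (iterations,
#'   ELBO trace, seed, topic usage, config snapshot).
#' @seealso [predict.seqlda()] to transform new samples,
#'   [driving_features()] to interpret topics, [topic_label_scores()] to
#'   build a classifier on top of the memberships.
#' @examples
#' sim <- simulate_topic_corpus(K = 2, V = 16, n_samples = 40,
#'                              tokens_per_sample = 200, seed = 1)
#' fit <- seqlda(sim$counts, n_topics = 2, seed = 1)
#' fit
#' rowSums(coef(fit))  # each topic is a distribution over features
#' @export
seqlda <- function(counts, n_topics = NULL, config = NULL, alpha = NULL,
                   eta = NULL, max_iter = 100L, tol = 1e-3, seed = NULL,
                   n_init = 3L, verbose = FALSE) {
  if (!is.null(config) && !inherits(config, "analysis_config"))
    stop("'config' must be an analysis_config", call. = FALSE)
  K <- if (!is.null(n_topics)) as.integer(n_topics)
       else if (!is.null(config)) config$n_topics
       else stop("'n_topics' is required (directly or via config)",
                 call. = FALSE)
  if (is.na(K) || K < 1) stop("'n_topics' must be >= 1", call. = FALSE)
  if (is.null(alpha)) alpha <- if (!is.null(config)) config$alpha else 1 / K
  if (is.null(eta)) eta <- if (!is.null(config)) config$eta else 1 / K
  if (is.null(seed)) seed <- if (!is.null(config)) config$seed else 1L
  if (alpha <= 0 || eta <= 0) stop("priors must be positive", call. = FALSE)

  X <- .as_counts(counts)
  if (is.null(rownames(X))) rownames(X) <- sprintf("sample%d", seq_len(nrow(X)))
  if (is.null(colnames(X))) stop("'counts' needs feature ids as colnames",
                                 call. = FALSE)
  if (any(X < 0)) stop("counts must be non-negative", call. = FALSE)
  doc_tokens <- rowSums(X)
  if (all(doc_tokens == 0)) stop("count matrix is all zero", call. = FALSE)
  D <- nrow(X)
  V <- ncol(X)
  if (K > D) warning(sprintf("n_topics (%d) exceeds the number of samples (%d)",
                             K, D), call. = FALSE)

  sp <- .sparse_triplets(X)
  n_init <- max(1L, as.integer(n_init))
  runs <- lapply(seq_len(n_init), function(r) {
    cand_seed <- as.integer(seed) + (r - 1L) * 1009L
    run <- .lda_fit_once(sp, K, V, alpha, eta, doc_tokens, max_iter, tol,
                         cand_seed, verbose)
    run$seed <- cand_seed
    run
  })
  finals <- vapply(runs, function(r) r$elbo[length(r$elbo)], numeric(1))
  best <- runs[[which.max(finals)]]
  lambda <- best$lambda
  elbo <- best$elbo
  converged <- best$converged

  # memberships under the final topics
  Elogbeta <- digamma(lambda) - digamma(rowSums(lambda))
  es <- .lda_estep(sp, exp(Elogbeta), alpha, doc_tokens, K)
  theta <- es$gamma / rowSums(es$gamma)
  phi <- lambda / rowSums(lambda)

  usage <- as.numeric(crossprod(theta, doc_tokens))
  ord <- order(usage, decreasing = TRUE)
  phi <- phi[ord, , drop = FALSE]
  theta <- theta[, ord, drop = FALSE]
  usage <- usage[ord]
  dimnames(phi) <- list(paste0("topic", seq_len(K)), colnames(X))
  dimnames(theta) <- list(rownames(X), paste0("topic", seq_len(K)))

  labels <- if (inherits(counts, "count_matrix")) counts$labels else NULL
  structure(list(
    n_topics = K, phi = phi, theta = theta,
    alpha = alpha, eta = eta,
    feature_ids = colnames(X),
    labels = labels,
    fit_info = list(iterations = length(elbo), elbo = elbo,
                    final_elbo = elbo[length(elbo)], converged = converged,
                    seed = as.integer(seed), n_init = n_init,
                    init_seed = best$seed, max_iter = as.integer(max_iter),
                    tol = tol, n_samples = D, n_features = V,
                    topic_usage = usage,
                    config = if (!is.null(config)) unclass(config) else NULL)
  ), class = "seqlda")
}

# One full variational EM run from one random initialization.
.lda_fit_once <- function(sp, K, V, alpha, eta, doc_tokens, max_iter, tol,
                          seed, verbose = FALSE) {
  set.seed(seed)
  lambda <- matrix(stats::rgamma(K * V, shape = 100, rate = 100), K, V)
  elbo <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Elogbeta <- digamma(lambda) - digamma(rowSums(lambda))
    expElogbeta <- exp(Elogbeta)
    es <- .lda_estep(sp, expElogbeta, alpha, doc_tokens, K)
    lambda <- eta + expElogbeta *
      as.matrix(Matrix::crossprod(es$expElogtheta, es$ratio_mat))
    b <- .lda_bound(sp, es, Elogbeta, lambda, alpha, eta, K, V)
    elbo <- c(elbo, b)
    if (verbose) message(sprintf("  init %d iter %3d  elbo %.4f",
                                 seed, iter, b))
    if (iter > 1 && abs(b - elbo[iter - 1]) < tol * abs(elbo[iter - 1])) {
      converged <- TRUE
      break
    }
  }
  list(lambda = lambda, elbo = elbo, converged = converged)
}

# Sparse triplet view of a count matrix plus a template dgCMatrix whose @x
# slot can be overwritten in place each iteration.
.sparse_triplets <- function(X) {
  Xs <- methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  ii <- Xs@i + 1L
  jj <- Xs@j + 1L
  xx <- Xs@x
  keep <- xx != 0
  ii <- ii[keep]; jj <- jj[keep]; xx <- xx[keep]
  tmpl <- Matrix::sparseMatrix(i = ii, j = jj, x = seq_along(xx),
                               dims = dim(X))
  perm <- tmpl@x  # triplet order -> dgC order
  list(ii = ii, jj = jj, xx = xx, tmpl = tmpl, perm = perm, dims = dim(X))
}

# One batch E-step: iterate per-document gamma to convergence under fixed
# topics. Returns gamma, exp(E[log theta]) and the sparse ratio matrix
# n_dw / s_dw needed by both the M-step and the bound.
.lda_estep <- function(sp, expElogbeta, alpha, doc_tokens, K,
                       max_doc_iter = 100L, doc_tol = 1e-4) {
  D <- sp$dims[1]
  gamma <- matrix(alpha + doc_tokens / K, D, K)
  expElogtheta <- exp(digamma(gamma) - digamma(rowSums(gamma)))
  eb_nz <- expElogbeta[, sp$jj, drop = FALSE]  # K x nnz
  s_at_nz <- function(expElogtheta) {
    s <- numeric(length(sp$xx))
    for (t in seq_len(K)) s <- s + expElogtheta[sp$ii, t] * eb_nz[t, ]
    s
  }
  ratio_mat <- sp$tmpl
  for (it in seq_len(max_doc_iter)) {
    s <- s_at_nz(expElogtheta)
    ratio_mat@x[sp$perm] <- sp$xx / s
    gamma_new <- alpha + expElogtheta *
      as.matrix(ratio_mat %*% t(expElogbeta))
    delta <- mean(abs(gamma_new - gamma))
    gamma <- gamma_new
    expElogtheta <- exp(digamma(gamma) - digamma(rowSums(gamma)))
    if (delta < doc_tol * mean(gamma)) break
  }
  s <- s_at_nz(expElogtheta)
  ratio_mat@x[sp$perm] <- sp$xx / s
  list(gamma = gamma, expElogtheta = expElogtheta, ratio_mat = ratio_mat,
       s = s)
}

# Variational evidence lower bound (up to count-only constants).
.lda_bound <- function(sp, es, Elogbeta, lambda, alpha, eta, K, V) {
  word_score <- sum(sp$xx * log(es$s))
  gamma <- es$gamma
  Elogtheta <- digamma(gamma) - digamma(rowSums(gamma))
  theta_score <- sum((alpha - gamma) * Elogtheta) + sum(lgamma(gamma)) -
    sum(lgamma(rowSums(gamma))) +
    nrow(gamma) * (lgamma(K * alpha) - K * lgamma(alpha))
  beta_score <- sum((eta - lambda) * Elogbeta) + sum(lgamma(lambda)) -
    sum(lgamma(rowSums(lambda))) +
    K * (lgamma(V * eta) - V * lgamma(eta))
  word_score + theta_score + beta_score
}

#' Transform samples into topic memberships
#'
#' Computes posterior topic proportions for new samples under the fixed
#' topics of a fitted model (variational inference on the document side
#' only). Features absent from `newdata` are treated as zero counts;
#' features unknown to the model are an error, since silently dropping
#' columns of a positional vocabulary is the likeliest way to misalign two
#' featurizations.
#'
#' @param object a fitted [seqlda()] model.
#' @param newdata a [count_matrix()] or plain matrix whose columns are a
#'   subset of the model's features.
#' @param type `"membership"` returns the theta matrix; `"label"`
#'   additionally requires `scores` and returns predicted labels via
#'   [predict_label()].
#' @param scores a [topic_label_scores()] matrix, required for
#'   `type = "label"`.
#' @param ... unused.
#' @return A samples x topics membership matrix with rows summing to 1, or
#'   a character vector of labels. An all-zero sample gets the uniform
#'   membership `1/K` (the prior mean).
#' @export
predict.seqlda <- function(object, newdata, type = c("membership", "label"),
                           scores = NULL, ...) {
  type <- match.arg(type)
  X <- .as_counts(newdata)
  if (is.null(colnames(X))) stop("'newdata' needs feature ids as colnames",
                                 call. = FALSE)
  unknown <- setdiff(colnames(X), object$feature_ids)
  if (length(unknown) > 0) {
    stop(sprintf("features unknown to the model: %s%s",
                 paste(utils::head(unknown, 5), collapse = ", "),
                 if (length(unknown) > 5) ", ..." else ""), call. = FALSE)
  }
  full <- matrix(0, nrow(X), length(object$feature_ids),
                 dimnames = list(rownames(X), object$feature_ids))
  full[, colnames(X)] <- X
  theta <- .lda_transform(full, object$phi, object$alpha)
  dimnames(theta) <- list(rownames(X), rownames(object$phi))
  if (type == "membership") return(theta)
  if (is.null(scores)) stop("type = 'label' needs 'scores'", call. = FALSE)
  apply(theta, 1, predict_label, scores = scores)
}

# Document-side variational inference with topics fixed at log(phi).
.lda_transform <- function(X, phi, alpha, max_doc_iter = 100L,
                           doc_tol = 1e-6) {
  K <- nrow(phi)
  doc_tokens <- rowSums(X)
  sp <- .sparse_triplets(X)
  expElogbeta <- pmax(phi, 1e-300)
  if (length(sp$xx) == 0) {
    gamma <- matrix(alpha, nrow(X), K)
    return(gamma / rowSums(gamma))
  }
  es <- .lda_estep(sp, expElogbeta, alpha, doc_tokens, K,
                   max_doc_iter = max_doc_iter, doc_tol = doc_tol)
  es$gamma / rowSums(es$gamma)
}

#' @export
print.seqlda <- function(x, ...) {
  cat(sprintf("seqlda topic model: %d topics, %d features, %d samples\n",
              x$n_topics, length(x$feature_ids),
              if (is.null(x$theta)) 0L else nrow(x$theta)))
  cat(sprintf("  priors: alpha = %g, eta = %g; seed = %s\n",
              x$alpha, x$eta, x$fit_info$seed))
  cat(sprintf("  %d iterations, %sconverged, final ELBO %.2f\n",
              x$fit_info$iterations,
              if (isTRUE(x$fit_info$converged)) "" else "not ",
              x$fit_info$final_elbo))
  invisible(x)
}

#' @export
summary.seqlda <- function(object, top_n = 5L, ...) {
  usage <- object$fit_info$topic_usage
  top <- t(apply(object$phi, 1, function(p) {
    names(sort(p, decreasing = TRUE))[seq_len(top_n)]
  }))
  out <- list(n_topics = object$n_topics, usage = usage / sum(usage),
              top_features = top, fit_info = object$fit_info)
  class(out) <- "summary.seqlda"
  out
}

#' @export
print.summary.seqlda <- function(x, ...) {
  cat(sprintf("seqlda topic model with %d topics\n", x$n_topics))
  for (t in seq_len(x$n_topics)) {
    cat(sprintf("  topic%-2d usage %5.1f%%  top features: %s\n", t,
                100 * x$usage[t], paste(x$top_features[t, ], collapse = " ")))
  }
  invisible(x)
}

#' @export
coef.seqlda <- function(object, ...) object$phi

#' @export
logLik.seqlda <- function(object, ...) {
  structure(object$fit_info$final_elbo,
            df = object$n_topics * (length(object$feature_ids) - 1),
            class = "logLik")
}

#' Structure plot of topic memberships
#'
#' Draws the standard stacked-bar "structure plot": one bar per sample,
#' partitioned by topic membership, optionally grouped by label and sorted
#' within group by one topic's proportion.
#'
#' @param x a fitted [seqlda()] model (its training memberships are drawn)
#'   or pass `theta` explicitly.
#' @param theta optional membership matrix to plot instead of `x$theta`.
#' @param group optional per-sample labels used to order the bars.
#' @param sort_by optional topic id to sort by within groups.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.seqlda <- function(x, theta = NULL, group = NULL, sort_by = NULL, ...) {
  if (is.null(theta)) theta <- x$theta
  if (is.null(theta)) stop("no memberships to plot", call. = FALSE)
  if (is.null(group)) group <- if (!is.null(x$labels) &&
                                   length(x$labels) == nrow(theta))
    x$labels else rep("all", nrow(theta))
  dat <- export_structure_data(theta, group = group, sort_by = sort_by)
  wide <- stats::reshape(dat, idvar = c("sample", "group"),
                         timevar = "topic", direction = "wide")
  ord <- order(match(wide$group, unique(dat$group)))
  m <- t(as.matrix(wide[ord, -(1:2)]))
  graphics::barplot(m, col = grDevices::hcl.colors(nrow(m), "Dark 3"),
                    border = NA, space = 0, names.arg = rep("", ncol(m)),
                    ylab = "topic membership", ...)
  invisible(m)
}

#' Simulate count data from a fitted topic model
#'
#' Draws new samples from the model's generative process: memberships from
#' `Dirichlet(alpha)`, then token counts from the membership-mixed topic
#' distributions.
#'
#' @param object a fitted [seqlda()] model.
#' @param nsim number of samples.
#' @param seed integer seed.
#' @param tokens_per_sample tokens drawn per sample.
#' @param ... unused.
#' @return A [count_matrix()] in bulk mode.
#' @export
simulate.seqlda <- function(object, nsim = 1, seed = 1L,
                            tokens_per_sample = 1000L, ...) {
  set.seed(seed)
  K <- object$n_topics
  theta <- .rdirichlet(nsim, rep(object$alpha, K))
  probs <- theta %*% object$phi
  counts <- t(vapply(seq_len(nsim), function(i) {
    as.integer(stats::rmultinom(1, tokens_per_sample, probs[i, ]))
  }, integer(ncol(probs))))
  dimnames(counts) <- list(sprintf("sim%d", seq_len(nsim)), object$feature_ids)
  count_matrix(counts, mode = "bulk", k = .guess_k(object$feature_ids))
}

.guess_k <- function(feature_ids) {
  w <- nchar(feature_ids[1])
  if (grepl("_at_", feature_ids[1]))
    w <- nchar(sub("_at_.*$", "", feature_ids[1]))
  max(1L, min(8L, w))
}

#' Wrap a topic-feature matrix as a topic model
#'
#' Builds a `seqlda` object around an externally specified topic-feature
#' probability matrix (e.g. a hand-constructed or published set of topics)
#' so it can be used with [predict.seqlda()], [driving_features()] and the
#' scoring functions.
#'
#' @param phi K x V matrix with rows summing to 1 and feature ids as
#'   colnames.
#' @param alpha,eta Dirichlet priors recorded on the object; `alpha` is
#'   used when transforming samples.
#' @return A `seqlda` object without training memberships.
#' @export
as_seqlda <- function(phi, alpha = 1 / nrow(phi), eta = 1 / nrow(phi)) {
  phi <- as.matrix(phi)
  if (is.null(colnames(phi))) stop("'phi' needs feature ids as colnames",
                                   call. = FALSE)
  if (any(phi <= 0)) stop("'phi' entries must be strictly positive",
                          call. = FALSE)
  if (any(abs(rowSums(phi) - 1) > 1e-8))
    stop("'phi' rows must sum to 1", call. = FALSE)
  if (is.null(rownames(phi)))
    rownames(phi) <- paste0("topic", seq_len(nrow(phi)))
  structure(list(n_topics = nrow(phi), phi = phi, theta = NULL,
                 alpha = alpha, eta = eta, feature_ids = colnames(phi),
                 labels = NULL,
                 fit_info = list(iterations = 0L, elbo = numeric(0),
                                 final_elbo = NA_real_, converged = NA,
                                 seed = NA_integer_,
                                 n_samples = 0L, n_features = ncol(phi))),
            class = "seqlda")
}

#' Serialize a topic model to JSON
#'
#' Writes a single JSON document holding the priors, feature ids, the full
#' topic-feature matrix, and the fit metadata (including any config
#' snapshot). Numbers are written at full precision so that
#' write/read/write round-trips are bit-identical.
#'
#' @param model a fitted [seqlda()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_seqlda <- function(model, path) {
  stopifnot(inherits(model, "seqlda"))
  payload <- list(
    format = "seqlda-model",
    version = 1L,
    n_topics = model$n_topics,
    alpha = model$alpha,
    eta = model$eta,
    feature_ids = model$feature_ids,
    phi = lapply(seq_len(model$n_topics),
                 function(t) unname(model$phi[t, ])),
    fit_info = model$fit_info[setdiff(names(model$fit_info), "elbo")]
  )
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read a serialized topic model
#'
#' @param path path to a JSON file written by [write_seqlda()].
#' @return A `seqlda` object (without training memberships).
#' @export
read_seqlda <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "seqlda-model")
    stop("not a seqlda model file", call. = FALSE)
  phi <- if (is.list(p$phi)) do.call(rbind, p$phi) else as.matrix(p$phi)
  dimnames(phi) <- list(paste0("topic", seq_len(p$n_topics)), p$feature_ids)
  structure(list(n_topics = as.integer(p$n_topics), phi = phi, theta = NULL,
                 alpha = p$alpha, eta = p$eta, feature_ids = p$feature_ids,
                 labels = NULL, fit_info = p$fit_info),
            class = "seqlda")
}

# Dirichlet sampler via normalized gammas.
.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  zero <- rowSums(x) == 0
  x[zero, ] <- 1  # numerically degenerate draw -> uniform
  x / rowSums(x)
}
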