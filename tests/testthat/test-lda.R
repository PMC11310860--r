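make_corpus <- function(seed = 1, K = 3, V = 64, n = 80, tokens = 400) {
  simulate_topic_corpus(K = K, V = V, n_samples = n,
                        tokens_per_sample = tokens, seed = seed)
}

test_that("single-topic fit degenerates to prior-smoothed corpus frequencies", {
  sim <- make_corpus(seed = 2, K = 1, V = 32, n = 20, tokens = 100)
  fit <- expect_warning(seqlda(sim$counts, n_topics = 1, eta = 0.5, seed = 1),
                        NA)
  cs <- colSums(as.matrix(sim$counts))
  expected <- (0.5 + cs) / sum(0.5 + cs)
  expect_equal(unname(fit$phi[1, ]), unname(expected), tolerance = 1e-12)
  expect_equal(unname(fit$theta[, 1]), rep(1, 20))
})

test_that("phi and theta are row-stochastic and strictly positive after fit", {
  sim <- make_corpus(seed = 3)
  fit <- seqlda(sim$counts, n_topics = 3, seed = 3)
  expect_equal(unname(rowSums(fit$phi)), rep(1, 3), tolerance = 1e-8)
  expect_equal(unname(rowSums(fit$theta)), rep(1, 80), tolerance = 1e-8)
  expect_true(all(fit$phi > 0))
  expect_true(all(fit$theta >= 0))
  # topics ordered by descending corpus usage
  expect_true(all(diff(fit$fit_info$topic_usage) <= 1e-8))
})

test_that("the evidence bound is non-decreasing across iterations", {
  sim <- make_corpus(seed = 4)
  fit <- seqlda(sim$counts, n_topics = 3, seed = 4, tol = 1e-6,
                max_iter = 50)
  elbo <- fit$fit_info$elbo
  expect_gt(length(elbo), 2)
  expect_true(all(diff(elbo) >= -1e-5 * abs(elbo[-length(elbo)])))
})

test_that("two disjoint feature blocks are split cleanly into two topics", {
  set.seed(5)
  V <- 20
  blockA <- 1:10
  blockB <- 11:20
  counts <- matrix(0L, 40, V,
                   dimnames = list(sprintf("s%d", 1:40),
                                   sprintf("f%02d", 1:V)))
  for (i in 1:20) counts[i, blockA] <- rpois(10, 20)
  for (i in 21:40) counts[i, blockB] <- rpois(10, 20)
  fit <- seqlda(count_matrix(counts, "bulk", 1), n_topics = 2, seed = 5)
  massA <- rowSums(fit$phi[, blockA])
  # each topic concentrates on one block
  expect_true(max(massA) >= 0.95 && min(massA) <= 0.05)
  topicA <- which.max(massA)
  expect_true(all(fit$theta[1:20, topicA] >= 0.95))
  expect_true(all(fit$theta[21:40, topicA] <= 0.05))
})

test_that("known parameters are recovered from simulated corpora", {
  tvs <- vapply(1:10, function(s) {
    sim <- make_corpus(seed = s, V = 256, n = 120, tokens = 2000)
    fit <- seqlda(sim$counts, n_topics = 3, seed = s)
    match_topics(fit$phi, sim$phi)$mean_tv
  }, numeric(1))
  expect_lte(mean(tvs), 0.1)

  # error shrinks as samples carry more tokens
  err_at <- function(tokens) {
    mean(vapply(1:3, function(s) {
      sim <- make_corpus(seed = 100 + s, tokens = tokens)
      fit <- seqlda(sim$counts, n_topics = 3, seed = s)
      match_topics(fit$phi, sim$phi)$mean_tv
    }, numeric(1)))
  }
  expect_lte(err_at(2000), err_at(100))
})

test_that("fitting is bitwise reproducible given the seed", {
  sim <- make_corpus(seed = 6)
  f1 <- seqlda(sim$counts, n_topics = 3, seed = 42)
  f2 <- seqlda(sim$counts, n_topics = 3, seed = 42)
  expect_identical(f1$phi, f2$phi)
  expect_identical(f1$theta, f2$theta)
  f3 <- seqlda(sim$counts, n_topics = 3, seed = 43)
  expect_false(identical(f1$phi, f3$phi))
})

test_that("transform reproduces training memberships and handles edge samples", {
  sim <- make_corpus(seed = 7, tokens = 800)
  fit <- seqlda(sim$counts, n_topics = 3, seed = 7)
  th <- predict(fit, sim$counts)
  expect_equal(unname(rowSums(th)), rep(1, nrow(th)), tolerance = 1e-8)
  expect_lt(mean(abs(th - fit$theta)), 0.02)

  # all-zero sample: uniform prior-mean membership
  z <- matrix(0L, 1, length(fit$feature_ids),
              dimnames = list("z", fit$feature_ids))
  expect_equal(unname(predict(fit, z)[1, ]), rep(1 / 3, 3))

  # a sample made only of one topic's most exclusive features
  excl <- order(fit$phi[1, ] / (fit$phi[2, ] + fit$phi[3, ]),
                decreasing = TRUE)[1:5]
  x <- matrix(0L, 1, length(fit$feature_ids),
              dimnames = list("x", fit$feature_ids))
  x[1, excl] <- 200L
  expect_gte(predict(fit, x)[1, 1], 0.95)

  # missing features are allowed, unknown features are not
  sub <- as.matrix(sim$counts)[1:3, 1:10]
  expect_silent(predict(fit, sub))
  bad <- matrix(1L, 1, 2, dimnames = list("b", c("f0001", "nope")))
  expect_error(predict(fit, bad), "unknown")
})

test_that("serialization round-trips bit-exactly", {
  sim <- make_corpus(seed = 8, n = 30, tokens = 200)
  fit <- seqlda(sim$counts, n_topics = 2, seed = 8)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_seqlda(fit, p1)
  back <- read_seqlda(p1)
  expect_identical(back$phi, fit$phi)
  expect_identical(back$alpha, fit$alpha)
  expect_identical(back$feature_ids, fit$feature_ids)
  write_seqlda(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a deserialized model transforms identically to the in-memory one
  expect_equal(predict(back, sim$counts), predict(fit, sim$counts))
})

test_that("degenerate inputs are rejected or warned about", {
  counts <- matrix(0L, 4, 4, dimnames = list(letters[1:4], LETTERS[1:4]))
  expect_error(seqlda(count_matrix(counts, "bulk", 1), n_topics = 2), "zero")
  counts[1, 1] <- 5L
  expect_warning(seqlda(count_matrix(counts, "bulk", 1), n_topics = 6,
                        seed = 1), "exceeds")
})

test_that("configuration objects validate and feed the fit", {
  cfg <- analysis_config(k = 6, n_topics = 3, window = 5, pack = 250,
                         seed = 99)
  expect_equal(cfg$alpha, 1 / 3)
  expect_error(analysis_config(k = 9, n_topics = 2), "k")
  expect_error(analysis_config(k = 4, n_topics = 2, alpha = 0), "alpha")
  expect_error(analysis_config(k = 4, n_topics = 0), "n_topics")

  sim <- make_corpus(seed = 12, n = 30, tokens = 200)
  cfg <- analysis_config(k = 1, n_topics = 3, seed = 12)
  fit <- seqlda(sim$counts, config = cfg)
  expect_identical(fit$n_topics, 3L)
  expect_identical(fit$fit_info$seed, 12L)
  expect_equal(fit$fit_info$config$n_topics, 3L)
  # identical to the explicit-argument call
  fit2 <- seqlda(sim$counts, n_topics = 3, seed = 12)
  expect_identical(fit$phi, fit2$phi)
})

test_that("model methods: simulate draws from the fit, plot renders", {
  sim <- make_corpus(seed = 13, n = 30, tokens = 200, V = 16)
  fit <- seqlda(sim$counts, n_topics = 2, seed = 13)
  drawn <- simulate(fit, nsim = 5, seed = 13, tokens_per_sample = 50)
  expect_identical(dim(drawn), c(5L, 16L))
  expect_true(all(rowSums(as.matrix(drawn)) == 50))
  expect_identical(colnames(as.matrix(drawn)), fit$feature_ids)

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, group = rep(c("a", "b"), 15), sort_by = 1))

  expect_s3_class(summary(fit), "summary.seqlda")
  expect_identical(coef(fit), fit$phi)
  expect_equal(as.numeric(logLik(fit)), fit$fit_info$final_elbo)

  # as_seqlda wraps an external phi and validates it
  expect_error(as_seqlda(matrix(c(0.6, 0.3), 1, 2,
                                dimnames = list(NULL, c("A", "C")))),
               "sum to 1")
  wrapped <- as_seqlda(fit$phi)
  expect_identical(predict(wrapped, sim$counts),
                   predict(fit, sim$counts))
})

test_that("variational fit agrees with an independent LDA implementation", {
  # Cross-check against scikit-learn's batch variational LDA on a small,
  # well-separated corpus; both should land on the same topics.
  skip_if(Sys.which("python") == "", "python not on PATH")
  sim <- make_corpus(seed = 9, K = 2, V = 32, n = 60, tokens = 500)
  fit <- seqlda(sim$counts, n_topics = 2, seed = 9, tol = 1e-6)
  csv <- withr::local_tempfile(fileext = ".csv")
  out <- withr::local_tempfile(fileext = ".json")
  utils::write.table(as.matrix(sim$counts), csv, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  script <- sprintf(paste0(
    "import json, numpy as np\n",
    "from sklearn.decomposition import LatentDirichletAllocation\n",
    "X = np.loadtxt(%s, delimiter=',')\n",
    "m = LatentDirichletAllocation(n_components=2, doc_topic_prior=0.5,\n",
    "    topic_word_prior=0.5, learning_method='batch', max_iter=200,\n",
    "    mean_change_tol=1e-6, random_state=0).fit(X)\n",
    "phi = m.components_ / m.components_.sum(axis=1, keepdims=True)\n",
    "json.dump(phi.tolist(), open(%s, 'w'))\n"),
    deparse(csv), deparse(out))
  res <- system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  skip_if(!file.exists(out), paste("sklearn unavailable:",
                                   paste(res, collapse = " ")))
  phi_py <- do.call(rbind, lapply(jsonlite::fromJSON(out,
                                                     simplifyVector = FALSE),
                                  unlist))
  m <- min(tv_dist(fit$phi[1, ] - 0, phi_py[1, ]) +
             tv_dist(fit$phi[2, ], phi_py[2, ]),
           tv_dist(fit$phi[1, ], phi_py[2, ]) +
             tv_dist(fit$phi[2, ], phi_py[1, ])) / 2
  expect_lt(m, 0.05)
})
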