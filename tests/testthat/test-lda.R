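toy_corpus <- function() {
  make_corpus(list(c("aaa", "aaa", "bbb"), c("bbb", "ccc"), c("aaa", "ccc", "ccc")))
}

state_consistent <- function(st) {
  total <- length(st$z)
  all(rowSums(st$n_dk) == tabulate(st$doc_of + 1L, nbins = st$M),
      rowSums(st$n_kw) == st$n_k,
      sum(st$n_k) == total,
      identical(as.integer(table(factor(st$z, levels = 0:(st$K - 1L)))),
                as.integer(st$n_k)))
}

test_that("config validation rejects degenerate parameters", {
  expect_error(lda_config(K = 0), "K")
  expect_error(lda_config(alpha = 0), "alpha")
  expect_error(lda_config(eta = -1), "eta")
  expect_error(lda_config(iterations = 5, burn_in = 5), "burn_in")
})

test_that("random initialization is seeded, consistent and uniform", {
  corp <- toy_corpus()
  st <- lda_init(corp, lda_config(K = 1, seed = 1, iterations = 10, burn_in = 0))
  expect_true(all(st$z == 0L))
  expect_identical(st$n_k, 8L)

  cfg <- lda_config(K = 3, seed = 5, iterations = 10, burn_in = 0)
  st1 <- lda_init(corp, cfg)
  st2 <- lda_init(corp, cfg)
  expect_identical(st1$z, st2$z)
  expect_true(state_consistent(st1))

  # 1000 tokens over K = 10: each topic count within 5 sigma of 100
  big <- make_corpus(list(rep(paste0("t", 1:20), 50)))
  stb <- lda_init(big, lda_config(K = 10, seed = 2, iterations = 10, burn_in = 0))
  sigma <- sqrt(1000 * 0.1 * 0.9)
  expect_true(all(abs(stb$n_k - 100) <= 5 * sigma))
})

test_that("a sweep conserves counts and is the identity for K = 1", {
  corp <- toy_corpus()
  cfg1 <- lda_config(K = 1, seed = 3, iterations = 10, burn_in = 0)
  st <- lda_init(corp, cfg1)
  st2 <- gibbs_sweep(st, cfg1)
  expect_identical(st2$z, st$z)

  cfg <- lda_config(K = 4, seed = 3, iterations = 10, burn_in = 0)
  st <- lda_init(corp, cfg)
  for (i in 1:5) {
    st <- gibbs_sweep(st, cfg)
    expect_true(state_consistent(st))
  }
})

test_that("K = 1 training gives closed-form phi and theta", {
  corp <- toy_corpus()
  m <- train_lda(corp, lda_config(K = 1, iterations = 5, burn_in = 0, seed = 1))
  expect_equal(unname(m$theta[, 1]), rep(1, 3))
  # phi row = smoothed corpus frequencies (counts: aaa 3, bbb 2, ccc 3)
  eta <- m$config$eta
  expect_equal(as.numeric(m$phi),
               (c(3, 2, 3) + eta) / (8 + 3 * eta), tolerance = 1e-12)
})

test_that("training is bit-reproducible under a fixed seed", {
  corp <- toy_corpus()
  cfg <- lda_config(K = 3, iterations = 20, burn_in = 0, seed = 99)
  m1 <- train_lda(corp, cfg)
  m2 <- train_lda(corp, cfg)
  expect_identical(m1$phi, m2$phi)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$state$z, m2$state$z)
})

test_that("phi and theta rows are strictly positive probability vectors", {
  set.seed(13)
  for (i in 1:5) {
    docs <- replicate(20, paste0("w", sample.int(30, sample(5:40, 1), TRUE)),
                      simplify = FALSE)
    corp <- make_corpus(docs)
    m <- train_lda(corp, lda_config(K = 4, iterations = 15, burn_in = 0, seed = i))
    expect_equal(rowSums(m$phi), rep(1, 4), tolerance = 1e-9)
    expect_equal(rowSums(m$theta), rep(1, corp$M), tolerance = 1e-9)
    expect_true(all(m$phi > 0))
    expect_true(all(m$theta > 0))
  }
})

test_that("post-burn-in averaging produces valid, distinct estimates", {
  corp <- toy_corpus()
  cfg <- lda_config(K = 2, iterations = 30, burn_in = 10, seed = 4,
                    average_after_burnin = TRUE)
  m <- train_lda(corp, cfg)
  expect_equal(rowSums(m$phi), rep(1, 2), tolerance = 1e-9)
  expect_equal(rowSums(m$theta), rep(1, 3), tolerance = 1e-9)
})

test_that("fold-in inference recovers the dominant topic of a pure document", {
  synth <- separated_corpus(K = 4, words_per_topic = 10, M = 120,
                            doc_len_mean = 40, purity = 1, seed = 21)
  toks <- preprocess_corpus(synth$docs)
  corp <- make_corpus(toks, doc_ids = as.integer(names(toks)))
  model <- train_lda(corp, lda_config(K = 4, iterations = 100, burn_in = 50, seed = 22))

  expect_error(infer_theta(model, doc2bow(corp$dictionary, "zzz")),
               "no in-vocabulary tokens")

  # K = 1 fold-in is the trivial simplex
  m1 <- train_lda(corp, lda_config(K = 1, iterations = 5, burn_in = 0, seed = 1))
  th1 <- infer_theta(m1, corp$docs[[1]], seed = 1)
  expect_equal(th1, 1)

  # a document drawn purely from one latent topic folds back onto the
  # estimated topic that matches it
  phi_aligned <- align_phi(model$phi, corp$dictionary, ncol(synth$truth$phi_true))
  mt <- match_topics(phi_aligned, synth$truth$phi_true)
  ok <- 0
  for (i in 1:20) {
    gold <- synth$truth$gold[i]
    th <- infer_theta(model, corp$docs[[i]], fold_iterations = 100, seed = 100 + i)
    est_topic <- which.max(th)
    ok <- ok + (mt$perm[est_topic] - 1L == gold)
  }
  expect_gte(ok, 18)
})

test_that("top_keywords sorts by probability with id tie-break", {
  corp <- make_corpus(list(c("aaa", "aaa", "aaa", "aaa", "aaa", "bbb", "bbb",
                             "bbb", "ccc", "ccc")))
  m <- train_lda(corp, lda_config(K = 1, iterations = 2, burn_in = 0, seed = 1))
  kw <- top_keywords(m, 0, n = 2)
  expect_identical(kw$token, c("aaa", "bbb"))
  kw_all <- top_keywords(m, 0, n = 3)
  expect_equal(sum(kw_all$probability), 1, tolerance = 1e-12)
  expect_error(top_keywords(m, 5), "out of range")

  # exact tie: lower token id wins
  m$phi <- matrix(c(0.4, 0.4, 0.2), nrow = 1)
  expect_identical(top_keywords(m, 0, n = 1)$token, "aaa")
})

test_that("model directories round-trip exactly", {
  corp <- toy_corpus()
  m <- train_lda(corp, lda_config(K = 2, iterations = 10, burn_in = 0, seed = 7))
  d <- withr::local_tempdir()
  save_lda_model(m, d)
  back <- load_lda_model(d)
  expect_equal(back$phi, m$phi, tolerance = 0)
  expect_equal(back$theta, m$theta, tolerance = 0)
  expect_identical(back$doc_ids, m$doc_ids)
  expect_identical(back$dictionary, m$dictionary)
  expect_identical(back$config$K, m$config$K)
})
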