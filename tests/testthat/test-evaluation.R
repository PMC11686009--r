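test_that("coherence matches hand cases", {
  doc_sets <- list(c(1L, 2L), c(1L, 2L), c(3L, 4L), c(2L, 3L), integer(0))
  # identical non-empty doc sets -> 1
  expect_equal(jaccard_coherence(c(0L, 1L), doc_sets), 1)
  # disjoint -> 0
  expect_equal(jaccard_coherence(c(0L, 2L), doc_sets), 0)
  # {1,2} vs {2,3} -> 1/3
  expect_equal(jaccard_coherence(c(0L, 3L), doc_sets), 1 / 3, tolerance = 1e-15)
  # empty union pair contributes 0
  expect_equal(jaccard_coherence(c(4L, 4L), doc_sets), 0)
  expect_error(jaccard_coherence(0L, doc_sets), "at least 2")
})

test_that("coherence equals the brute-force pair loop and is permutation-invariant", {
  set.seed(31)
  for (i in 1:50) {
    inst <- random_coherence_instance()
    cv <- jaccard_coherence(inst$word_ids, inst$doc_sets)
    expect_equal(cv, brute_coherence(inst$word_ids, inst$doc_sets),
                 tolerance = 1e-12)
    expect_equal(jaccard_coherence(sample(inst$word_ids), inst$doc_sets), cv,
                 tolerance = 1e-12)
    expect_gte(cv, 0); expect_lte(cv, 1)
  }
})

test_that("adding a document that contains none of the words leaves Cv unchanged", {
  set.seed(32)
  inst <- random_coherence_instance(V = 10, n_docs = 20, n_words = 5)
  cv <- jaccard_coherence(inst$word_ids, inst$doc_sets)
  # document 999 joins the doc sets of words outside the scored list only
  other <- setdiff(0:9, inst$word_ids)[1] + 1L
  inst$doc_sets[[other]] <- c(inst$doc_sets[[other]], 999L)
  expect_equal(jaccard_coherence(inst$word_ids, inst$doc_sets), cv)
})

test_that("perplexity closed forms hold", {
  # uniform model over V words: perplexity = V
  corp <- make_corpus(list(c("aaa", "bbb"), c("ccc", "aaa", "bbb")))
  V <- corp$dictionary$V
  model <- structure(list(
    phi = matrix(1 / V, nrow = 2, ncol = V),
    theta = NULL, config = lda_config(K = 2, seed = 1),
    dictionary = corp$dictionary, doc_ids = corp$doc_ids), class = "lda_model")
  res <- perplexity(model, corp, fold_iterations = 5, seed = 1)
  expect_equal(res$perplexity, V, tolerance = 1e-12)
  expect_equal(res$perplexity, exp(res$log_perplexity))
  expect_equal(res$per_word_log_likelihood, -res$log_perplexity)

  # probability-1 model: every token has likelihood 1 -> perplexity 1, log 0
  corp1 <- make_corpus(list(c("aaa", "aaa"), "aaa"))
  model1 <- structure(list(
    phi = matrix(1, nrow = 1, ncol = 1),
    theta = NULL, config = lda_config(K = 1, seed = 1),
    dictionary = corp1$dictionary, doc_ids = corp1$doc_ids), class = "lda_model")
  res1 <- perplexity(model1, corp1, fold_iterations = 5, seed = 1)
  expect_equal(res1$perplexity, 1, tolerance = 1e-12)
  expect_equal(res1$log_perplexity, 0, tolerance = 1e-12)
})

test_that("perplexity matches hand arithmetic on a 3-token document", {
  # phi: 2 topics x 3 words; theta = (0.6, 0.4); doc = (w0, w1, w1)
  phi <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.1, 0.8))
  theta <- c(0.6, 0.4)
  docs <- list(structure(list(doc_id = 1L, ids = c(0L, 1L),
                              counts = c(1L, 2L), N = 3L),
                         class = "bow_document"))
  p0 <- 0.6 * 0.5 + 0.4 * 0.1   # P(w0) = 0.34
  p1 <- 0.6 * 0.3 + 0.4 * 0.1   # P(w1) = 0.22
  expected <- exp(-(log(p0) + 2 * log(p1)) / 3)
  res <- perplexity_from_theta(phi, theta, docs)
  expect_equal(res$perplexity, expected, tolerance = 1e-12)
  expect_equal(res$n_tokens, 3L)
})

test_that("empty test documents are excluded, all-empty errors", {
  corp <- make_corpus(list(c("aaa", "bbb"), "aaa"))
  m <- train_lda(corp, lda_config(K = 2, iterations = 10, burn_in = 0, seed = 1))
  test_docs <- list(doc2bow(corp$dictionary, c("aaa", "zzz")),
                    doc2bow(corp$dictionary, "qqq"))
  tc <- structure(list(docs = test_docs, doc_ids = 1:2, M = 2L,
                       dictionary = corp$dictionary), class = "bow_corpus")
  expect_warning(res <- perplexity(m, tc, fold_iterations = 5, seed = 2),
                 "excluding 1")
  expect_equal(res$n_docs, 1L)
  all_oov <- structure(list(docs = test_docs[2], doc_ids = 2L, M = 1L,
                            dictionary = corp$dictionary), class = "bow_corpus")
  expect_error(perplexity(m, all_oov, seed = 1), "empty")
})

test_that("coherence scan is deterministic and favors the true topic count", {
  synth <- separated_corpus(K = 5, words_per_topic = 10, M = 150,
                            doc_len_mean = 30, purity = 0.95, seed = 41)
  toks <- preprocess_corpus(synth$docs)
  corp <- make_corpus(toks, doc_ids = as.integer(names(toks)))
  cfg <- lda_config(iterations = 60, burn_in = 30, seed = 42)
  s1 <- coherence_scan(corp, K_values = c(2L, 5L), config = cfg, top_n = 8)
  s2 <- coherence_scan(corp, K_values = c(2L, 5L), config = cfg, top_n = 8)
  expect_identical(s1, s2)
  expect_gte(s1$mean_by_K[["5"]], s1$mean_by_K[["2"]])
  expect_true(all(s1$per_topic$cv >= 0 & s1$per_topic$cv <= 1))
})

test_that("accuracy matches hand counts and validates lengths", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(accuracy(c("a", "a", "b", "c"), c("a", "b", "b", "c")), 0.75)
  expect_error(accuracy("a", c("a", "b")), "equal length")
})

test_that("f1 matches hand-computed confusion counts across averaging modes", {
  expect_equal(f1_score(c("a", "b"), c("a", "b"), "weighted"), 1)
  expect_equal(f1_score(c("a", "b"), c("a", "b"), "macro"), 1)
  expect_equal(f1_score(c("a", "b"), c("a", "b"), "micro"), 1)
  # gold a,a,b,b vs pred a,b,b,b: F1(a)=2/3, F1(b)=4/5 -> weighted 11/15
  g <- c("a", "a", "b", "b"); p <- c("a", "b", "b", "b")
  expect_equal(f1_score(g, p, "weighted"), 11 / 15, tolerance = 1e-15)
  expect_equal(f1_score(g, p, "macro"), (2 / 3 + 4 / 5) / 2, tolerance = 1e-15)
  expect_equal(f1_score(c("x", "x"), c("x", "x")), 1)
})

test_that("micro-F1 equals accuracy for single-label multi-class data", {
  set.seed(51)
  for (i in 1:20) {
    g <- sample(letters[1:4], 50, replace = TRUE)
    p <- sample(letters[1:4], 50, replace = TRUE)
    expect_equal(f1_score(g, p, "micro"), accuracy(g, p), tolerance = 1e-12)
  }
})
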