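#' LDA training configuration
#'
#' Symmetric scalar Dirichlet priors are used throughout: `alpha` on the
#' per-document topic proportions and `eta` on the per-topic word
#' distributions, both defaulting to 0.1 (a common weakly-sparse choice
#' for short health documents). `K = 10` topics with 10 keywords per
#' topic are the defaults used for the Afaan Oromo health corpus.
#'
#' @param K Number of topics (>= 1, default 10).
#' @param alpha Dirichlet prior on document-topic proportions (> 0).
#' @param eta Dirichlet prior on topic-word distributions (> 0).
#' @param iterations Number of Gibbs sweeps (default 200).
#' @param burn_in Sweeps discarded before estimation when
#'   `average_after_burnin = TRUE`; must be < `iterations`.
#' @param seed Integer RNG seed, or `NULL` to use the session RNG state.
#' @param top_n_words Keywords reported per topic (default 10).
#' @param average_after_burnin If `TRUE`, `phi`/`theta` are averaged over
#'   the post-burn-in sweeps instead of taken from the final state
#'   (default `FALSE`: the final-state point estimate is the simplest
#'   deterministic choice).
#' @param n_starts Number of independent Gibbs chains run from different
#'   random initializations (default 3); the chain with the highest
#'   training log-likelihood is kept. Collapsed Gibbs on strongly
#'   clustered corpora can lock into a topic-merge local mode that long
#'   chains do not escape; seeded restarts are the standard remedy.
#' @return An object of class `lda_config`.
#' @export
lda_config <- function(K = 10L, alpha = 0.1, eta = 0.1, iterations = 200L,
                       burn_in = 100L, seed = NULL, top_n_words = 10L,
                       average_after_burnin = FALSE, n_starts = 3L) {
  K <- as.integer(K); iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in); top_n_words <- as.integer(top_n_words)
  if (K < 1L) stop_("K must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0) stop_("alpha must be > 0")
  if (!is.numeric(eta) || eta <= 0) stop_("eta must be > 0")
  if (iterations < 1L) stop_("iterations must be >= 1")
  if (burn_in >= iterations) stop_("burn_in must be < iterations")
  if (top_n_words < 1L) stop_("top_n_words must be >= 1")
  n_starts <- as.integer(n_starts)
  if (n_starts < 1L) stop_("n_starts must be >= 1")
  cfg <- list(K = K, alpha = alpha, eta = eta, iterations = iterations,
              burn_in = burn_in, seed = seed, top_n_words = top_n_words,
              average_after_burnin = isTRUE(average_after_burnin),
              n_starts = n_starts)
  class(cfg) <- "lda_config"
  cfg
}

# Flatten a bow corpus into one entry per token occurrence (0-based doc
# and word indices). Token order within a document is ascending token id
# with count-many consecutive positions; document order is corpus order.
# This fixed ordering is what makes seeded runs bit-reproducible.
expand_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "bow_corpus"))
  doc_of <- integer(0); word_of <- integer(0)
  docs <- corpus$docs
  per_doc_word <- lapply(docs, function(b) rep(b$ids, b$counts))
  len <- lengths(per_doc_word)
  list(
    doc_of = rep(seq_along(docs) - 1L, len),
    word_of = unlist(per_doc_word, use.names = FALSE) %||% integer(0),
    N_d = as.integer(len)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Random topic initialization for the Gibbs sampler
#'
#' Assigns every token occurrence a topic drawn uniformly from
#' `0:(K-1)` and builds the count matrices consistent with the
#' assignment.
#'
#' @param corpus A `bow_corpus` with at least one token.
#' @param config An [lda_config()]; `config$seed` (if non-NULL) seeds the
#'   draw.
#' @return An object of class `lda_state`: list with `z` (0-based topic
#'   per token occurrence), `n_dk` (M x K), `n_kw` (K x V), `n_k`
#'   (length K), plus the flattened corpus (`doc_of`, `word_of`) and
#'   dimensions.
#' @export
lda_init <- function(corpus, config) {
  stopifnot(inherits(corpus, "bow_corpus"), inherits(config, "lda_config"))
  ex <- expand_corpus(corpus)
  if (length(ex$word_of) == 0L) stop_("corpus has no tokens")
  restore <- push_seed(config$seed)
  on.exit(restore())
  z <- cpp_random_topics(length(ex$word_of), config$K)
  counts <- cpp_count_state(z, ex$doc_of, ex$word_of,
                            corpus$M, corpus$dictionary$V, config$K)
  st <- list(z = z, n_dk = counts$n_dk, n_kw = counts$n_kw, n_k = counts$n_k,
             doc_of = ex$doc_of, word_of = ex$word_of, N_d = ex$N_d,
             M = corpus$M, V = corpus$dictionary$V, K = config$K)
  class(st) <- "lda_state"
  st
}

#' Run collapsed Gibbs sweeps on a sampler state
#'
#' Each sweep resamples every token occurrence once, in document order.
#' With the token's current assignment removed from the counts, topic `k`
#' is drawn with probability proportional to
#' `(n_dk[d,k] + alpha) * (n_kw[k,w] + eta) / (n_k[k] + V * eta)`.
#' Draws consume the R session RNG stream (seed via [set.seed()] or via
#' `config$seed` in [train_lda()]).
#'
#' @param state An `lda_state` from [lda_init()] or a previous sweep.
#' @param config An [lda_config()] (only `alpha` and `eta` are used).
#' @param sweeps Number of full sweeps to run (default 1).
#' @return The updated `lda_state`.
#' @export
gibbs_sweep <- function(state, config, sweeps = 1L) {
  stopifnot(inherits(state, "lda_state"), inherits(config, "lda_config"))
  out <- cpp_gibbs(state$z, state$doc_of, state$word_of,
                   state$n_dk, state$n_kw, state$n_k,
                   config$alpha, config$eta, as.integer(sweeps), 0L, FALSE)
  state$z <- out$z; state$n_dk <- out$n_dk
  state$n_kw <- out$n_kw; state$n_k <- out$n_k
  state
}

#' Train an LDA topic model by collapsed Gibbs sampling
#'
#' Runs random initialization followed by `config$iterations` sweeps,
#' for each of `config$n_starts` independent chains (chain `r` is
#' seeded with `config$seed + r - 1` when a seed is given); the chain
#' with the highest training log-likelihood is returned. Point
#' estimates are taken from the final state (or averaged over
#' post-burn-in sweeps when `config$average_after_burnin`):
#' `phi[k,w] = (n_kw[k,w] + eta) / (n_k[k] + V*eta)` and
#' `theta[m,k] = (n_dk[m,k] + alpha) / (N_m + K*alpha)`.
#' The same seed yields a bit-identical model.
#'
#' @param corpus A `bow_corpus`.
#' @param config An [lda_config()].
#' @return An object of class `lda_model`: list with `phi` (K x V
#'   row-stochastic matrix of topic-word distributions), `theta` (M x K
#'   row-stochastic matrix of document-topic proportions), `config`,
#'   `dictionary`, `doc_ids`, `N_d`, the final sampler `state` and
#'   `log_likelihood` (training log-likelihood of the kept chain).
#' @export
train_lda <- function(corpus, config = lda_config()) {
  stopifnot(inherits(corpus, "bow_corpus"), inherits(config, "lda_config"))
  n_starts <- config$n_starts %||% 1L
  if (n_starts > 1L) {
    best <- NULL
    for (r in seq_len(n_starts)) {
      cfg_r <- config
      cfg_r$n_starts <- 1L
      if (!is.null(config$seed)) cfg_r$seed <- config$seed + r - 1L
      m <- train_lda(corpus, cfg_r)
      if (is.null(best) || m$log_likelihood > best$log_likelihood) best <- m
    }
    best$config <- config
    return(best)
  }
  if (corpus$M == 0L) stop_("corpus is empty")
  if (corpus$dictionary$V == 0L) stop_("vocabulary is empty")
  n_empty <- sum(vapply(corpus$docs, `[[`, 0L, "N") == 0L)
  if (n_empty > 0L)
    warning(sprintf("%d document(s) have no in-vocabulary tokens; their theta rows are the prior mean", n_empty),
            call. = FALSE)
  restore <- push_seed(config$seed)
  on.exit(restore())
  ex <- expand_corpus(corpus)
  if (length(ex$word_of) == 0L) stop_("corpus has no tokens")
  K <- config$K; V <- corpus$dictionary$V; M <- corpus$M
  z0 <- cpp_random_topics(length(ex$word_of), K)
  counts <- cpp_count_state(z0, ex$doc_of, ex$word_of, M, V, K)
  out <- cpp_gibbs(z0, ex$doc_of, ex$word_of,
                   counts$n_dk, counts$n_kw, counts$n_k,
                   config$alpha, config$eta,
                   config$iterations, config$burn_in,
                   config$average_after_burnin)
  if (config$average_after_burnin && out$n_avg > 0L) {
    phi <- out$phi_avg
    theta <- out$theta_avg
  } else {
    phi <- (out$n_kw + config$eta) / (out$n_k + V * config$eta)
    theta <- (out$n_dk + config$alpha) / (ex$N_d + K * config$alpha)
  }
  dimnames(phi) <- NULL; dimnames(theta) <- NULL
  st <- list(z = out$z, n_dk = out$n_dk, n_kw = out$n_kw, n_k = out$n_k,
             doc_of = ex$doc_of, word_of = ex$word_of, N_d = ex$N_d,
             M = M, V = V, K = K)
  class(st) <- "lda_state"
  lik <- perplexity_from_theta(phi, theta, corpus$docs)
  model <- list(phi = phi, theta = theta, config = config,
                dictionary = corpus$dictionary, doc_ids = corpus$doc_ids,
                N_d = ex$N_d, state = st,
                log_likelihood = lik$per_word_log_likelihood * lik$n_tokens)
  class(model) <- "lda_model"
  model
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> K = %d topics, V = %d tokens, M = %d documents (alpha = %g, eta = %g)\n",
              x$config$K, x$dictionary$V, nrow(x$theta),
              x$config$alpha, x$config$eta))
  invisible(x)
}

#' Fold-in inference of topic proportions for an unseen document
#'
#' The trained topic-word distributions are held fixed while the new
#' document's topic assignments are resampled `fold_iterations` times;
#' the returned row is `(n_dk + alpha) / (N_d + K*alpha)` from the final
#' assignment and sums to one.
#'
#' @param model An `lda_model`.
#' @param bow A `bow_document` built against `model$dictionary`
#'   (out-of-vocabulary tokens already dropped by [doc2bow()]).
#' @param fold_iterations Number of fold-in sweeps (default 100).
#' @param seed Optional RNG seed.
#' @return Numeric vector of length K summing to one.
#' @export
infer_theta <- function(model, bow, fold_iterations = 100L, seed = NULL) {
  stopifnot(inherits(model, "lda_model"), inherits(bow, "bow_document"))
  if (bow$N == 0L) stop_("query has no in-vocabulary tokens")
  restore <- push_seed(seed)
  on.exit(restore())
  word_of <- rep(bow$ids, bow$counts)
  as.numeric(cpp_fold_in(word_of, model$phi, model$config$alpha,
                         as.integer(fold_iterations)))
}

#' Top keywords of a topic
#'
#' @param model An `lda_model`.
#' @param topic 0-based topic index in `0:(K-1)`.
#' @param n Number of keywords (default `config$top_n_words`, capped at
#'   the vocabulary size); ties in probability are broken by ascending
#'   token id.
#' @return Data frame with columns `token` and `probability`, sorted by
#'   probability descending.
#' @export
top_keywords <- function(model, topic,
                         n = min(model$config$top_n_words, model$dictionary$V)) {
  stopifnot(inherits(model, "lda_model"))
  K <- model$config$K
  if (topic < 0L || topic >= K)
    stop_(sprintf("topic index %d out of range 0..%d", topic, K - 1L))
  V <- model$dictionary$V
  if (n < 1L || n > V) stop_(sprintf("n must be in 1..%d", V))
  p <- model$phi[topic + 1L, ]
  ord <- order(-p, seq_len(V))[seq_len(n)]
  data.frame(token = model$dictionary$id2token[ord], probability = p[ord],
             stringsAsFactors = FALSE)
}

#' Save / load a trained model directory
#'
#' Writes `config.json`, `dictionary.tsv`, `phi.tsv` (K rows of V
#' tab-separated values) and `theta.tsv` (doc_id followed by K values per
#' row; the leading doc_id column supports retrieval by document id
#' after reload). Numbers are written with 17 significant digits so the
#' round trip is exact.
#'
#' @param model An `lda_model`.
#' @param dir Directory path (created if missing).
#' @return `save_lda_model()` returns `dir` invisibly;
#'   `load_lda_model()` returns an `lda_model` (without sampler state).
#' @export
save_lda_model <- function(model, dir) {
  stopifnot(inherits(model, "lda_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  cfg_list <- list(K = cfg$K, alpha = cfg$alpha, eta = cfg$eta,
                   iterations = cfg$iterations, burn_in = cfg$burn_in,
                   seed = cfg$seed, top_n_words = cfg$top_n_words,
                   average_after_burnin = cfg$average_after_burnin,
                   n_starts = cfg$n_starts %||% 1L)
  jsonlite::write_json(cfg_list, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  save_dictionary(model$dictionary, file.path(dir, "dictionary.tsv"))
  write_num_matrix(model$phi, file.path(dir, "phi.tsv"))
  theta_out <- cbind(model$doc_ids, model$theta)
  write_num_matrix(theta_out, file.path(dir, "theta.tsv"))
  invisible(dir)
}

write_num_matrix <- function(m, path) {
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
}

read_num_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
}

#' @rdname save_lda_model
#' @export
load_lda_model <- function(dir) {
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  config <- lda_config(K = cfg$K, alpha = cfg$alpha, eta = cfg$eta,
                       iterations = cfg$iterations, burn_in = cfg$burn_in,
                       seed = cfg$seed, top_n_words = cfg$top_n_words,
                       average_after_burnin = isTRUE(cfg$average_after_burnin),
                       n_starts = cfg$n_starts %||% 1L)
  dict <- load_dictionary(file.path(dir, "dictionary.tsv"))
  phi <- read_num_matrix(file.path(dir, "phi.tsv"))
  th <- read_num_matrix(file.path(dir, "theta.tsv"))
  doc_ids <- as.integer(th[, 1L])
  theta <- th[, -1L, drop = FALSE]
  model <- list(phi = phi, theta = theta, config = config, dictionary = dict,
                doc_ids = doc_ids, N_d = NULL, state = NULL)
  class(model) <- "lda_model"
  model
}
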