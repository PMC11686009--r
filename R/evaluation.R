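#' Held-out perplexity of a topic model
#'
#' For each test document `d`, topic proportions `theta_d` are obtained
#' by fold-in sampling ([infer_theta()]); the document log-likelihood is
#' `log p(w_d) = sum_n log( sum_k theta_dk * phi[k, w_n] )` and
#' `perplexity = exp( -sum_d log p(w_d) / sum_d N_d )`.
#' Documents with no in-vocabulary tokens are excluded with a warning.
#'
#' @param model An `lda_model`.
#' @param test_corpus A `bow_corpus` built against `model$dictionary`.
#' @param fold_iterations Fold-in sweeps per document (default 100).
#' @param seed Optional RNG seed covering the whole evaluation.
#' @return List with `perplexity`, `log_perplexity` (its natural log, so
#'   `perplexity == exp(log_perplexity)` exactly) and
#'   `per_word_log_likelihood` (`= -log_perplexity`; the per-word
#'   log-likelihood convention under which a well-fit model reports a
#'   negative number), plus `n_docs` and `n_tokens` actually scored.
#' @export
perplexity <- function(model, test_corpus, fold_iterations = 100L, seed = NULL) {
  stopifnot(inherits(model, "lda_model"), inherits(test_corpus, "bow_corpus"))
  restore <- push_seed(seed)
  on.exit(restore())
  keep <- vapply(test_corpus$docs, `[[`, 0L, "N") > 0L
  if (!any(keep)) stop_("every test document is empty after vocabulary filtering")
  if (any(!keep))
    warning(sprintf("excluding %d empty test document(s) from perplexity", sum(!keep)),
            call. = FALSE)
  docs <- test_corpus$docs[keep]
  theta <- t(vapply(docs, function(b)
    infer_theta(model, b, fold_iterations = fold_iterations, seed = NULL),
    numeric(model$config$K)))
  res <- perplexity_from_theta(model$phi, theta, docs)
  res$n_docs <- length(docs)
  res
}

#' Perplexity from explicit topic proportions
#'
#' The likelihood half of [perplexity()], exposed separately so that
#' training-set perplexity (where `theta` is already known) and exact
#' hand-specified cases can be computed without fold-in sampling.
#'
#' @param phi K x V row-stochastic topic-word matrix.
#' @param theta Matrix with one K-length row per document in `docs`.
#' @param docs List of `bow_document`s.
#' @return Same fields as [perplexity()] (minus `n_docs`).
#' @export
perplexity_from_theta <- function(phi, theta, docs) {
  theta <- matrix(theta, nrow = length(docs))
  total_ll <- 0
  total_n <- 0
  for (i in seq_along(docs)) {
    b <- docs[[i]]
    if (b$N == 0L) next
    pw <- as.numeric(theta[i, , drop = FALSE] %*% phi[, b$ids + 1L, drop = FALSE])
    total_ll <- total_ll + sum(b$counts * log(pw))
    total_n <- total_n + b$N
  }
  if (total_n == 0L) stop_("no tokens to score")
  log_perp <- -total_ll / total_n
  list(perplexity = exp(log_perp), log_perplexity = log_perp,
       per_word_log_likelihood = -log_perp, n_tokens = total_n)
}

#' Pairwise-Jaccard topic coherence
#'
#' Coherence of one topic's top-word list:
#' `Cv = 2 / (N(N-1)) * sum_{i<j} |D(wi) n D(wj)| / |D(wi) u D(wj)|`
#' where `D(w)` is the set of documents containing word `w` and a pair
#' with an empty union contributes 0. `Cv` lies in `[0, 1]`; higher means
#' the topic's keywords co-occur in the same documents more often, i.e.
#' the topic is more interpretable.
#'
#' @param word_ids Integer vector (0-based token ids) of the topic's
#'   top-N words; N >= 2.
#' @param doc_sets List of length V: element `i` holds the ids of the
#'   documents containing token id `i - 1` (see [token_doc_sets()]).
#' @return Coherence score in `[0, 1]`.
#' @export
jaccard_coherence <- function(word_ids, doc_sets) {
  n <- length(word_ids)
  if (n < 2L) stop_("coherence needs at least 2 words")
  sets <- doc_sets[word_ids + 1L]
  all_docs <- unique(unlist(sets, use.names = FALSE))
  if (length(all_docs) == 0L) return(0)
  inc <- vapply(sets, function(s) all_docs %in% s, logical(length(all_docs)))
  inc <- matrix(inc, nrow = length(all_docs))
  inter <- crossprod(inc)                       # |D(wi) n D(wj)|
  sizes <- colSums(inc)
  uni <- outer(sizes, sizes, `+`) - inter       # |D(wi) u D(wj)|
  sim <- ifelse(uni > 0, inter / uni, 0)
  ut <- upper.tri(sim)
  2 / (n * (n - 1)) * sum(sim[ut])
}

#' Document sets per token for coherence
#'
#' @param corpus A `bow_corpus`.
#' @return List of length V; element `i` is the integer vector of
#'   document ids whose bag of words contains token id `i - 1`.
#' @export
token_doc_sets <- function(corpus) {
  stopifnot(inherits(corpus, "bow_corpus"))
  V <- corpus$dictionary$V
  ids_all <- unlist(lapply(corpus$docs, `[[`, "ids"), use.names = FALSE)
  doc_rep <- rep(corpus$doc_ids, vapply(corpus$docs, function(b) length(b$ids), 0L))
  out <- split(doc_rep, factor(ids_all, levels = 0:(V - 1L)))
  lapply(out, as.integer)
}

#' Coherence scan over candidate numbers of topics
#'
#' Trains one seeded model per K and scores every topic's top-`top_n`
#' words with [jaccard_coherence()] against the training corpus'
#' document sets.
#'
#' @param corpus A `bow_corpus`.
#' @param K_values Integer vector of topic counts to scan
#'   (default `c(2, 4, 6, 8, 10)`).
#' @param config Template [lda_config()]; its K is overridden per scan
#'   point, everything else (priors, iterations, seed) is reused.
#' @param top_n Words per topic entering the coherence score (default 10).
#' @return List with `per_topic` (data frame: `K`, `topic`, `cv`) and
#'   `mean_by_K` (named numeric vector of per-K mean coherence).
#' @export
coherence_scan <- function(corpus, K_values = c(2L, 4L, 6L, 8L, 10L),
                           config = lda_config(), top_n = 10L) {
  stopifnot(length(K_values) >= 1L)
  dsets <- token_doc_sets(corpus)
  rows <- list()
  for (K in K_values) {
    cfg <- config
    cfg$K <- as.integer(K)
    model <- train_lda(corpus, cfg)
    for (k in 0:(K - 1L)) {
      p <- model$phi[k + 1L, ]
      top_ids <- order(-p, seq_along(p))[seq_len(min(top_n, length(p)))] - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        K = K, topic = k, cv = jaccard_coherence(top_ids, dsets))
    }
  }
  per_topic <- do.call(rbind, rows)
  means <- tapply(per_topic$cv, per_topic$K, mean)
  list(per_topic = per_topic,
       mean_by_K = stats::setNames(as.numeric(means), names(means)))
}

#' Classification accuracy
#'
#' @param gold,pred Equal-length label vectors.
#' @return Fraction of positions where `gold == pred`.
#' @export
accuracy <- function(gold, pred) {
  if (length(gold) != length(pred)) stop_("gold and pred must have equal length")
  if (length(gold) == 0L) stop_("empty label vectors")
  mean(gold == pred)
}

#' Multi-class F1 score
#'
#' Per-class F1 is `2PR/(P+R)` from one-vs-rest counts; a class with
#' zero predicted and zero gold support contributes 0. Classes are the
#' union of gold and predicted labels.
#'
#' @param gold,pred Equal-length label vectors.
#' @param average `"weighted"` (by gold support; the default, standard
#'   for imbalanced multi-class reporting), `"macro"` (unweighted mean)
#'   or `"micro"` (global counts; equals accuracy for single-label data).
#' @return F1 score in `[0, 1]`.
#' @export
f1_score <- function(gold, pred, average = c("weighted", "macro", "micro")) {
  average <- match.arg(average)
  if (length(gold) != length(pred)) stop_("gold and pred must have equal length")
  classes <- sort(unique(c(as.character(gold), as.character(pred))))
  g <- factor(as.character(gold), levels = classes)
  p <- factor(as.character(pred), levels = classes)
  cm <- table(g, p)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  if (average == "micro") {
    denom <- 2 * sum(tp) + sum(fp) + sum(fn)
    return(if (denom == 0) 0 else 2 * sum(tp) / denom)
  }
  f1 <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
  if (average == "macro") return(mean(f1))
  support <- rowSums(cm)
  sum(f1 * support) / sum(support)
}
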