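# Symmetric Dirichlet draws via normalized gamma variates.
rdirichlet_sym <- function(n, dim, concentration) {
  g <- matrix(rgamma(n * dim, shape = concentration, rate = 1), nrow = n)
  # guard against all-zero rows at very small concentrations
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- rgamma(sum(zero) * dim, shape = 1, rate = 1)
  g / rowSums(g)
}

#' Sample topic-word distributions
#'
#' Each of the K topic rows is drawn independently from the symmetric
#' Dirichlet(eta) on the V-simplex — the topic half of the LDA
#' generative process.
#'
#' @param K Number of topics (>= 1).
#' @param V Vocabulary size (>= 1).
#' @param eta Dirichlet concentration (> 0); small values give sparse,
#'   well-separated topics.
#' @param seed Optional RNG seed.
#' @return K x V row-stochastic matrix.
#' @export
sample_topics <- function(K, V, eta = 0.1, seed = NULL) {
  if (K < 1L || V < 1L) stop_("K and V must be >= 1")
  if (!is.numeric(eta) || eta <= 0) stop_("eta must be > 0")
  restore <- push_seed(seed)
  on.exit(restore())
  rdirichlet_sym(K, V, eta)
}

render_tokens <- function(word_ids) paste(sprintf("w%04d", word_ids), collapse = " ")

build_synthetic <- function(phi, theta, doc_len_mean, gold = NULL) {
  M <- nrow(theta)
  K <- nrow(phi)
  V <- ncol(phi)
  z_true <- vector("list", M)
  texts <- character(M)
  for (m in seq_len(M)) {
    len <- 1L + rpois(1L, max(doc_len_mean - 1, 0))
    z <- sample.int(K, len, replace = TRUE, prob = theta[m, ]) - 1L
    w <- integer(len)
    for (k in unique(z)) {
      pos <- z == k
      w[pos] <- sample.int(V, sum(pos), replace = TRUE, prob = phi[k + 1L, ]) - 1L
    }
    z_true[[m]] <- z
    texts[m] <- render_tokens(w)
  }
  list(
    docs = data.frame(doc_id = seq_len(M), text = texts,
                      stringsAsFactors = FALSE),
    truth = list(phi_true = phi, theta_true = theta, z_true = z_true,
                 gold = gold)
  )
}

#' Generate a synthetic corpus from the LDA generative process
#'
#' For each document: `theta_m ~ Dirichlet(alpha)`; length `~ 1 +
#' Poisson(doc_len_mean - 1)` (shifted so every document has at least
#' one token); each token draws a topic from `theta_m` and a word from
#' the topic's row of `phi`. Words are rendered as pseudo-words
#' `"w0000" ...` (all >= 3 characters, no special characters), so the
#' preprocessing pipeline is the identity on synthetic text and LDA
#' behavior is tested in isolation.
#'
#' @param phi K x V row-stochastic topic-word matrix
#'   (e.g. from [sample_topics()]).
#' @param M Number of documents (>= 0).
#' @param alpha Dirichlet concentration for document-topic proportions.
#' @param doc_len_mean Mean document length (>= 1).
#' @param seed Optional RNG seed.
#' @return An object of class `synthetic_corpus`: list with `docs`
#'   (data frame `doc_id`, `text`) and `truth` (list with `phi_true`,
#'   `theta_true`, `z_true` and `params`).
#' @export
sample_corpus <- function(phi, M, alpha = 0.1, doc_len_mean = 50, seed = NULL) {
  stopifnot(is.matrix(phi))
  if (M < 0L) stop_("M must be >= 0")
  if (!is.numeric(alpha) || alpha <= 0) stop_("alpha must be > 0")
  if (doc_len_mean < 1) stop_("doc_len_mean must be >= 1")
  restore <- push_seed(seed)
  on.exit(restore())
  K <- nrow(phi)
  theta <- if (M == 0L) matrix(numeric(0), nrow = 0L, ncol = K) else
    rdirichlet_sym(M, K, alpha)
  out <- build_synthetic(phi, theta, doc_len_mean)
  out$truth$params <- list(K = K, V = ncol(phi), M = M, alpha = alpha,
                           eta = NA_real_, doc_len_mean = doc_len_mean,
                           seed = seed)
  class(out) <- "synthetic_corpus"
  out
}

#' Generate a well-separated synthetic corpus with gold labels
#'
#' Topics have disjoint vocabularies (uniform over `words_per_topic`
#' dedicated pseudo-words each); every document is assigned a designated
#' topic uniformly at random, recorded as its gold label, and its theta
#' puts mass `purity` there and `(1 - purity)/(K - 1)` on each other
#' topic. This is the classification testbed: with high purity the
#' dominant topic is recoverable by construction.
#'
#' @param K Number of topics (>= 1).
#' @param words_per_topic Dedicated vocabulary size per topic (>= 2).
#' @param M Number of documents.
#' @param doc_len_mean Mean document length.
#' @param purity Designated-topic mass in (0, 1].
#' @param seed Optional RNG seed.
#' @return A `synthetic_corpus`; `truth$gold` holds the designated
#'   (0-based) topic per document.
#' @export
separated_corpus <- function(K, words_per_topic = 20L, M = 500L,
                             doc_len_mean = 50, purity = 0.9, seed = NULL) {
  if (K < 1L) stop_("K must be >= 1")
  if (words_per_topic < 2L) stop_("words_per_topic must be >= 2")
  if (purity <= 0 || purity > 1) stop_("purity must be in (0, 1]")
  if (K == 1L && purity < 1) stop_("purity must be 1 when K = 1")
  restore <- push_seed(seed)
  on.exit(restore())
  V <- K * words_per_topic
  phi <- matrix(0, nrow = K, ncol = V)
  for (k in seq_len(K))
    phi[k, ((k - 1L) * words_per_topic + 1L):(k * words_per_topic)] <-
      1 / words_per_topic
  gold <- sample.int(K, M, replace = TRUE) - 1L
  off <- if (K > 1L) (1 - purity) / (K - 1L) else 0
  theta <- matrix(off, nrow = M, ncol = K)
  theta[cbind(seq_len(M), gold + 1L)] <- purity
  out <- build_synthetic(phi, theta, doc_len_mean, gold = gold)
  out$truth$params <- list(K = K, V = V, M = M, alpha = NA_real_,
                           eta = NA_real_, doc_len_mean = doc_len_mean,
                           purity = purity, words_per_topic = words_per_topic,
                           seed = seed)
  class(out) <- "synthetic_corpus"
  out
}

#' Five-document sample health corpus
#'
#' A tiny fixture of Afaan Oromo patient-symptom sentences (hemorrhoid,
#' head swelling, discharge, headache/insomnia, knee pain), useful for
#' exercising the preprocessing rules on real orthography — including
#' word-internal apostrophes.
#'
#' @return Data frame with columns `doc_id` (1 to 5) and `text`.
#' @export
fixture_table1 <- function() {
  data.frame(
    doc_id = 1:5,
    text = c(
      "karaa bobbaa koo dhiigni na ba\u2019a, keessisaa na guba, hooqi hooqii na godha, bobbaan dafee naaf hin ba\u2019u",
      "mataa keessaan dhiita\u2019ee ba\u2019e, bakki sun diimatee ni guba",
      "Dhangala\u2019aa karaa qaama koon na ba\u2019a, foolii badaa kan qabuu fi adii kan ta\u2019etu na ba\u2019a, shiffi jedhee natti bibbiqila",
      "Mataa koo na bowwaafata, yaada natti baay\u2019isa, Irribni sirnaan naaf hin dhufu, nan yaadda\u2019a",
      "Jilba koo keessa deeme na nyaataa, yeroo dheeraa deemu hin danda\u2019u"
    ),
    stringsAsFactors = FALSE
  )
}

#' Total-variation distance between two probability vectors
#'
#' @param p,q Probability vectors of equal length.
#' @return `0.5 * sum(abs(p - q))`, in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  0.5 * sum(abs(p - q))
}

#' Greedy topic matching between estimated and true topic-word matrices
#'
#' Topics carry no intrinsic order, so recovered topics must be aligned
#' with the generating ones before distances mean anything. Pairs are
#' matched greedily: the globally closest (estimated, true) pair by
#' total-variation distance is fixed first, then the closest among the
#' remaining topics, until each topic is used once.
#'
#' @param phi_est,phi_true K x V row-stochastic matrices.
#' @return List with `perm` (integer vector: `perm[k]` is the 1-based
#'   true-topic row matched to estimated row `k`), `tv` (per-pair
#'   distances, ordered by estimated row) and `mean_tv`.
#' @export
match_topics <- function(phi_est, phi_true) {
  stopifnot(nrow(phi_est) == nrow(phi_true), ncol(phi_est) == ncol(phi_true))
  K <- nrow(phi_est)
  D <- matrix(0, K, K)
  for (i in seq_len(K))
    for (j in seq_len(K))
      D[i, j] <- tv_distance(phi_est[i, ], phi_true[j, ])
  perm <- integer(K)
  tv <- numeric(K)
  free_e <- rep(TRUE, K); free_t <- rep(TRUE, K)
  for (step in seq_len(K)) {
    Dm <- D
    Dm[!free_e, ] <- Inf
    Dm[, !free_t] <- Inf
    idx <- arrayInd(which.min(Dm), dim(Dm))
    i <- idx[1L]; j <- idx[2L]
    perm[i] <- j
    tv[i] <- D[i, j]
    free_e[i] <- FALSE; free_t[j] <- FALSE
  }
  list(perm = perm, tv = tv, mean_tv = mean(tv))
}

#' Write a synthetic corpus and its latent truth to disk
#'
#' Writes `corpus.txt` (one document per line), `truth_phi.tsv`,
#' `truth_theta.tsv` and, when gold labels exist, `gold_labels.tsv`
#' (`doc_id<TAB>gold_topic`).
#'
#' @param synth A `synthetic_corpus`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_synthetic_corpus <- function(synth, dir) {
  stopifnot(inherits(synth, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(synth$docs$text, file.path(dir, "corpus.txt"), useBytes = TRUE)
  write_num_matrix(synth$truth$phi_true, file.path(dir, "truth_phi.tsv"))
  write_num_matrix(synth$truth$theta_true, file.path(dir, "truth_theta.tsv"))
  if (!is.null(synth$truth$gold)) {
    df <- data.frame(doc_id = synth$docs$doc_id, gold_topic = synth$truth$gold)
    write.table(df, file.path(dir, "gold_labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
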