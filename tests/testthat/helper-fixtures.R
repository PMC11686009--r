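# Shared test fixtures and independent oracles.

# Bag-of-words corpus straight from token lists.
make_corpus <- function(token_lists, doc_ids = seq_along(token_lists)) {
  names(token_lists) <- as.character(doc_ids)
  dict <- build_dictionary(token_lists)
  bow_corpus(dict, token_lists)
}

# Align an estimated phi (columns in dictionary first-occurrence order
# over pseudo-words "wNNNN") to the generating phi's word-id order.
# Words never emitted get a zero column, so lost mass counts in TV.
align_phi <- function(phi_est, dict, V_true) {
  wid <- as.integer(sub("^w", "", dict$id2token))
  out <- matrix(0, nrow = nrow(phi_est), ncol = V_true)
  out[, wid + 1L] <- phi_est
  out
}

# Brute-force pairwise-Jaccard coherence: explicit double loop with set
# intersect/union. Independent of the incidence-matrix implementation.
brute_coherence <- function(word_ids, doc_sets) {
  n <- length(word_ids)
  total <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- doc_sets[[word_ids[i] + 1L]]
      b <- doc_sets[[word_ids[j] + 1L]]
      u <- union(a, b)
      total <- total + if (length(u) == 0) 0 else length(intersect(a, b)) / length(u)
    }
  }
  2 / (n * (n - 1)) * total
}

# Random (incidence, word list) coherence instance.
random_coherence_instance <- function(V = 20L, n_docs = 50L, n_words = 10L) {
  doc_sets <- lapply(seq_len(V), function(i) {
    k <- sample(0:n_docs, 1L)
    if (k == 0L) integer(0) else sort(sample.int(n_docs, k))
  })
  list(word_ids = sample(0:(V - 1L), n_words), doc_sets = doc_sets)
}

# Collapsed-Gibbs conditional for one token, enumerated directly from an
# assignment vector (counts rebuilt from scratch each call).
enumerate_conditional <- function(z, doc_of, word_of, t, K, V, alpha, eta) {
  zm <- z[-t]
  dm <- doc_of[-t]
  wm <- word_of[-t]
  d <- doc_of[t]; w <- word_of[t]
  p <- numeric(K)
  for (k in 0:(K - 1L)) {
    n_dk <- sum(zm == k & dm == d)
    n_kw <- sum(zm == k & wm == w)
    n_k <- sum(zm == k)
    p[k + 1L] <- (n_dk + alpha) * (n_kw + eta) / (n_k + V * eta)
  }
  p / sum(p)
}

cli_script <- function() {
  system.file("cli", "oromotopics.R", package = "oromotopics", mustWork = TRUE)
}

run_cli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(shQuote(cli_script()), shQuote(args)),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("CLI failed: ", paste(out, collapse = "\n"))
  invisible(out)
}
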