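#' Build a token/integer-ID dictionary from tokenized documents
#'
#' Ids are assigned 0-based in order of first occurrence during a single
#' forward scan over the documents, which makes the mapping deterministic
#' and stable when documents are appended to the corpus.
#'
#' @param docs List of character vectors (one per document), e.g. the
#'   output of [preprocess_corpus()].
#' @return An object of class `lda_dictionary`: a list with `token2id`
#'   (named integer vector, values `0:(V-1)`), `id2token` (character
#'   vector, position `i` holds the token with id `i - 1`), `doc_freq`
#'   (integer vector aligned with `id2token`: number of documents
#'   containing each token) and `V` (vocabulary size).
#' @export
build_dictionary <- function(docs) {
  stopifnot(is.list(docs))
  all_tokens <- unlist(docs, use.names = FALSE)
  if (length(all_tokens) == 0L)
    stop_("cannot build a dictionary: all documents are empty")
  vocab <- unique(all_tokens)
  per_doc <- lapply(docs, unique)
  df_tab <- table(factor(unlist(per_doc, use.names = FALSE), levels = vocab))
  d <- list(
    token2id = stats::setNames(seq_along(vocab) - 1L, vocab),
    id2token = vocab,
    doc_freq = as.integer(df_tab),
    V = length(vocab)
  )
  class(d) <- "lda_dictionary"
  d
}

#' @export
print.lda_dictionary <- function(x, ...) {
  cat(sprintf("<lda_dictionary> V = %d tokens\n", x$V))
  invisible(x)
}

#' Convert a token sequence to a bag-of-words document
#'
#' Tokens absent from the dictionary are silently dropped (this is what
#' makes unseen queries usable at inference time).
#'
#' @param dict An `lda_dictionary`.
#' @param tokens Character vector of (already preprocessed) tokens.
#' @param doc_id Optional document id to attach.
#' @return An object of class `bow_document`: list with `doc_id`, `ids`
#'   (strictly increasing 0-based token ids), `counts` (positive
#'   integers, aligned with `ids`) and `N` (total token count).
#' @export
doc2bow <- function(dict, tokens, doc_id = NA_integer_) {
  stopifnot(inherits(dict, "lda_dictionary"))
  ids <- unname(dict$token2id[tokens])
  ids <- ids[!is.na(ids)]
  u <- sort(unique(ids))
  counts <- tabulate(match(ids, u), nbins = length(u))
  bow <- list(doc_id = doc_id, ids = as.integer(u),
              counts = as.integer(counts), N = as.integer(sum(counts)))
  class(bow) <- "bow_document"
  bow
}

#' Build a bag-of-words corpus
#'
#' @param dict An `lda_dictionary`.
#' @param docs Named list of token vectors (names are document ids), as
#'   returned by [preprocess_corpus()].
#' @return An object of class `bow_corpus`: list with `docs` (list of
#'   `bow_document`), `doc_ids`, `M` (number of documents) and
#'   `dictionary`.
#' @export
bow_corpus <- function(dict, docs) {
  stopifnot(inherits(dict, "lda_dictionary"), is.list(docs))
  ids <- if (!is.null(names(docs))) as.integer(names(docs)) else seq_along(docs)
  bows <- Map(function(toks, id) doc2bow(dict, toks, doc_id = id), docs, ids)
  corp <- list(docs = unname(bows), doc_ids = ids, M = length(bows),
               dictionary = dict)
  class(corp) <- "bow_corpus"
  corp
}

#' @export
print.bow_corpus <- function(x, ...) {
  cat(sprintf("<bow_corpus> M = %d documents, V = %d tokens, %d occurrences\n",
              x$M, x$dictionary$V, sum(vapply(x$docs, `[[`, 0L, "N"))))
  invisible(x)
}

#' Save / load a dictionary as TSV
#'
#' The file format is UTF-8 TSV with header `id<TAB>token<TAB>doc_freq`.
#' `load_dictionary()` validates that the ids are exactly `0:(V-1)` with
#' no duplicates and reports the offending line otherwise.
#'
#' @param dict An `lda_dictionary`.
#' @param path File path.
#' @return `save_dictionary()` returns `path` invisibly;
#'   `load_dictionary()` returns an `lda_dictionary`.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "lda_dictionary"))
  df <- data.frame(id = seq_len(dict$V) - 1L, token = dict$id2token,
                   doc_freq = dict$doc_freq)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   colClasses = c("character", "character", "integer"),
                   encoding = "UTF-8")
  ids <- suppressWarnings(as.integer(df$id))
  bad <- which(is.na(ids))
  if (length(bad) > 0L)
    stop_(sprintf("malformed dictionary file '%s': non-integer id on line %d",
                  path, bad[1L] + 1L))
  dup <- which(duplicated(ids))
  if (length(dup) > 0L)
    stop_(sprintf("malformed dictionary file '%s': duplicate id %d on line %d",
                  path, ids[dup[1L]], dup[1L] + 1L))
  if (!identical(sort(ids), seq_along(ids) - 1L))
    stop_(sprintf("malformed dictionary file '%s': ids are not 0..V-1", path))
  ord <- order(ids)
  d <- list(
    token2id = stats::setNames(ids[ord], df$token[ord]),
    id2token = df$token[ord],
    doc_freq = as.integer(df$doc_freq[ord]),
    V = length(ids)
  )
  class(d) <- "lda_dictionary"
  d
}

#' Save / load a bag-of-words corpus as JSONL
#'
#' One JSON object per line: `{"doc_id": 1, "bow": [[id, count], ...]}`.
#'
#' @param corpus A `bow_corpus`.
#' @param path File path.
#' @param dict Dictionary to attach on load (the JSONL file stores only
#'   ids and counts).
#' @return `save_bow_corpus()` returns `path` invisibly;
#'   `load_bow_corpus()` returns a `bow_corpus`.
#' @export
save_bow_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "bow_corpus"))
  lines <- vapply(corpus$docs, function(b) {
    pairs <- if (length(b$ids) == 0L) "[]" else
      paste0("[", paste(sprintf("[%d,%d]", b$ids, b$counts), collapse = ","), "]")
    sprintf('{"doc_id":%d,"bow":%s}', b$doc_id, pairs)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_bow_corpus
#' @export
load_bow_corpus <- function(path, dict) {
  stopifnot(inherits(dict, "lda_dictionary"))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  bows <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyMatrix = TRUE)
    m <- obj$bow
    if (length(m) == 0L) {
      ids <- integer(0); counts <- integer(0)
    } else {
      ids <- as.integer(m[, 1L]); counts <- as.integer(m[, 2L])
    }
    if (any(ids >= dict$V))
      stop_(sprintf("bow corpus '%s': token id %d exceeds vocabulary size %d",
                    path, max(ids), dict$V))
    b <- list(doc_id = as.integer(obj$doc_id), ids = ids, counts = counts,
              N = sum(counts))
    class(b) <- "bow_document"
    b
  })
  corp <- list(docs = bows,
               doc_ids = vapply(bows, `[[`, 0L, "doc_id"),
               M = length(bows), dictionary = dict)
  class(corp) <- "bow_corpus"
  corp
}
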