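#' Topic label map
#'
#' Human-curated mapping from topic index to a specialist or
#' disease-category name. Labels are supplied, never inferred: the model
#' only produces keyword clusters, and naming them is an upstream human
#' annotation step whose product this object carries.
#'
#' @param labels Character vector of K non-empty labels; element `i`
#'   names topic `i - 1`. Duplicate labels are permitted but warned
#'   about.
#' @return An object of class `label_map`: named character vector with
#'   names `"0" ... "K-1"`.
#' @export
label_map <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L || any(!nzchar(labels)) || anyNA(labels))
    stop_("labels must be non-empty strings")
  if (anyDuplicated(labels))
    warning("duplicate topic labels: distinct topics will share a class name",
            call. = FALSE)
  lm <- stats::setNames(labels, as.character(seq_along(labels) - 1L))
  class(lm) <- "label_map"
  lm
}

#' Read a label map from JSON
#'
#' Expected format: `{"0": "Nervous disease", "1": "Gynecology", ...}`.
#' The packaged example map for a 10-topic health-document model lives at
#' `system.file("extdata", "labels_health10.json", package = "oromotopics")`.
#'
#' @param path JSON file path.
#' @return A `label_map`.
#' @export
read_label_map <- function(path) {
  obj <- jsonlite::fromJSON(path)
  keys <- suppressWarnings(as.integer(names(obj)))
  if (anyNA(keys)) stop_(sprintf("label map '%s': non-integer topic key", path))
  if (!identical(sort(keys), seq_along(keys) - 1L))
    stop_(sprintf("label map '%s': topic keys must be exactly 0..K-1", path))
  label_map(unlist(obj, use.names = FALSE)[order(keys)])
}

check_label_map <- function(lm, K) {
  stopifnot(inherits(lm, "label_map"))
  have <- as.integer(names(lm))
  missing <- setdiff(0:(K - 1L), have)
  if (length(missing) > 0L)
    stop_(sprintf("label map is missing topics: %s",
                  paste(missing, collapse = ", ")))
  extra <- setdiff(have, 0:(K - 1L))
  if (length(extra) > 0L)
    stop_(sprintf("label map has labels for unknown topics: %s",
                  paste(extra, collapse = ", ")))
  invisible(lm)
}

#' Dominant topic of a document
#'
#' @param theta_row Probability vector of length K (sums to one within
#'   tolerance). Ties are broken by the lowest topic index.
#' @return List with `topic` (0-based index) and `contribution`
#'   (its probability).
#' @export
dominant_topic <- function(theta_row) {
  if (any(!is.finite(theta_row))) stop_("theta row contains non-finite entries")
  i <- which.max(theta_row)
  list(topic = as.integer(i - 1L), contribution = as.numeric(theta_row[i]))
}

#' Classify every training document by its dominant topic
#'
#' Produces one record per document: dominant topic, its contribution
#' weight, the attached human label and the dominant topic's top
#' keywords.
#'
#' @param model An `lda_model`.
#' @param labels A [label_map()] whose keys match the model's K.
#' @param tokens Optional named list of token vectors (names = doc ids)
#'   used to fill the `cleaned_text` column.
#' @return Data frame with columns `doc_id`, `dominant_topic`,
#'   `contribution`, `label`, `keywords` (comma-separated top tokens)
#'   and `cleaned_text`.
#' @export
classify_corpus <- function(model, labels, tokens = NULL) {
  stopifnot(inherits(model, "lda_model"))
  K <- model$config$K
  check_label_map(labels, K)
  kw_by_topic <- vapply(0:(K - 1L), function(k)
    paste(top_keywords(model, k)$token, collapse = ", "), character(1))
  M <- nrow(model$theta)
  dom <- apply(model$theta, 1L, which.max) - 1L
  contrib <- model$theta[cbind(seq_len(M), dom + 1L)]
  cleaned <- rep(NA_character_, M)
  if (!is.null(tokens)) {
    idx <- match(as.character(model$doc_ids), names(tokens))
    cleaned <- vapply(idx, function(i)
      if (is.na(i)) NA_character_ else paste(tokens[[i]], collapse = " "),
      character(1))
  }
  data.frame(doc_id = model$doc_ids,
             dominant_topic = as.integer(dom),
             contribution = as.numeric(contrib),
             label = unname(unclass(labels)[as.character(dom)]),
             keywords = kw_by_topic[dom + 1L],
             cleaned_text = cleaned,
             stringsAsFactors = FALSE)
}

#' Reproducible train/test split of document ids
#'
#' @param doc_ids Vector of document ids (length >= 2).
#' @param test_fraction Fraction held out, in (0, 1); the test set has
#'   `round(test_fraction * M)` ids.
#' @param seed Optional RNG seed.
#' @return List with sorted `train` and `test` id vectors: disjoint and
#'   jointly exhaustive.
#' @export
train_test_split <- function(doc_ids, test_fraction = 0.2, seed = NULL) {
  M <- length(doc_ids)
  if (M < 2L) stop_("need at least 2 documents to split")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_("test_fraction must be in (0, 1)")
  restore <- push_seed(seed)
  on.exit(restore())
  n_test <- round(test_fraction * M)
  test <- sort(sample(doc_ids, n_test))
  list(train = sort(setdiff(doc_ids, test)), test = test)
}

# Shared inference path for unseen text: preprocess, map to the model
# vocabulary, fold-in. Returns NULL when nothing survives (abstention).
infer_query_theta <- function(model, text, stopwords = character(0),
                              min_len = 3L, fold_iterations = 100L,
                              seed = NULL) {
  toks <- suppressWarnings(
    preprocess_pipeline(text, stopwords = stopwords, min_len = min_len))
  bow <- doc2bow(model$dictionary, toks)
  if (bow$N == 0L) return(NULL)
  infer_theta(model, bow, fold_iterations = fold_iterations, seed = seed)
}

#' Classify an unseen document
#'
#' Runs the full path preprocess -> bag of words -> fold-in inference ->
#' dominant topic -> label. When no in-vocabulary token survives
#' preprocessing the result is a typed abstention (`status = "abstain"`),
#' never a silent default class.
#'
#' @param model An `lda_model`.
#' @param labels A [label_map()] matching the model's K.
#' @param text Raw document text.
#' @param stopwords Stop-word vector used at preprocessing.
#' @param min_len Minimum token length (default 3).
#' @param fold_iterations Fold-in sweeps (default 100).
#' @param seed Optional RNG seed.
#' @return An object of class `classified_document`: list with `status`
#'   (`"ok"` or `"abstain"`) and, when ok, `dominant_topic`,
#'   `contribution`, `label`, `keywords` and `theta`.
#' @export
classify_unseen <- function(model, labels, text, stopwords = character(0),
                            min_len = 3L, fold_iterations = 100L, seed = NULL) {
  check_label_map(labels, model$config$K)
  theta <- infer_query_theta(model, text, stopwords, min_len,
                             fold_iterations, seed)
  if (is.null(theta)) {
    out <- list(status = "abstain", text = text)
    class(out) <- "classified_document"
    return(out)
  }
  d <- dominant_topic(theta)
  out <- list(status = "ok", text = text,
              dominant_topic = d$topic, contribution = d$contribution,
              label = unname(unclass(labels)[as.character(d$topic)]),
              keywords = top_keywords(model, d$topic)$token,
              theta = theta)
  class(out) <- "classified_document"
  out
}

#' @export
print.classified_document <- function(x, ...) {
  if (x$status == "abstain") {
    cat("<classified_document> abstained: no in-vocabulary tokens\n")
  } else {
    cat(sprintf("<classified_document> topic %d (%s), contribution %.4f\n",
                x$dominant_topic, x$label, x$contribution))
  }
  invisible(x)
}
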