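#' Retrieve a document's topic mix by its id
#'
#' The trained theta row, ranked by probability descending (ties by
#' ascending topic index), mirroring the topic-contribution tables a
#' document-id lookup produces.
#'
#' @param model An `lda_model`.
#' @param doc_id A document id present in the trained corpus.
#' @return An object of class `topic_mix`: list with `doc_id`, `ranked`
#'   (data frame `topic`, `probability`, descending) and `dominant`
#'   (first row of `ranked`).
#' @export
topic_mix <- function(model, doc_id) {
  stopifnot(inherits(model, "lda_model"))
  i <- match(doc_id, model$doc_ids)
  if (is.na(i)) stop_(sprintf("unknown document id: %s", doc_id))
  row <- model$theta[i, ]
  K <- length(row)
  ord <- order(-row, seq_len(K))
  ranked <- data.frame(topic = ord - 1L, probability = as.numeric(row[ord]))
  out <- list(doc_id = doc_id, ranked = ranked, dominant = ranked[1L, ])
  class(out) <- "topic_mix"
  out
}

#' @export
print.topic_mix <- function(x, ...) {
  cat(sprintf("<topic_mix> document %s, dominant topic %d (%.4f)\n",
              x$doc_id, x$dominant$topic, x$dominant$probability))
  print(transform(x$ranked, probability = round(probability, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Recommend a medical specialist for a free-text query
#'
#' The query is preprocessed, mapped to the model vocabulary and folded
#' in; topics are ranked by posterior probability and the top topic's
#' human label is the recommended specialty. The full ranked label list
#' is returned so callers can surface top-n suggestions. Queries with no
#' in-vocabulary token yield a typed abstention.
#' [recommend_specialist()] and [classify_unseen()] share the same
#' inference path, so they agree on the predicted topic for identical
#' seeds.
#'
#' @inheritParams classify_unseen
#' @param query Free-text patient query.
#' @return An object of class `recommendation`: list with `query_text`,
#'   `status` (`"ok"`/`"abstain"`) and, when ok, `predicted_topic`,
#'   `predicted_label`, `score` (the top probability) and `ranked`
#'   (data frame `topic`, `label`, `probability`, descending).
#' @export
recommend_specialist <- function(model, labels, query,
                                 stopwords = character(0), min_len = 3L,
                                 fold_iterations = 100L, seed = NULL) {
  check_label_map(labels, model$config$K)
  theta <- infer_query_theta(model, query, stopwords, min_len,
                             fold_iterations, seed)
  if (is.null(theta)) {
    out <- list(query_text = query, status = "abstain")
    class(out) <- "recommendation"
    return(out)
  }
  K <- length(theta)
  ord <- order(-theta, seq_len(K))
  ranked <- data.frame(topic = ord - 1L,
                       label = unname(unclass(labels)[as.character(ord - 1L)]),
                       probability = as.numeric(theta[ord]),
                       stringsAsFactors = FALSE)
  out <- list(query_text = query, status = "ok",
              predicted_topic = ranked$topic[1L],
              predicted_label = ranked$label[1L],
              score = ranked$probability[1L],
              ranked = ranked)
  class(out) <- "recommendation"
  out
}

#' @export
print.recommendation <- function(x, ...) {
  if (x$status == "abstain") {
    cat("<recommendation> abstained: query has no in-vocabulary tokens\n")
  } else {
    cat(sprintf("<recommendation> %s (topic %d, score %.4f)\n",
                x$predicted_label, x$predicted_topic, x$score))
    print(transform(x$ranked, probability = round(probability, 4)),
          row.names = FALSE)
  }
  invisible(x)
}
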