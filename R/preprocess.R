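#' Split raw text into word tokens
#'
#' Words in Afaan Oromo (Qubee orthography) are separated by blanks;
#' commas, quotation marks, semicolons and periods also act as separators.
#' The apostrophe (hudhaa) is word-internal and never splits a token.
#'
#' @param text A single character string (may be empty).
#' @return Character vector of tokens in their original order; `character(0)`
#'   for empty input.
#' @examples
#' tokenize("mataa keessaan dhiita\u2019ee ba\u2019e, bakki sun diimatee ni guba")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  out <- strsplit(text, "[\\s,;.\"\u201c\u201d]+", perl = TRUE)[[1L]]
  out[nzchar(out)]
}

#' Lowercase every token
#'
#' Topic models are frequency-based and case-sensitive; "dhukkuba" and
#' "DHUKKUBA" are the same word and must share one vocabulary entry.
#'
#' @param tokens Character vector.
#' @return Character vector of the same length, all lowercase.
#' @export
lowercase_fold <- function(tokens) tolower(tokens)

# characters deleted from tokens: brackets, punctuation and symbols;
# the apostrophe is deliberately absent (word-internal in Qubee).
.removal_class <- "[][,:.\";/~!@#%^$*&()\u201c\u201d]"

#' Strip special characters from tokens
#'
#' Deletes brackets, punctuation and symbol characters from each token.
#' The typographic apostrophe U+2019 is normalized to the ASCII single
#' quote U+0027 and retained, since the hudhaa is phonemic in Afaan Oromo.
#' Tokens that become empty are dropped.
#'
#' @param tokens Character vector.
#' @return Character vector of cleaned, non-empty tokens.
#' @examples
#' remove_special_chars(c("(guba)", "ba\u2019e,"))
#' @export
remove_special_chars <- function(tokens) {
  x <- gsub("\u2019", "'", tokens, fixed = TRUE)
  x <- gsub(.removal_class, "", x, perl = TRUE)
  x[nzchar(x)]
}

#' Remove stop-words from a token sequence
#'
#' @param tokens Character vector, already lowercased.
#' @param stopwords Character vector of lowercase stop-words.
#' @return Tokens not present in `stopwords`, order preserved.
#' @export
remove_stopwords <- function(tokens, stopwords = character(0)) {
  tokens[!(tokens %in% stopwords)]
}

#' Drop tokens shorter than a minimum length
#'
#' Very short tokens in Afaan Oromo are almost exclusively clitics and
#' function fragments; the default keeps tokens of three or more
#' characters (the apostrophe counts as a character).
#'
#' @param tokens Character vector.
#' @param min_len Minimum number of characters to keep (default 3).
#' @return Tokens with `nchar(token) >= min_len`.
#' @export
filter_short_tokens <- function(tokens, min_len = 3L) {
  stopifnot(min_len >= 1L)
  tokens[nchar(tokens) >= min_len]
}

#' Full preprocessing pipeline for one document
#'
#' Applies, in order: tokenization, special-character removal (with
#' apostrophe normalization), lowercasing, stop-word removal and
#' short-token filtering. Emits a warning when the result is empty, since
#' empty documents are excluded from model training.
#'
#' @param text A single character string.
#' @param stopwords Character vector of lowercase stop-words
#'   (default: none; see [default_stopwords()] for the packaged list).
#' @param min_len Minimum token length to keep (default 3).
#' @param drop_numeric_tokens If `TRUE`, tokens consisting only of digits
#'   are removed (default `FALSE`: the separator and removal rules contain
#'   no digits, so numerals survive unless asked for).
#' @return Character vector of cleaned tokens.
#' @examples
#' preprocess_pipeline("Mataa koo na bowwaafata, nan yaadda\u2019a",
#'                     stopwords = c("koo", "na", "nan"))
#' @export
preprocess_pipeline <- function(text, stopwords = character(0), min_len = 3L,
                                drop_numeric_tokens = FALSE) {
  toks <- tokenize(text)
  toks <- remove_special_chars(toks)
  toks <- lowercase_fold(toks)
  toks <- remove_stopwords(toks, stopwords)
  toks <- filter_short_tokens(toks, min_len)
  if (drop_numeric_tokens) toks <- toks[!grepl("^[0-9]+$", toks)]
  if (length(toks) == 0L && nzchar(trimws(text)))
    warning("document is empty after preprocessing and will be excluded from training",
            call. = FALSE)
  toks
}

#' Preprocess a whole corpus
#'
#' @param corpus Data frame with columns `doc_id` and `text`
#'   (as returned by [read_corpus()] or [fixture_table1()]).
#' @param ... Passed on to [preprocess_pipeline()].
#' @param drop_empty If `TRUE` (default) documents that are empty after
#'   cleaning are removed, with one warning listing their ids.
#' @return Named list of token vectors; names are the document ids of the
#'   retained documents.
#' @export
preprocess_corpus <- function(corpus, ..., drop_empty = TRUE) {
  stopifnot(is.data.frame(corpus), all(c("doc_id", "text") %in% names(corpus)))
  toks <- lapply(corpus$text, function(txt)
    suppressWarnings(preprocess_pipeline(txt, ...)))
  names(toks) <- as.character(corpus$doc_id)
  if (drop_empty) {
    empty <- lengths(toks) == 0L
    if (any(empty)) {
      warning(sprintf("excluding %d empty document(s) after preprocessing: %s",
                      sum(empty), paste(corpus$doc_id[empty], collapse = ", ")),
              call. = FALSE)
      toks <- toks[!empty]
    }
  }
  toks
}

#' Read a one-document-per-line corpus file
#'
#' @param path UTF-8 text file, one document per line; the 1-based line
#'   number becomes the document id.
#' @return Data frame with columns `doc_id` (integer) and `text`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  data.frame(doc_id = seq_along(lines), text = lines, stringsAsFactors = FALSE)
}

#' Read a stop-word file
#'
#' One token per line; blank lines and lines starting with `#` are
#' ignored; entries are lowercased and de-duplicated.
#'
#' @param path UTF-8 text file.
#' @return Character vector of lowercase stop-words.
#' @export
read_stopwords <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(tolower(lines))
}

#' Packaged default Afaan Oromo stop-word list
#'
#' A small list of common function words (conjunctions, pronouns,
#' demonstratives). It is a starting point, not a linguistic authority:
#' pass your own list to any function that accepts `stopwords`.
#'
#' @return Character vector of lowercase stop-words.
#' @export
default_stopwords <- function() {
  read_stopwords(system.file("extdata", "stopwords_om.txt",
                             package = "oromotopics", mustWork = TRUE))
}
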