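#' Construct a quote corpus
#'
#' A corpus is the fixed set of numbered quotes that every rater sorts; the
#' quotes become the nodes of the co-occurrence network. Ids are 1-based
#' positive integers (study quotes are typically labelled 1..N) and must be
#' unique.
#'
#' @param quote_id Integer vector of unique positive quote ids.
#' @param text Character vector of quote texts (recycled "" if omitted).
#' @param source_tag Optional character vector tagging each quote's origin
#'   (e.g. survey vs reflective journal); `NA` where unknown.
#' @return A `data.frame` of class `pte_corpus` with columns `quote_id`,
#'   `text`, `source_tag`, ordered by `quote_id`.
#' @examples
#' quote_corpus(1:3, text = c("a", "b", "c"))
#' @export
quote_corpus <- function(quote_id, text = NULL, source_tag = NULL) {
  quote_id <- parse_quote_id(quote_id)
  if (anyDuplicated(quote_id)) {
    pte_stop("duplicate quote_id in corpus", "pte_format_error")
  }
  n <- length(quote_id)
  text <- as.character(text %||% rep("", n))
  source_tag <- as.character(source_tag %||% rep(NA_character_, n))
  stopifnot(length(text) == n, length(source_tag) == n)
  ord <- order(quote_id)
  out <- data.frame(
    quote_id = quote_id[ord], text = text[ord], source_tag = source_tag[ord],
    stringsAsFactors = FALSE
  )
  class(out) <- c("pte_corpus", "data.frame")
  out
}

#' Read a quote corpus from CSV
#'
#' Expects a UTF-8 CSV with header `quote_id,text,source_tag` (the
#' `source_tag` column is optional).
#'
#' @param path Path to the corpus CSV.
#' @return A [quote_corpus()] data frame.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    pte_stop(sprintf("corpus file not found: %s", path), "pte_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("quote_id", "text")) {
    if (!col %in% names(df)) {
      pte_stop(sprintf("corpus file is missing required column %s", dQuote(col)),
               "pte_format_error")
    }
  }
  quote_corpus(
    parse_quote_id(df$quote_id),
    text = df$text,
    source_tag = if ("source_tag" %in% names(df)) df$source_tag else NULL
  )
}

#' Write a quote corpus to CSV
#'
#' @param corpus A [quote_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  utils::write.csv(as.data.frame(corpus), path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.pte_corpus <- function(x, ...) {
  cat(sprintf("Quote corpus: %d quotes (ids %d..%d)\n",
              nrow(x), min(x$quote_id), max(x$quote_id)))
  invisible(x)
}
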