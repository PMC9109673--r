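#' Construct a single rater's sort
#'
#' One rater's partition of quote ids into self-labelled groups. Group labels
#' are rater-scoped strings: "Grp1" from rater A and "Grp1" from rater B are
#' unrelated. A rater may leave quotes unassigned (the study protocol does not
#' force completeness); unassigned quotes simply do not appear in
#' `assignment`.
#'
#' @param rater_id Non-empty string identifying the rater.
#' @param assignment Named character vector mapping quote id (names, coercible
#'   to positive integers) to group label; or a data.frame with columns
#'   `quote_id` and `group_label`.
#' @return An object of class `pte_rater_sort` with elements `rater_id`,
#'   `assignment` (named character vector sorted by quote id) and `n_groups`.
#' @examples
#' rater_sort("A", c(`1` = "g1", `2` = "g1", `3` = "g2"))
#' @export
rater_sort <- function(rater_id, assignment) {
  rater_id <- as.character(rater_id)
  if (length(rater_id) != 1L || is.na(rater_id) || !nzchar(rater_id)) {
    pte_stop("rater_id must be a single non-empty string", "pte_format_error")
  }
  if (is.data.frame(assignment)) {
    assignment <- stats::setNames(as.character(assignment$group_label),
                                  assignment$quote_id)
  }
  ids <- parse_quote_id(names(assignment) %||% character())
  labels <- as.character(assignment)
  if (length(labels) && any(is.na(labels) | !nzchar(labels))) {
    pte_stop("group labels must be non-empty strings", "pte_format_error")
  }
  if (anyDuplicated(ids)) {
    pte_stop(sprintf("rater %s assigns a quote more than once", rater_id),
             "pte_duplicate_error")
  }
  ord <- order(ids)
  assignment <- stats::setNames(labels[ord], ids[ord])
  structure(
    list(rater_id = rater_id, assignment = assignment,
         n_groups = length(unique(labels))),
    class = "pte_rater_sort"
  )
}

#' Groups of a rater sort
#'
#' @param sort A [rater_sort()].
#' @return Named list mapping group label to the integer quote ids it holds.
#' @export
sort_groups <- function(sort) {
  ids <- as.integer(names(sort$assignment))
  lapply(split(ids, sort$assignment), sort)
}

#' @export
print.pte_rater_sort <- function(x, ...) {
  cat(sprintf("Rater sort %s: %d quotes in %d groups\n",
              dQuote(x$rater_id), length(x$assignment), x$n_groups))
  invisible(x)
}

#' Bundle a corpus and rater sorts into a sort study
#'
#' @param corpus A [quote_corpus()].
#' @param sorts List of [rater_sort()] objects with distinct rater ids.
#' @return Object of class `pte_study`: `corpus`, `sorts` (named by rater id),
#'   `n_raters`.
#' @export
sort_study <- function(corpus, sorts) {
  stopifnot(inherits(corpus, "pte_corpus"))
  if (!is.list(sorts) || !all(vapply(sorts, inherits, TRUE, "pte_rater_sort"))) {
    pte_stop("sorts must be a list of rater_sort objects", "pte_format_error")
  }
  rater_ids <- vapply(sorts, function(s) s$rater_id, "")
  if (anyDuplicated(rater_ids)) {
    pte_stop("rater ids must be distinct within a study", "pte_duplicate_error")
  }
  names(sorts) <- rater_ids
  structure(
    list(corpus = corpus, sorts = sorts, n_raters = length(sorts)),
    class = "pte_study"
  )
}

#' @export
print.pte_study <- function(x, ...) {
  cat(sprintf("Sort study: %d quotes, %d raters\n",
              nrow(x$corpus), x$n_raters))
  invisible(x)
}

# Resolve the three study columns in a raw table, honouring user aliases and
# the Topic/Person/Group names used when sorts are transcribed from a
# whiteboard into a spreadsheet.
resolve_sort_columns <- function(nms, aliases) {
  canonical <- c(quote_id = "quote_id", rater_id = "rater_id",
                 group_label = "group_label")
  fallback <- c(quote_id = "Topic", rater_id = "Person", group_label = "Group")
  if (!is.null(aliases)) canonical[names(aliases)] <- aliases
  out <- character(3)
  names(out) <- names(canonical)
  for (k in names(canonical)) {
    if (canonical[[k]] %in% nms) {
      out[[k]] <- canonical[[k]]
    } else if (is.null(aliases) && fallback[[k]] %in% nms) {
      out[[k]] <- fallback[[k]]
    } else {
      pte_stop(sprintf("sort table is missing required column %s",
                       dQuote(canonical[[k]])), "pte_format_error")
    }
  }
  out
}

#' Read rater sorts from a three-column long-format CSV
#'
#' The canonical layout has header `quote_id,rater_id,group_label`; the
#' spreadsheet-transcription names `Topic,Person,Group` are recognised
#' automatically, and arbitrary header names can be supplied via `aliases`.
#' Rows are grouped by rater; group labels are kept verbatim as strings.
#'
#' @param path Path to the CSV file.
#' @param aliases Optional named character vector renaming any of
#'   `quote_id`, `rater_id`, `group_label` to the header actually used, e.g.
#'   `c(quote_id = "Topic", rater_id = "Person", group_label = "Group")`.
#' @return Named list of [rater_sort()] objects, in order of first appearance.
#' @export
read_sort_table <- function(path, aliases = NULL) {
  if (!file.exists(path)) {
    pte_stop(sprintf("sort table not found: %s", path), "pte_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  cols <- resolve_sort_columns(names(df), aliases)
  qid <- parse_quote_id(df[[cols[["quote_id"]]]], context = "quote id")
  rid <- as.character(df[[cols[["rater_id"]]]])
  grp <- as.character(df[[cols[["group_label"]]]])
  if (nrow(df) && any(is.na(rid) | !nzchar(rid))) {
    pte_stop("empty rater_id in sort table", "pte_format_error")
  }
  if (nrow(df) && any(is.na(grp) | !nzchar(grp))) {
    pte_stop("empty group_label in sort table", "pte_format_error")
  }
  # duplicate (quote, rater) rows: identical group is tolerated, a conflict
  # is a transcription error and names the offending row.
  key <- paste(qid, rid, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    for (i in which(dup)) {
      first <- match(key[i], key)
      if (grp[first] != grp[i]) {
        pte_stop(sprintf(
          "row %d: quote %d already assigned by rater %s to group %s (conflicts with %s)",
          i + 1L, qid[i], dQuote(rid[i]), dQuote(grp[first]), dQuote(grp[i])),
          "pte_duplicate_error")
      }
    }
    qid <- qid[!dup]; rid <- rid[!dup]; grp <- grp[!dup]
  }
  out <- list()
  for (r in unique(rid)) {
    sel <- rid == r
    out[[r]] <- rater_sort(r, stats::setNames(grp[sel], qid[sel]))
  }
  out
}

#' Write rater sorts to the canonical long-format CSV
#'
#' Inverse of [read_sort_table()]: `read_sort_table(write_sort_table(x, p))`
#' reproduces `x` exactly, including labels containing commas or quotes.
#'
#' @param sorts List of [rater_sort()] objects (or a `pte_study`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sort_table <- function(sorts, path) {
  if (inherits(sorts, "pte_study")) sorts <- sorts$sorts
  if (inherits(sorts, "pte_rater_sort")) sorts <- list(sorts)
  rows <- do.call(rbind, lapply(sorts, function(s) {
    data.frame(quote_id = as.integer(names(s$assignment)),
               rater_id = s$rater_id,
               group_label = unname(s$assignment),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(quote_id = integer(), rater_id = character(),
                       group_label = character())
  }
  ok <- tryCatch({
    utils::write.csv(rows, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) pte_stop(sprintf("cannot write sort table to %s", path), "pte_io_error")
  invisible(path)
}

#' Validate a sort study
#'
#' Produces a findings table rather than failing: unknown quote ids are
#' errors, quotes a rater left unassigned are warnings (or errors when
#' `require_complete = TRUE`). The caller decides how to act.
#'
#' @param study A [sort_study()].
#' @param require_complete If `TRUE`, every rater must assign every corpus
#'   quote; unassigned quotes are reported at error level.
#' @return A data frame of class `pte_validation` with columns `level`
#'   (`"error"`/`"warning"`), `rater_id`, `quote_id`, `message`. Zero rows
#'   means the study is clean.
#' @export
validate_study <- function(study, require_complete = FALSE) {
  stopifnot(inherits(study, "pte_study"))
  corpus_ids <- study$corpus$quote_id
  findings <- list()
  add <- function(level, rater, quote, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, rater_id = rater, quote_id = quote, message = msg,
      stringsAsFactors = FALSE)
  }
  for (s in study$sorts) {
    ids <- as.integer(names(s$assignment))
    unknown <- setdiff(ids, corpus_ids)
    for (q in unknown) {
      add("error", s$rater_id, q,
          sprintf("rater %s assigns quote %d which is not in the %d-quote corpus",
                  s$rater_id, q, length(corpus_ids)))
    }
    missing <- setdiff(corpus_ids, ids)
    for (q in missing) {
      add(if (require_complete) "error" else "warning", s$rater_id, q,
          sprintf("rater %s left quote %d unassigned", s$rater_id, q))
    }
  }
  out <- if (length(findings)) do.call(rbind, findings) else
    data.frame(level = character(), rater_id = character(),
               quote_id = integer(), message = character(),
               stringsAsFactors = FALSE)
  attr(out, "n_quotes") <- length(unique(corpus_ids))
  attr(out, "n_raters") <- study$n_raters
  class(out) <- c("pte_validation", "data.frame")
  out
}

#' @export
print.pte_validation <- function(x, ...) {
  cat(sprintf("Study validation: %d quotes, %d raters, %d finding(s)\n",
              attr(x, "n_quotes"), attr(x, "n_raters"), nrow(x)))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}
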