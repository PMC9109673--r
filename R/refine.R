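# Theme sets and documented post-hoc refinement. Community detection gives a
# starting grouping; the analysis-and-interpretation session may rename
# groups, move quotes, or create new themes, and every such action is kept in
# an ordered provenance trail with its rationale.

#' Construct a theme set
#'
#' @param themes Named list mapping theme label to an integer vector of quote
#'   ids; the themes must partition the assigned quotes (no overlaps).
#' @param provenance Ordered list of refinement actions already applied (see
#'   [refinement_action()]).
#' @return Object of class `pte_themes`.
#' @export
theme_set <- function(themes, provenance = list()) {
  if (is.null(names(themes)) || anyDuplicated(names(themes)) ||
      any(!nzchar(names(themes)))) {
    pte_stop("theme labels must be unique non-empty strings", "pte_format_error")
  }
  all_ids <- unlist(themes, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    pte_stop("themes must partition the quote set: a quote appears twice",
             "pte_format_error")
  }
  themes <- lapply(themes, function(v) sort(as.integer(v)))
  structure(list(themes = themes, provenance = provenance),
            class = "pte_themes")
}

#' Theme membership as a named vector
#'
#' @param themes A `pte_themes`.
#' @return Named character vector quote id -> theme label, sorted by id.
#' @export
themes_assignment <- function(themes) {
  labs <- rep(names(themes$themes), lengths(themes$themes))
  ids <- unlist(themes$themes, use.names = FALSE)
  ord <- order(ids)
  stats::setNames(labs[ord], ids[ord])
}

#' Convert a consensus partition to a theme set
#'
#' Communities become themes labelled `"Group 1"` .. `"Group K"` in the
#' partition's stable community order.
#'
#' @param partition A `pte_partition`.
#' @return A `pte_themes` with empty provenance.
#' @export
as_theme_set <- function(partition) {
  stopifnot(inherits(partition, "pte_partition"))
  ids <- as.integer(names(partition$assignment))
  themes <- lapply(split(ids, partition$assignment), sort)
  names(themes) <- paste("Group", names(themes))
  theme_set(themes)
}

#' @export
print.pte_themes <- function(x, ...) {
  cat(sprintf("Theme set: %d themes over %d quotes (%d refinement action(s))\n",
              length(x$themes), length(unlist(x$themes)), length(x$provenance)))
  for (lab in names(x$themes)) {
    cat(sprintf("  %s: %d quotes\n", lab, length(x$themes[[lab]])))
  }
  invisible(x)
}

#' Record one refinement action
#'
#' @param type One of `"create_theme"`, `"move_quote"`, `"rename_theme"`.
#' @param label New theme label (`create_theme`).
#' @param quote_id Quote to relocate (`move_quote`).
#' @param to Destination theme label (`move_quote`).
#' @param from,to_label Old and new labels (`rename_theme`; `to_label`
#'   defaults to `label`).
#' @param rationale Free-text reason recorded in provenance.
#' @return A list of class `pte_refinement_action`.
#' @export
refinement_action <- function(type = c("create_theme", "move_quote", "rename_theme"),
                              label = NULL, quote_id = NULL, to = NULL,
                              from = NULL, to_label = NULL, rationale = "") {
  type <- match.arg(type)
  act <- switch(type,
    create_theme = {
      if (is.null(label)) pte_stop("create_theme needs a label", "pte_usage_error")
      list(type = type, label = as.character(label))
    },
    move_quote = {
      if (is.null(quote_id) || is.null(to)) {
        pte_stop("move_quote needs quote_id and to", "pte_usage_error")
      }
      list(type = type, quote_id = parse_quote_id(quote_id), to = as.character(to))
    },
    rename_theme = {
      if (is.null(from)) pte_stop("rename_theme needs from", "pte_usage_error")
      new_lab <- to_label %||% label
      if (is.null(new_lab)) pte_stop("rename_theme needs to_label", "pte_usage_error")
      list(type = type, from = as.character(from), to = as.character(new_lab))
    })
  act$rationale <- as.character(rationale)
  class(act) <- "pte_refinement_action"
  act
}

#' Apply documented refinement actions to a detected partition
#'
#' Starts from the communities of `base` (labelled `"Group 1..K"`), applies
#' the actions in order, and returns the refined theme set with full
#' provenance. When a move empties a theme the theme is dropped unless
#' `retain_empty = TRUE` (so a deliberately kept empty theme is visible in
#' reports). If `net` is supplied, the modularity of the refined grouping is
#' recomputed and attached as attribute `"modularity"` — it may be lower than
#' the detected optimum, since refinement is human-led.
#'
#' @param base A `pte_partition` (or an existing `pte_themes` to refine
#'   further).
#' @param actions List of [refinement_action()] objects.
#' @param net Optional `pte_network` for modularity recomputation.
#' @param retain_empty Keep themes that refinement emptied.
#' @return A `pte_themes`; provenance lists every action in order.
#' @examples
#' part <- structure(list(assignment = c(`1`=1L, `2`=1L, `3`=2L, `4`=2L)),
#'                   class = "pte_partition")
#' apply_refinement(part, list(
#'   refinement_action("create_theme", label = "Future Courses"),
#'   refinement_action("move_quote", quote_id = 4, to = "Future Courses")))
#' @export
apply_refinement <- function(base, actions = list(), net = NULL,
                             retain_empty = FALSE) {
  themes <- if (inherits(base, "pte_themes")) base$themes
            else as_theme_set(base)$themes
  provenance <- if (inherits(base, "pte_themes")) base$provenance else list()
  for (act in actions) {
    if (!inherits(act, "pte_refinement_action")) {
      pte_stop("actions must be built with refinement_action()", "pte_usage_error")
    }
    if (act$type == "create_theme") {
      if (act$label %in% names(themes)) {
        pte_stop(sprintf("theme %s already exists", dQuote(act$label)),
                 "pte_reference_error")
      }
      themes[[act$label]] <- integer()
    } else if (act$type == "move_quote") {
      if (!act$to %in% names(themes)) {
        pte_stop(sprintf("unknown destination theme %s (create it first)",
                         dQuote(act$to)), "pte_reference_error")
      }
      cur <- NULL
      for (lab in names(themes)) {
        if (act$quote_id %in% themes[[lab]]) { cur <- lab; break }
      }
      if (is.null(cur)) {
        pte_stop(sprintf("quote %d is not in any theme", act$quote_id),
                 "pte_reference_error")
      }
      if (cur != act$to) {
        themes[[cur]] <- setdiff(themes[[cur]], act$quote_id)
        themes[[act$to]] <- sort(c(themes[[act$to]], act$quote_id))
        if (!length(themes[[cur]]) && !retain_empty) {
          themes[[cur]] <- NULL
        }
      }
    } else { # rename_theme
      if (!act$from %in% names(themes)) {
        pte_stop(sprintf("unknown theme %s", dQuote(act$from)),
                 "pte_reference_error")
      }
      if (act$to %in% names(themes)) {
        pte_stop(sprintf("theme %s already exists", dQuote(act$to)),
                 "pte_reference_error")
      }
      names(themes)[names(themes) == act$from] <- act$to
    }
    provenance[[length(provenance) + 1L]] <- act
  }
  out <- theme_set(themes, provenance)
  if (!is.null(net)) {
    attr(out, "modularity") <- modularity_q(themes_assignment(out), net)
  }
  out
}

#' Serialise a theme set to JSON
#'
#' Writes themes, provenance and (when available) modularity, resolution and
#' seed, so a refined grouping is fully reproducible from the file.
#'
#' @param themes A `pte_themes`.
#' @param path Output path.
#' @param partition Optional `pte_partition` whose Q, resolution and seed are
#'   echoed.
#' @return `path`, invisibly.
#' @export
write_themes_json <- function(themes, path, partition = NULL) {
  payload <- list(
    themes = themes$themes,
    provenance = lapply(themes$provenance, unclass)
  )
  if (!is.null(attr(themes, "modularity"))) {
    payload$refined_modularity <- attr(themes, "modularity")
  }
  if (!is.null(partition)) {
    payload$detected <- list(modularity = partition$modularity,
                             resolution = partition$resolution,
                             seed = partition$seed,
                             n_communities = partition$n_communities)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
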