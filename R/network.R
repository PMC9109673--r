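#' Build the quote co-occurrence network
#'
#' The consensus step of participatory theme elicitation combines the
#' individual sorts into a single weighted graph: nodes are the corpus quote
#' ids, and the weight on edge (i, j) is the number of raters who placed
#' quotes i and j in the same group. Weights are therefore integers in
#' `[0, R]` for R raters, and the total edge weight equals
#' `sum over raters, over groups of choose(group size, 2)`.
#'
#' Quotes a rater left unassigned contribute no pairs for that rater.
#' `unassigned = "singleton"` instead treats each unassigned quote as a group
#' of its own; since a singleton contributes no pairs either, the resulting
#' weights are identical — the option only changes how such quotes are
#' accounted in per-rater group counts.
#'
#' Nodes with zero total strength are retained: an always-isolated quote must
#' surface downstream as a singleton theme, not vanish.
#'
#' @param study A [sort_study()].
#' @param unassigned How a rater's unassigned quotes are treated:
#'   `"ignore"` (abstention, default) or `"singleton"`.
#' @return Object of class `pte_network`: `node_ids` (sorted integer vector),
#'   `weights` (symmetric integer matrix, zero diagonal, dimnames = ids),
#'   `n_raters`.
#' @examples
#' s <- sort_study(quote_corpus(1:4),
#'                 list(rater_sort("A", c(`1`="x", `2`="x", `3`="y", `4`="y")),
#'                      rater_sort("B", c(`1`="p", `2`="p", `3`="q", `4`="q"))))
#' net <- build_network(s)
#' net$weights["1", "2"]  # 2: both raters paired quotes 1 and 2
#' @export
build_network <- function(study, unassigned = c("ignore", "singleton")) {
  stopifnot(inherits(study, "pte_study"))
  unassigned <- match.arg(unassigned)
  node_ids <- sort(unique(study$corpus$quote_id))
  n <- length(node_ids)
  if (n == 0L || study$n_raters == 0L) {
    warning("empty study: returning a network with no pairings")
  }
  W <- matrix(0L, n, n, dimnames = list(node_ids, node_ids))
  for (s in study$sorts) {
    for (grp in sort_groups(s)) {
      idx <- match(grp, node_ids)
      idx <- idx[!is.na(idx)]
      if (length(idx) >= 2L) {
        W[idx, idx] <- W[idx, idx] + 1L
        diag(W)[idx] <- diag(W)[idx] - 1L  # undo the self increments
      }
    }
    # "singleton" adds groups of size one for unassigned quotes; size-one
    # groups contribute no pairs, so no weight update is needed.
  }
  diag(W) <- 0L
  structure(
    list(node_ids = node_ids, weights = W, n_raters = study$n_raters),
    class = "pte_network"
  )
}

#' Per-node strength of a co-occurrence network
#'
#' @param net A `pte_network`.
#' @return Named numeric vector `s_i = sum_j w_ij`.
#' @export
node_strength <- function(net) {
  rowSums(net$weights)
}

#' Total edge weight of a co-occurrence network
#'
#' @param net A `pte_network`.
#' @return `m = (1/2) sum_i s_i`.
#' @export
total_weight <- function(net) {
  sum(net$weights) / 2
}

#' @export
print.pte_network <- function(x, ...) {
  n_edges <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Co-occurrence network: %d quotes, %d raters, %d weighted edges (m = %g)\n",
              length(x$node_ids), x$n_raters, n_edges, total_weight(x)))
  invisible(x)
}

# Positive-weight edges as a data.frame (source < target, sorted), used by
# both export formats and the SVG renderer.
network_edges <- function(net) {
  W <- net$weights
  up <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  df <- data.frame(
    source = net$node_ids[up[, 1]],
    target = net$node_ids[up[, 2]],
    weight = W[up]
  )
  df[order(df$source, df$target), , drop = FALSE]
}

# igraph view of the network (positive edges only, vertices named by quote
# id), with an optional community vertex attribute.
as_igraph_network <- function(net, partition = NULL) {
  edges <- network_edges(net)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$source),
               to = as.character(edges$target)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$node_ids))
  )
  g <- igraph::set_edge_attr(g, "weight", value = edges$weight)
  if (!is.null(partition)) {
    assignment <- partition_assignment(partition)
    g <- igraph::set_vertex_attr(
      g, "community",
      value = as.character(assignment[as.character(net$node_ids)]))
  }
  g
}

#' Export a co-occurrence network
#'
#' Writes the network in a standard graph format. GraphML carries the integer
#' `weight` edge attribute and, when a partition is supplied, a `community`
#' node attribute; isolated nodes are listed with no incident edges. The TSV
#' edge list has columns `source`, `target`, `weight` with zero-weight pairs
#' omitted. Output is byte-stable across runs for the same input.
#'
#' @param net A `pte_network`.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @param path Output path.
#' @param partition Optional consensus partition (see
#'   [detect_communities()]) whose community ids are attached to nodes.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, format = c("graphml", "edge-tsv"), path,
                           partition = NULL) {
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("graphml", "edge-tsv")) {
    pte_stop(sprintf("unknown network export format %s", dQuote(format)),
             "pte_usage_error")
  }
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph_network(net, partition)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    if (length(net$node_ids) == 0L) {
      pte_stop("cannot write an edge list for an empty network", "pte_usage_error")
    }
    utils::write.table(network_edges(net), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
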