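# Deterministic force-directed layout for network diagrams: node proximity
# reflects co-sorting strength, edge width the number of raters pairing the
# two quotes, and node colour the detected community.

# fixed qualitative palette (12 colours), indexed by community id modulo 12
pte_palette <- c(
  "#e6194b", "#3cb44b", "#ffe119", "#4363d8", "#f58231", "#911eb4",
  "#46f0f0", "#f032e6", "#bcf60c", "#fabebe", "#008080", "#e6beff"
)

#' Seeded force-directed layout of a co-occurrence network
#'
#' Fruchterman-Reingold layout with edge attraction proportional to the
#' co-occurrence weight, computed under a fixed seed so coordinates are
#' identical across runs for the same `(network, seed)`. A single-node
#' network is placed at the origin. Each node carries a colour index: its
#' community id mapped onto a fixed 12-colour palette.
#'
#' @param net A `pte_network` with at least one node.
#' @param partition Optional `pte_partition`; without it all nodes share
#'   community 1.
#' @param seed Integer seed.
#' @return Object of class `pte_layout`: a data frame with columns
#'   `quote_id`, `x`, `y`, `community`, `colour_index`, plus attribute
#'   `"edges"` (source, target, weight = line width).
#' @export
compute_layout <- function(net, partition = NULL, seed = 1L) {
  stopifnot(inherits(net, "pte_network"))
  n <- length(net$node_ids)
  if (n < 1L) pte_stop("cannot lay out an empty network", "pte_usage_error")
  comm <- if (is.null(partition)) {
    stats::setNames(rep(1L, n), as.character(net$node_ids))
  } else {
    partition_assignment(partition)
  }
  if (n == 1L) {
    coords <- matrix(0, 1, 2)
  } else {
    g <- as_igraph_network(net)
    coords <- with_rng_seed(seed, {
      igraph::layout_with_fr(g, weights = igraph::E(g)$weight, niter = 500)
    })
  }
  community <- as.integer(comm[as.character(net$node_ids)])
  out <- data.frame(
    quote_id = net$node_ids,
    x = coords[, 1], y = coords[, 2],
    community = community,
    colour_index = ((community - 1L) %% length(pte_palette)) + 1L
  )
  attr(out, "edges") <- network_edges(net)
  class(out) <- c("pte_layout", "data.frame")
  out
}

#' Write a network diagram as SVG
#'
#' Renders the layout as a plain-text SVG: edges as lines with width
#' proportional to weight, nodes as palette-coloured circles labelled with
#' the quote id. The output is byte-stable for a fixed layout.
#'
#' @param layout A [compute_layout()] result.
#' @param path Output path.
#' @param size Canvas size in pixels (square).
#' @return `path`, invisibly.
#' @export
write_layout_svg <- function(layout, path, size = 800) {
  stopifnot(inherits(layout, "pte_layout"))
  pad <- 40
  rng_x <- range(layout$x); rng_y <- range(layout$y)
  scale_to <- function(v, rng) {
    if (diff(rng) < 1e-12) rep(size / 2, length(v))
    else pad + (v - rng[1]) / diff(rng) * (size - 2 * pad)
  }
  px <- scale_to(layout$x, rng_x)
  py <- scale_to(layout$y, rng_y)
  names(px) <- names(py) <- as.character(layout$quote_id)
  edges <- attr(layout, "edges")
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            size, size, size, size),
    '<rect width="100%" height="100%" fill="white"/>'
  )
  if (!is.null(edges) && nrow(edges)) {
    lines <- c(lines, sprintf(
      '<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#999999" stroke-width="%.2f" stroke-opacity="0.6"/>',
      px[as.character(edges$source)], py[as.character(edges$source)],
      px[as.character(edges$target)], py[as.character(edges$target)],
      0.8 * edges$weight))
  }
  lines <- c(lines,
    sprintf('<circle cx="%.2f" cy="%.2f" r="8" fill="%s" stroke="#333333"/>',
            px, py, pte_palette[layout$colour_index]),
    sprintf('<text x="%.2f" y="%.2f" font-size="7" text-anchor="middle" dy="2">%d</text>',
            px, py, layout$quote_id),
    "</svg>")
  writeLines(lines, path)
  invisible(path)
}
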