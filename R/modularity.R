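# Weighted Newman modularity with a resolution parameter, the objective the
# consensus step maximises.

# Accept either a consensus partition object or a bare named vector
# (names = quote ids, values = community/theme labels).
partition_assignment <- function(partition) {
  if (inherits(partition, "pte_partition")) return(partition$assignment)
  if (inherits(partition, "pte_themes")) return(themes_assignment(partition))
  if (is.null(names(partition))) {
    pte_stop("partition must be named by quote id", "pte_coverage_error")
  }
  partition
}

#' Weighted modularity of a partition
#'
#' Computes `Q = sum_c [ W_c/(2m) - gamma * (S_c/(2m))^2 ]` where, for each
#' community c, `W_c` is the total weight of internal edges counted in both
#' orders, `S_c` the summed node strengths, and `m` the network's total edge
#' weight. `gamma` is the resolution: values above 1 favour more, smaller
#' communities. By convention `Q = 0` when the network has no edges (`m = 0`).
#'
#' @param partition Named vector mapping every network node (quote id) to a
#'   community label, or a consensus partition / theme set object.
#' @param net A `pte_network`.
#' @param resolution Resolution parameter `gamma` (> 0, default 1).
#' @return The real number Q.
#' @examples
#' s <- sort_study(quote_corpus(1:4),
#'                 list(rater_sort("A", c(`1`="x", `2`="x", `3`="y", `4`="y"))))
#' net <- build_network(s)
#' modularity_q(c(`1`=1, `2`=1, `3`=2, `4`=2), net)
#' @export
modularity_q <- function(partition, net, resolution = 1) {
  stopifnot(inherits(net, "pte_network"))
  if (resolution <= 0) {
    pte_stop("resolution must be > 0", "pte_parameter_error")
  }
  assignment <- partition_assignment(partition)
  keys <- as.character(net$node_ids)
  missing <- setdiff(keys, names(assignment))
  if (length(missing)) {
    pte_stop(sprintf("partition does not cover node %s", missing[1]),
             "pte_coverage_error")
  }
  two_m <- sum(net$weights)
  if (two_m == 0) return(0)
  comm <- as.character(assignment[keys])
  s <- rowSums(net$weights)
  q <- 0
  for (c_id in unique(comm)) {
    idx <- which(comm == c_id)
    W_c <- sum(net$weights[idx, idx])
    S_c <- sum(s[idx])
    q <- q + W_c / two_m - resolution * (S_c / two_m)^2
  }
  q
}

# Relabel community ids 1..K, ordered by descending size then by smallest
# member quote id, so output labelling is stable across runs and methods.
relabel_partition <- function(assignment) {
  ids <- as.integer(names(assignment))
  comm <- as.character(assignment)
  sizes <- table(comm)
  smallest <- tapply(ids, comm, min)
  labs <- names(smallest)
  ord <- order(-as.integer(sizes[labs]), smallest[labs])
  new_ids <- stats::setNames(seq_along(labs), labs[ord])
  out <- unname(new_ids[comm])
  stats::setNames(as.integer(out), names(assignment))
}

new_pte_partition <- function(assignment, net, resolution, seed, method) {
  assignment <- relabel_partition(assignment)
  structure(
    list(assignment = assignment,
         n_communities = length(unique(assignment)),
         modularity = modularity_q(assignment, net, resolution),
         resolution = resolution,
         seed = seed,
         method = method),
    class = "pte_partition"
  )
}

#' @export
print.pte_partition <- function(x, ...) {
  cat(sprintf("Consensus partition (%s): %d communities, Q = %.4f (gamma = %g, seed = %s)\n",
              x$method, x$n_communities, x$modularity, x$resolution,
              if (is.null(x$seed)) "none" else x$seed))
  sizes <- sort(table(x$assignment), decreasing = TRUE)
  cat("  sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a partition or theme set to CSV
#'
#' Writes two columns `quote_id,theme_label`.
#'
#' @param partition A consensus partition or theme set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(partition, path) {
  assignment <- partition_assignment(partition)
  df <- data.frame(quote_id = as.integer(names(assignment)),
                   theme_label = as.character(assignment),
                   stringsAsFactors = FALSE)
  df <- df[order(df$quote_id), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
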