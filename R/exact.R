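#' Globally optimal modularity partition of a small network
#'
#' Enumerates every set partition of the nodes via restricted-growth strings
#' (Bell-number enumeration) and returns one maximising weighted modularity.
#' Intended as a validation oracle for [detect_communities()]; the node count
#' is capped at 12 (Bell(12) is about 4.2 million partitions).
#'
#' The per-pair decomposition keeps the search cheap: with
#' `B_ij = 2 (w_ij - gamma s_i s_j / (2m)) / (2m)` for i != j, modularity is
#' the sum of `B_ij` over same-community pairs plus a partition-independent
#' constant `-gamma * sum_i (s_i/(2m))^2`, so only the pair sum is maximised.
#' Ties are broken towards the lexicographically smallest restricted-growth
#' string.
#'
#' @param net A `pte_network` with at most 12 nodes.
#' @param resolution Resolution `gamma` (> 0).
#' @return A `pte_partition` with `method = "exact"`.
#' @export
exact_max_modularity <- function(net, resolution = 1) {
  stopifnot(inherits(net, "pte_network"))
  if (resolution <= 0) {
    pte_stop("resolution must be > 0", "pte_parameter_error")
  }
  n <- length(net$node_ids)
  if (n < 1L) pte_stop("network has no nodes", "pte_usage_error")
  if (n > 12L) {
    pte_stop(sprintf("exact enumeration is limited to 12 nodes (got %d)", n),
             "pte_size_error")
  }
  keys <- as.character(net$node_ids)
  two_m <- sum(net$weights)
  if (two_m == 0) {
    assignment <- stats::setNames(seq_len(n), keys)
    return(new_pte_partition(assignment, net, resolution, NULL, "exact"))
  }
  s <- rowSums(net$weights)
  B <- 2 * (net$weights - resolution * outer(s, s) / two_m) / two_m
  diag(B) <- 0
  res <- exact_partition_rgs(B, 1e-12)
  assignment <- stats::setNames(res$assignment, keys)
  new_pte_partition(assignment, net, resolution, NULL, "exact")
}
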