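# Seeded two-phase greedy modularity maximisation (Louvain-style):
# repeated local node-move sweeps in seeded random order, followed by graph
# aggregation, until neither phase improves.

# One level of local moving on a (possibly aggregated) weight matrix M.
# M follows the doubled-diagonal convention: M[i, i] holds twice the
# self-loop weight, so k = rowSums(M) and 2m = sum(M) without special cases.
# Returns the community vector (ints 1..C, relabelled compactly).
louvain_level <- function(M, gamma) {
  n <- nrow(M)
  comm <- seq_len(n)
  k <- rowSums(M)
  two_m <- sum(M)
  S <- k # community strengths, indexed by community id
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      w_i <- M[i, ]
      w_i[i] <- 0
      # detach i from its community
      S[ci] <- S[ci] - k[i]
      nz <- which(w_i > 0)
      cand <- unique(c(comm[nz], ci))
      l <- vapply(cand, function(cc) sum(w_i[comm == cc]), 0)
      # gain relative to sitting alone: 2*l_ic/2m - 2*gamma*k_i*S_c/(2m)^2
      gain <- 2 * l / two_m - 2 * gamma * k[i] * S[cand] / two_m^2
      best <- max(gain)
      if (best > 1e-12) {
        # tie-break: lowest candidate community id wins
        target <- min(cand[gain >= best - 1e-12])
      } else {
        # no positive gain: stay alone (reuse own id if free, else a fresh one)
        target <- if (!any(comm[-i] == ci)) ci else max(comm) + 1L
      }
      S[target] <- (if (target <= length(S)) S[target] else 0) + k[i]
      if (target != ci) moved <- TRUE
      comm[i] <- target
    }
    if (!moved) break
  }
  match(comm, sort(unique(comm)))
}

#' Detect consensus communities in a co-occurrence network
#'
#' Two-phase greedy maximisation of weighted modularity (see
#' [modularity_q()]): local node moves are attempted in a seeded random
#' order until no move improves Q, the graph is then aggregated with
#' communities as super-nodes, and the two phases repeat until convergence.
#' The result is a pure function of `(net, resolution, seed)`; isolated
#' nodes end as singleton communities; an edgeless network returns the
#' all-singletons partition with Q = 0.
#'
#' Community ids are assigned by descending community size, ties broken by
#' smallest member quote id, so labelling is stable.
#'
#' @param net A `pte_network`.
#' @param resolution Resolution `gamma` (> 0). The default 1 is standard
#'   Newman modularity; raising it yields more, finer communities.
#' @param seed Integer seed controlling the node sweep order.
#' @return Object of class `pte_partition` with elements `assignment` (named
#'   integer vector quote id -> community), `n_communities`, `modularity`,
#'   `resolution`, `seed`, `method`.
#' @export
detect_communities <- function(net, resolution = 1, seed = 1L) {
  stopifnot(inherits(net, "pte_network"))
  if (resolution <= 0) {
    pte_stop("resolution must be > 0", "pte_parameter_error")
  }
  n <- length(net$node_ids)
  if (n < 1L) {
    pte_stop("network has no nodes", "pte_usage_error")
  }
  keys <- as.character(net$node_ids)
  if (sum(net$weights) == 0) {
    assignment <- stats::setNames(seq_len(n), keys)
    return(new_pte_partition(assignment, net, resolution, seed,
                             "greedy-two-phase"))
  }
  membership <- seq_len(n) # node -> community in original indexing
  M <- matrix(as.numeric(net$weights), n, n)
  with_rng_seed(seed, {
    repeat {
      comm <- louvain_level(M, resolution)
      membership <- comm[membership]
      C <- max(comm)
      if (C == nrow(M)) break
      # aggregate: M'[a, b] = sum of M over node pairs in communities a, b;
      # the diagonal picks up twice the internal weight, as required.
      M <- rowsum(t(rowsum(M, comm)), comm)
      dimnames(M) <- NULL
    }
  })
  assignment <- stats::setNames(membership, keys)
  new_pte_partition(assignment, net, resolution, seed, "greedy-two-phase")
}
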