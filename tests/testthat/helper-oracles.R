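# Independent oracles and small-study generators used across the suite.
# Each oracle is a brute-force/enumerative restatement of the quantity it
# checks, kept free of the package's own computational path.

# random sort study: each rater partitions 1..n into up to g groups
random_study <- function(n, n_raters, max_groups = 4, complete = TRUE) {
  corpus <- quote_corpus(seq_len(n))
  sorts <- lapply(seq_len(n_raters), function(r) {
    labels <- paste0("g", sample.int(max_groups, n, replace = TRUE))
    ids <- seq_len(n)
    if (!complete) {
      keep <- sort(sample(ids, max(1L, n - sample.int(3, 1))))
      ids <- keep; labels <- labels[keep]
    }
    rater_sort(paste0("R", r), stats::setNames(labels, ids))
  })
  sort_study(corpus, sorts)
}

# exhaustive pair-counting oracle for co-occurrence weights
brute_force_weights <- function(study) {
  ids <- sort(study$corpus$quote_id)
  n <- length(ids)
  W <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (s in study$sorts) {
    a <- s$assignment
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ki <- as.character(ids[i]); kj <- as.character(ids[j])
        if (ki %in% names(a) && kj %in% names(a) && a[[ki]] == a[[kj]]) {
          W[i, j] <- W[i, j] + 1L
          W[j, i] <- W[j, i] + 1L
        }
      }
    }
  }
  W
}

# sum over raters and groups of choose(group size, 2)
pair_budget <- function(study) {
  sum(vapply(study$sorts, function(s) {
    sum(choose(table(s$assignment), 2))
  }, numeric(1)))
}

# exhaustive search over all injective theme -> coder-group mappings
brute_force_alignment <- function(counts) {
  K <- nrow(counts); L <- ncol(counts)
  best <- -1
  cols <- seq_len(L)
  # enumerate ordered selections of min(K, L) columns assigned to a subset
  # of rows of that size
  rows_sets <- utils::combn(K, min(K, L), simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (rows in rows_sets) {
    for (p in perms(cols)[] ) {
      p <- p[seq_along(rows)]
      tot <- sum(counts[cbind(rows, p)])
      if (tot > best) best <- tot
    }
  }
  best
}

# pair-counting ARI from first principles: agreement over all quote pairs
brute_force_ari <- function(p1, p2) {
  p2 <- p2[names(p1)]
  n <- length(p1)
  same1 <- outer(p1, p1, "==")[upper.tri(diag(n))]
  same2 <- outer(p2, p2, "==")[upper.tri(diag(n))]
  a <- sum(same1 & same2); b <- sum(!same1 & !same2)
  c_ <- sum(same1 & !same2); d <- sum(!same1 & same2)
  total <- a + b + c_ + d
  expected <- (a + c_) * (a + d) / total
  maximum <- ((a + c_) + (a + d)) / 2
  if (abs(maximum - expected) < 1e-12) return(if (c_ + d == 0) 1 else 0)
  (a - expected) / (maximum - expected)
}

# direct evaluation of the modularity sum, independent of modularity_q
direct_modularity <- function(assignment, W, gamma = 1) {
  two_m <- sum(W)
  if (two_m == 0) return(0)
  s <- rowSums(W)
  q <- 0
  for (cc in unique(assignment)) {
    idx <- which(assignment == cc)
    q <- q + sum(W[idx, idx]) / two_m - gamma * (sum(s[idx]) / two_m)^2
  }
  q
}

# network whose raters all share one partition (block-diagonal cliques)
identical_sort_study <- function(partition, n_raters) {
  corpus <- quote_corpus(as.integer(names(partition)))
  sorts <- lapply(seq_len(n_raters), function(r) {
    rater_sort(paste0("R", r),
               stats::setNames(paste0("g", partition), names(partition)))
  })
  sort_study(corpus, sorts)
}

planted_as_labels <- function(planted) {
  stats::setNames(as.character(planted), names(planted))
}
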