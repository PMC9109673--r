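# Agreement between the consensus themes and an independent coder's
# partition: contingency table, optimal injective theme alignment, percent
# agreement, adjusted Rand index, normalised mutual information.

#' Cross-tabulate consensus themes against an independent coder
#'
#' Counts `n_kl = |theme_k intersect group_l|` over the quotes covered by
#' both partitions. Quotes covered by only one side are excluded from the
#' table but listed in the result, never silently dropped.
#'
#' @param reference A `pte_themes` (the consensus grouping).
#' @param coder A [rater_sort()] holding the independent coder's partition.
#' @return Object of class `pte_contingency`: `counts` (K x L integer matrix,
#'   rows in theme order, columns in sorted coder-label order), `n` (total
#'   jointly covered quotes), `excluded_reference`, `excluded_coder`.
#' @export
contingency_table <- function(reference, coder) {
  stopifnot(inherits(reference, "pte_themes"), inherits(coder, "pte_rater_sort"))
  ref_assign <- themes_assignment(reference)
  coder_assign <- coder$assignment
  common <- intersect(names(ref_assign), names(coder_assign))
  if (!length(common)) {
    pte_stop("the consensus and coder partitions cover no common quotes",
             "pte_coverage_error")
  }
  row_labs <- names(reference$themes)
  col_labs <- sort(unique(unname(coder_assign)), method = "radix")
  counts <- table(
    factor(ref_assign[common], levels = row_labs),
    factor(coder_assign[common], levels = col_labs)
  )
  counts <- matrix(as.integer(counts), nrow = length(row_labs),
                   dimnames = list(row_labs, col_labs))
  structure(
    list(counts = counts, n = length(common),
         excluded_reference = sort(as.integer(setdiff(names(ref_assign), common))),
         excluded_coder = sort(as.integer(setdiff(names(coder_assign), common)))),
    class = "pte_contingency"
  )
}

#' @export
print.pte_contingency <- function(x, ...) {
  cat(sprintf("Contingency table: %d themes x %d coder groups, N = %d\n",
              nrow(x$counts), ncol(x$counts), x$n))
  print(x$counts)
  invisible(x)
}

#' Optimally align consensus themes with coder groups
#'
#' Finds the injective mapping from themes to coder groups maximising the
#' total number of matched quotes (a rectangular assignment problem, solved
#' exactly by dynamic programming over subsets of coder groups). When there
#' are more themes than coder groups, the surplus themes stay unmapped. Ties
#' are broken towards the mapping that is lexicographically smallest in theme
#' order, with mapped preferred to unmapped.
#'
#' @param table A `pte_contingency` (or a bare counts matrix).
#' @return List with `mapping` (named character vector theme -> coder group,
#'   `NA` for unmapped themes), `matched` (total matched quotes),
#'   `unmapped_themes`.
#' @export
align_partitions <- function(table) {
  counts <- if (inherits(table, "pte_contingency")) table$counts else table
  K <- nrow(counts); L <- ncol(counts)
  if (K < 1L || L < 1L) {
    pte_stop("contingency table must have at least one row and column",
             "pte_usage_error")
  }
  if (L > 16L) {
    pte_stop("alignment supports at most 16 coder groups", "pte_size_error")
  }
  n_masks <- bitwShiftL(1L, L)
  # g[k, mask + 1]: best total over themes k..K given the used-column mask.
  g <- matrix(0, K + 1L, n_masks)
  for (k in K:1) {
    for (mask in 0:(n_masks - 1L)) {
      best <- g[k + 1L, mask + 1L] # leave theme k unmapped
      for (j in seq_len(L)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0L) {
          v <- counts[k, j] + g[k + 1L, bitwOr(mask, bit) + 1L]
          if (v > best) best <- v
        }
      }
      g[k, mask + 1L] <- best
    }
  }
  # forward pass: lexicographically smallest optimal choice per theme,
  # columns in order, unmapped last.
  mapping <- stats::setNames(rep(NA_character_, K), rownames(counts))
  mask <- 0L
  for (k in seq_len(K)) {
    target <- g[k, mask + 1L]
    chosen <- NA_integer_
    for (j in seq_len(L)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L &&
          counts[k, j] + g[k + 1L, bitwOr(mask, bit) + 1L] == target) {
        chosen <- j
        break
      }
    }
    if (!is.na(chosen)) {
      mapping[k] <- colnames(counts)[chosen]
      mask <- bitwOr(mask, bitwShiftL(1L, chosen - 1L))
    }
  }
  list(mapping = mapping,
       matched = g[1L, 1L],
       unmapped_themes = names(mapping)[is.na(mapping)])
}

# partitions as named vectors over an identical quote set
check_same_coverage <- function(p1, p2) {
  if (is.null(names(p1)) || is.null(names(p2)) ||
      !setequal(names(p1), names(p2))) {
    pte_stop("partitions must cover the same quote set", "pte_coverage_error")
  }
}

#' Adjusted Rand index between two partitions
#'
#' Standard pair-counting ARI with the permutation-model correction for
#' chance: 1 for identical partitions (up to relabelling), expectation 0 for
#' independent partitions. When the chance-expected index equals the maximum
#' (both partitions trivially identical, e.g. a single quote), the value is
#' 1 if the partitions are identical and 0 otherwise.
#'
#' @param p1,p2 Named vectors mapping the same quote ids to group labels.
#' @return A number in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(p1, p2) {
  check_same_coverage(p1, p2)
  p2 <- p2[names(p1)]
  tab <- table(as.character(p1), as.character(p2))
  nij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  n_pairs <- choose(sum(tab), 2)
  expected <- if (n_pairs > 0) a * b / n_pairs else 0
  maximum <- (a + b) / 2
  if (abs(maximum - expected) < 1e-12) {
    return(if (abs(nij - maximum) < 1e-12 && a == b) 1 else 0)
  }
  (nij - expected) / (maximum - expected)
}

#' Normalised mutual information between two partitions
#'
#' Mutual information normalised by the arithmetic mean of the two
#' partition entropies (natural log): `NMI = 2 I / (H1 + H2)`, in `[0, 1]`.
#' Defined as 1 when both partitions are the trivial single group.
#'
#' @param p1,p2 Named vectors mapping the same quote ids to group labels.
#' @return A number in `[0, 1]`.
#' @export
normalized_mutual_info <- function(p1, p2) {
  check_same_coverage(p1, p2)
  p2 <- p2[names(p1)]
  n <- length(p1)
  tab <- table(as.character(p1), as.character(p2)) / n
  pi <- rowSums(tab); pj <- colSums(tab)
  h1 <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  h2 <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (h1 + h2 < 1e-12) return(1)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pi, pj)[nz]))
  max(0, min(1, 2 * mi / (h1 + h2)))
}

#' Agreement report between consensus themes and an independent coder
#'
#' Composes [contingency_table()] and [align_partitions()], then reports:
#' overall percent agreement (matched quotes over all jointly covered
#' quotes), per-theme percent agreement (matched quotes over theme size by
#' default, or over the mapped coder group's size with
#' `denominator = "coder"`; 0 for unmapped themes), the adjusted Rand index
#' and normalised mutual information. Percentages are on the 0-100 scale at
#' full precision; the print method renders one decimal place.
#'
#' @param reference A `pte_themes`.
#' @param coder A [rater_sort()].
#' @param denominator Per-theme denominator convention: `"theme"` (consensus
#'   theme size, default) or `"coder"` (mapped coder group size).
#' @return Object of class `pte_agreement` with fields `table`, `mapping`,
#'   `overall_percent`, `per_theme_percent`, `ari`, `nmi`,
#'   `unmapped_themes`, `excluded_reference`, `excluded_coder`, `n`.
#' @examples
#' ref <- theme_set(list(T1 = 1:5, T2 = 6:10))
#' coder <- rater_sort("coder", stats::setNames(rep(c("G1", "G2"), c(6, 4)), 1:10))
#' agreement_report(ref, coder)$overall_percent  # 90
#' @export
agreement_report <- function(reference, coder,
                             denominator = c("theme", "coder")) {
  denominator <- match.arg(denominator)
  ct <- contingency_table(reference, coder)
  al <- align_partitions(ct)
  counts <- ct$counts
  matched_k <- vapply(seq_len(nrow(counts)), function(k) {
    if (is.na(al$mapping[k])) 0L else counts[k, al$mapping[k]]
  }, integer(1))
  denom_k <- vapply(seq_len(nrow(counts)), function(k) {
    if (denominator == "theme") sum(counts[k, ])
    else if (is.na(al$mapping[k])) 0L else sum(counts[, al$mapping[k]])
  }, numeric(1))
  per_theme <- ifelse(denom_k > 0, 100 * matched_k / denom_k, 0)
  names(per_theme) <- rownames(counts)
  ref_assign <- themes_assignment(reference)
  common <- intersect(names(ref_assign), names(coder$assignment))
  structure(
    list(table = ct,
         mapping = al$mapping,
         overall_percent = 100 * al$matched / ct$n,
         per_theme_percent = per_theme,
         ari = adjusted_rand_index(ref_assign[common], coder$assignment[common]),
         nmi = normalized_mutual_info(ref_assign[common], coder$assignment[common]),
         unmapped_themes = al$unmapped_themes,
         excluded_reference = ct$excluded_reference,
         excluded_coder = ct$excluded_coder,
         n = ct$n,
         denominator = denominator),
    class = "pte_agreement"
  )
}

#' @export
print.pte_agreement <- function(x, ...) {
  cat(sprintf("Agreement vs independent coder (N = %d jointly covered quotes)\n", x$n))
  cat(sprintf("  overall: %.1f%%   ARI: %.3f   NMI: %.3f\n",
              x$overall_percent, x$ari, x$nmi))
  for (k in names(x$per_theme_percent)) {
    cat(sprintf("  %s -> %s: %.1f%%\n", k,
                if (is.na(x$mapping[k])) "(unmapped)" else x$mapping[k],
                x$per_theme_percent[k]))
  }
  if (length(x$excluded_reference) || length(x$excluded_coder)) {
    cat(sprintf("  excluded (one-sided coverage): %d consensus-only, %d coder-only\n",
                length(x$excluded_reference), length(x$excluded_coder)))
  }
  invisible(x)
}

#' Serialise an agreement report to JSON
#'
#' @param report A `pte_agreement`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_json <- function(report, path) {
  payload <- list(
    n = report$n,
    overall_percent = report$overall_percent,
    per_theme_percent = as.list(report$per_theme_percent),
    mapping = as.list(report$mapping),
    ari = report$ari,
    nmi = report$nmi,
    unmapped_themes = report$unmapped_themes,
    excluded_reference = report$excluded_reference,
    excluded_coder = report$excluded_coder,
    denominator = report$denominator,
    contingency = list(
      row_labels = rownames(report$table$counts),
      col_labels = colnames(report$table$counts),
      counts = unname(apply(report$table$counts, 1, as.list, simplify = FALSE))
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
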