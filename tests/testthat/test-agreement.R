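# Contingency tables, optimal alignment, percent agreement, ARI, NMI.

test_that("contingency tables count theme/group intersections exactly", {
  ref <- theme_set(list(T1 = 1:2, T2 = 3:4))
  coder <- rater_sort("c", stats::setNames(c("A", "A", "B", "B"), 1:4))
  ct <- contingency_table(ref, coder)
  expect_equal(unname(ct$counts), matrix(c(2L, 0L, 0L, 2L), 2))

  ref2 <- theme_set(list(T1 = 1:5, T2 = 6:10))
  coder2 <- rater_sort("c", stats::setNames(rep(c("G1", "G2"), c(6, 4)), 1:10))
  ct2 <- contingency_table(ref2, coder2)
  expect_equal(unname(ct2$counts), matrix(c(5L, 1L, 0L, 4L), 2))

  # random partitions against a per-quote exhaustive tally
  set.seed(19)
  for (i in 1:10) {
    ids <- 1:30
    ref_assign <- sample(paste0("T", 1:4), 30, TRUE)
    coder_assign <- sample(paste0("G", 1:5), 30, TRUE)
    ref_i <- theme_set(split(ids, ref_assign))
    coder_i <- rater_sort("c", stats::setNames(coder_assign, ids))
    ct_i <- contingency_table(ref_i, coder_i)
    for (k in rownames(ct_i$counts)) {
      for (l in colnames(ct_i$counts)) {
        expect_equal(ct_i$counts[k, l],
                     sum(ref_assign == k & coder_assign == l))
      }
    }
    expect_equal(sum(ct_i$counts), 30L)
  }
})

test_that("one-sided quotes are excluded and reported, empty overlap errors", {
  ref <- theme_set(list(T1 = 1:3, T2 = 4:6))
  coder <- rater_sort("c", stats::setNames(rep("A", 4), 4:7))
  ct <- contingency_table(ref, coder)
  expect_equal(ct$n, 3L)
  expect_equal(ct$excluded_reference, 1:3)
  expect_equal(ct$excluded_coder, 7L)
  disjoint <- rater_sort("c", stats::setNames(rep("A", 2), 8:9))
  expect_error(contingency_table(ref, disjoint), class = "pte_coverage_error")
})

test_that("alignment finds the optimal injective mapping with stated tie-breaks", {
  m <- matrix(c(5L, 1L, 0L, 4L), 2, dimnames = list(c("T1", "T2"), c("G1", "G2")))
  al <- align_partitions(m)
  expect_equal(al$mapping, c(T1 = "G1", T2 = "G2"))
  expect_equal(al$matched, 9)

  # coder merged two themes: injectivity leaves one theme unmapped,
  # tie broken towards the earlier theme
  merged <- matrix(c(5L, 5L), 2, dimnames = list(c("T1", "T2"), "G1"))
  al2 <- align_partitions(merged)
  expect_equal(al2$mapping, c(T1 = "G1", T2 = NA))
  expect_equal(al2$unmapped_themes, "T2")

  # lexicographic tie-break among equally good columns
  tie <- matrix(c(3L, 0L, 3L, 0L, 0L, 7L), 2,
                dimnames = list(c("T1", "T2"), c("G1", "G2", "G3")))
  expect_equal(align_partitions(tie)$mapping, c(T1 = "G1", T2 = "G3"))
})

test_that("alignment equals exhaustive enumeration on random tables", {
  set.seed(61)
  for (i in 1:100) {
    K <- sample(1:6, 1); L <- sample(1:6, 1)
    counts <- matrix(rpois(K * L, 3), K,
                     dimnames = list(paste0("T", 1:K), paste0("G", 1:L)))
    expect_equal(align_partitions(counts)$matched, brute_force_alignment(counts))
  }
})

test_that("agreement report reproduces the hand-worked two-theme example", {
  ref <- theme_set(list(T1 = 1:5, T2 = 6:10))
  coder <- rater_sort("c", stats::setNames(rep(c("G1", "G2"), c(6, 4)), 1:10))
  rep_ <- agreement_report(ref, coder)
  expect_equal(rep_$overall_percent, 90)
  expect_equal(unname(rep_$per_theme_percent), c(100, 80))
  # sensitivity convention: denominators from the mapped coder groups
  rep_coder <- agreement_report(ref, coder, denominator = "coder")
  expect_equal(unname(rep_coder$per_theme_percent), c(100 * 5 / 6, 100))
})

test_that("identical partitions give 100 percent, ARI 1, NMI 1", {
  ref <- theme_set(split(1:20, rep(paste0("T", 1:4), each = 5)))
  coder <- rater_sort("c", stats::setNames(rep(paste0("z", 4:1), each = 5), 1:20))
  rep_ <- agreement_report(ref, coder)
  expect_equal(rep_$overall_percent, 100)
  expect_true(all(rep_$per_theme_percent == 100))
  expect_equal(rep_$ari, 1)
  expect_equal(rep_$nmi, 1)
})

test_that("overall percent is bounded, relabel-invariant, above max cell share", {
  set.seed(67)
  for (i in 1:10) {
    ids <- 1:25
    ref_assign <- sample(paste0("T", 1:3), 25, TRUE)
    coder_assign <- sample(paste0("G", 1:4), 25, TRUE)
    ref_i <- theme_set(split(ids, ref_assign))
    coder_i <- rater_sort("c", stats::setNames(coder_assign, ids))
    rep_i <- agreement_report(ref_i, coder_i)
    expect_gte(rep_i$overall_percent, 100 * max(rep_i$table$counts) / 25)
    expect_lte(rep_i$overall_percent, 100)
    # relabel both sides: the overall percentage cannot change
    relab <- rater_sort("c", stats::setNames(
      paste0("relabelled-", coder_assign), ids))
    expect_equal(agreement_report(ref_i, relab)$overall_percent,
                 rep_i$overall_percent)
  }
})

test_that("ARI matches pair-counting oracle, mclust, and its invariants", {
  set.seed(71)
  for (i in 1:15) {
    p1 <- stats::setNames(sample(letters[1:3], 12, TRUE), 1:12)
    p2 <- stats::setNames(sample(LETTERS[1:4], 12, TRUE), 1:12)
    expect_equal(adjusted_rand_index(p1, p2), brute_force_ari(p1, p2))
    expect_equal(adjusted_rand_index(p1, p2), adjusted_rand_index(p2, p1))
    expect_equal(adjusted_rand_index(p1, p1), 1)
    expect_equal(adjusted_rand_index(p1, p2),
                 mclust::adjustedRandIndex(p1[as.character(1:12)],
                                           p2[as.character(1:12)]))
  }
  # degeneracy convention: all-in-one vs all-singletons
  allone <- stats::setNames(rep("x", 6), 1:6)
  singles <- stats::setNames(letters[1:6], 1:6)
  expect_equal(adjusted_rand_index(allone, singles), 0)
  expect_error(adjusted_rand_index(allone, singles[1:3]),
               class = "pte_coverage_error")
})

test_that("NMI is normalised, symmetric and 1 only for matching structure", {
  p1 <- stats::setNames(rep(c("a", "b"), each = 5), 1:10)
  p2 <- stats::setNames(rep(c("X", "Y"), each = 5), 1:10)
  expect_equal(normalized_mutual_info(p1, p2), 1)
  set.seed(73)
  for (i in 1:10) {
    q1 <- stats::setNames(sample(letters[1:3], 15, TRUE), 1:15)
    q2 <- stats::setNames(sample(letters[1:3], 15, TRUE), 1:15)
    v <- normalized_mutual_info(q1, q2)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, normalized_mutual_info(q2, q1))
  }
})

test_that("independent partitions have mean ARI near zero (Monte-Carlo null)", {
  set.seed(79)
  aris <- replicate(20, {
    ref <- stats::setNames(sample(paste0("T", 1:5), 94, TRUE), 1:94)
    coder <- stats::setNames(sample(paste0("G", 1:6), 94, TRUE), 1:94)
    adjusted_rand_index(ref, coder)
  })
  expect_lt(abs(mean(aris)), 3 * stats::sd(aris) / sqrt(20) + 0.01)
})
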