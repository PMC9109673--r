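# Synthetic sort studies with planted theme structure. Defaults mirror a
# typical participatory theme elicitation study: 94 quotes, 5 underlying
# themes, 8 raters each producing 4-12 groups, plus one independent coder.

#' Configuration for a synthetic sort study
#'
#' @param n_quotes Number of quotes N (default 94).
#' @param n_themes Number of planted themes K (default 5).
#' @param n_raters Number of raters R (default 8).
#' @param misassignment_rate Probability that a rater displaces a quote to a
#'   uniformly chosen other group, after coarsening/refining to the rater's
#'   group count (default 0).
#' @param rater_group_range Inclusive integer range the per-rater group count
#'   is drawn from (default `c(4, 12)`).
#' @param coder_misassignment_rate Displacement probability for the
#'   independent coder (default 0).
#' @param coder_group_count Target group count for the independent coder;
#'   defaults to `n_themes`.
#' @param seed Integer master seed; every rater and the coder draw from
#'   independently derived streams, so adding a rater never perturbs the
#'   sorts of existing ones.
#' @return A validated list of class `pte_synthetic_config`.
#' @export
synthetic_config <- function(n_quotes = 94L, n_themes = 5L, n_raters = 8L,
                             misassignment_rate = 0,
                             rater_group_range = c(4L, 12L),
                             coder_misassignment_rate = 0,
                             coder_group_count = NULL,
                             seed = 1L) {
  n_quotes <- as.integer(n_quotes); n_themes <- as.integer(n_themes)
  n_raters <- as.integer(n_raters)
  rater_group_range <- as.integer(rater_group_range)
  coder_group_count <- as.integer(coder_group_count %||% n_themes)
  if (n_themes < 1L || n_quotes < n_themes) {
    pte_stop("need n_quotes >= n_themes >= 1", "pte_config_error")
  }
  if (n_raters < 1L) pte_stop("need n_raters >= 1", "pte_config_error")
  for (rate in c(misassignment_rate, coder_misassignment_rate)) {
    if (rate < 0 || rate > 1) {
      pte_stop("misassignment rates must lie in [0, 1]", "pte_config_error")
    }
  }
  if (length(rater_group_range) != 2L || rater_group_range[1] > rater_group_range[2] ||
      rater_group_range[1] < 1L || rater_group_range[2] > n_quotes) {
    pte_stop("rater_group_range must be an increasing pair within [1, n_quotes]",
             "pte_config_error")
  }
  if (coder_group_count < 1L || coder_group_count > n_quotes) {
    pte_stop("coder_group_count must lie in [1, n_quotes]", "pte_config_error")
  }
  structure(
    list(n_quotes = n_quotes, n_themes = n_themes, n_raters = n_raters,
         misassignment_rate = misassignment_rate,
         rater_group_range = rater_group_range,
         coder_misassignment_rate = coder_misassignment_rate,
         coder_group_count = coder_group_count,
         seed = as.integer(seed)),
    class = "pte_synthetic_config"
  )
}

#' Planted theme partition
#'
#' Distributes quotes 1..N over K themes with sizes as equal as possible,
#' remainder going to the lowest theme ids (e.g. N = 94, K = 5 gives sizes
#' 19, 19, 19, 19, 18). The layout is deterministic.
#'
#' @param config A [synthetic_config()].
#' @return Named integer vector quote id -> theme id (1..K).
#' @export
generate_planted_partition <- function(config) {
  stopifnot(inherits(config, "pte_synthetic_config"))
  N <- config$n_quotes; K <- config$n_themes
  sizes <- rep(N %/% K, K)
  extra <- N %% K
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stats::setNames(rep(seq_len(K), times = sizes), seq_len(N))
}

# Coarsen (merge random group pairs) or refine (split random groups, moving
# a uniformly chosen floor(size/2) of the members to a new group) a
# partition until it has `target` groups. Uses the current RNG stream.
adjust_group_count <- function(part, target) {
  part <- as.integer(factor(part))
  repeat {
    g <- length(unique(part))
    if (g == target) break
    if (g > target) {
      pair <- sample(unique(part), 2L)
      part[part == pair[2]] <- pair[1]
    } else {
      sizes <- table(part)
      splittable <- as.integer(names(sizes)[sizes >= 2L])
      victim <- if (length(splittable) == 1L) splittable else sample(splittable, 1L)
      members <- which(part == victim)
      take <- sample(members, length(members) %/% 2L)
      part[take] <- max(part) + 1L
    }
  }
  as.integer(factor(part))
}

# Build one noisy partition from the planted truth: adjust to `g` groups,
# then displace each quote independently with probability `rate` to a
# uniformly chosen *other* group.
noisy_partition <- function(planted, g, rate) {
  part <- adjust_group_count(unname(planted), g)
  g_now <- length(unique(part))
  if (rate > 0 && g_now > 1L) {
    hit <- stats::runif(length(part)) < rate
    for (i in which(hit)) {
      others <- setdiff(seq_len(g_now), part[i])
      part[i] <- if (length(others) == 1L) others else sample(others, 1L)
    }
  }
  part
}

# group ids -> rater-scoped labels G1..Gg in order of first appearance
label_groups <- function(part) {
  paste0("G", match(part, unique(part)))
}

#' Simulate rater sorts around a planted partition
#'
#' Each rater draws a target group count from `rater_group_range`, coarsens
#' or refines the planted partition to that count (merging random theme
#' pairs, or splitting random themes by moving half their quotes to a new
#' group), then independently displaces each quote with probability
#' `misassignment_rate` to a uniformly chosen other group. Every rater uses
#' an independently derived seed stream.
#'
#' @param planted Named integer vector from [generate_planted_partition()].
#' @param config A [synthetic_config()].
#' @return Named list of [rater_sort()] objects `R1..Rn`.
#' @export
simulate_rater_sorts <- function(planted, config) {
  stopifnot(inherits(config, "pte_synthetic_config"))
  N <- length(planted)
  lo <- config$rater_group_range[1]; hi <- config$rater_group_range[2]
  sorts <- list()
  for (r in seq_len(config$n_raters)) {
    rid <- paste0("R", r)
    sorts[[rid]] <- with_rng_seed(stream_seed(config$seed, r), {
      g <- if (lo == hi) lo else sample(lo:hi, 1L)
      part <- noisy_partition(planted, g, config$misassignment_rate)
      rater_sort(rid, stats::setNames(label_groups(part), names(planted)))
    })
  }
  sorts
}

#' Simulate the independent coder's partition
#'
#' Built from the planted partition with the coder's own target group count
#' (`coder_group_count`) and displacement rate (`coder_misassignment_rate`),
#' on a seed stream independent of every rater's.
#'
#' @param planted Named integer vector from [generate_planted_partition()].
#' @param config A [synthetic_config()].
#' @return A [rater_sort()] with rater id `"independent_coder"`.
#' @export
simulate_independent_coder <- function(planted, config) {
  stopifnot(inherits(config, "pte_synthetic_config"))
  with_rng_seed(stream_seed(config$seed, 999983L), {
    part <- noisy_partition(planted, config$coder_group_count,
                            config$coder_misassignment_rate)
    rater_sort("independent_coder",
               stats::setNames(label_groups(part), names(planted)))
  })
}

#' Generate a complete synthetic sort study
#'
#' Combines the planted partition, the simulated rater sorts, the simulated
#' independent coder and a placeholder corpus into one reproducible object:
#' the same config (including seed) always yields the identical study.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `pte_synthetic_study`: `planted`, `study`
#'   (a [sort_study()]), `coder`, `config`.
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "pte_synthetic_config"))
  planted <- generate_planted_partition(config)
  corpus <- quote_corpus(seq_len(config$n_quotes),
                         text = sprintf("Synthetic quote %d", seq_len(config$n_quotes)),
                         source_tag = rep("synthetic", config$n_quotes))
  study <- sort_study(corpus, simulate_rater_sorts(planted, config))
  structure(
    list(planted = planted, study = study,
         coder = simulate_independent_coder(planted, config),
         config = config),
    class = "pte_synthetic_study"
  )
}

#' Write a synthetic study to CSV files
#'
#' Emits `corpus.csv`, `sorts.csv`, `coder.csv` and the planted truth
#' `planted.csv` (`quote_id,theme_id`) into `dir`, so the full pipeline can
#' run on files alone.
#'
#' @param synthetic A `pte_synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_synthetic_study <- function(synthetic, dir) {
  stopifnot(inherits(synthetic, "pte_synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(corpus = file.path(dir, "corpus.csv"),
             sorts = file.path(dir, "sorts.csv"),
             coder = file.path(dir, "coder.csv"),
             planted = file.path(dir, "planted.csv"))
  write_corpus(synthetic$study$corpus, paths["corpus"])
  write_sort_table(synthetic$study$sorts, paths["sorts"])
  write_sort_table(list(synthetic$coder), paths["coder"])
  utils::write.csv(
    data.frame(quote_id = as.integer(names(synthetic$planted)),
               theme_id = unname(synthetic$planted)),
    paths["planted"], row.names = FALSE)
  invisible(paths)
}
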