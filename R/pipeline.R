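# End-to-end pipeline: read -> validate -> network -> detect -> (refine) ->
# agreement -> export, with a consolidated machine-readable run report.

log_levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

pte_log <- function(level, msg, threshold = "info") {
  if (log_levels[[level]] >= log_levels[[threshold]]) {
    message(sprintf("[%s] %s", toupper(level), msg))
  }
}

#' Pipeline run configuration
#'
#' @param sorts Path to the long-format sort-table CSV (required).
#' @param out_dir Output directory for all artefacts (required).
#' @param corpus Optional corpus CSV path; without it the corpus is inferred
#'   as the union of quote ids in the sorts.
#' @param coder Optional independent-coder CSV (same long format, single
#'   rater); when absent the agreement stage is skipped.
#' @param refinement Optional JSON file holding an array of refinement
#'   actions (fields as in [refinement_action()]).
#' @param resolution Resolution `gamma` for community detection.
#' @param seed Integer seed used for detection sweeps and the layout.
#' @param denominator Per-theme agreement denominator, `"theme"` or
#'   `"coder"`.
#' @param unassigned Treatment of unassigned quotes in [build_network()].
#' @param require_complete Fail validation if any rater left quotes
#'   unassigned.
#' @param log_level Minimum level written to standard error.
#' @return A list of class `pte_run_config`.
#' @export
run_config <- function(sorts, out_dir, corpus = NULL, coder = NULL,
                       refinement = NULL, resolution = 1, seed = 1L,
                       denominator = c("theme", "coder"),
                       unassigned = c("ignore", "singleton"),
                       require_complete = FALSE,
                       log_level = c("info", "debug", "warning", "error")) {
  if (missing(sorts) || is.null(sorts)) {
    pte_stop("run_config needs a sorts path", "pte_config_error")
  }
  if (missing(out_dir) || is.null(out_dir)) {
    pte_stop("run_config needs an output directory", "pte_config_error")
  }
  for (p in c(sorts, corpus, coder, refinement)) {
    if (!file.exists(p)) {
      pte_stop(sprintf("input path does not exist: %s", p), "pte_config_error")
    }
  }
  if (resolution <= 0) pte_stop("resolution must be > 0", "pte_config_error")
  structure(
    list(sorts = sorts, out_dir = out_dir, corpus = corpus, coder = coder,
         refinement = refinement, resolution = resolution,
         seed = as.integer(seed),
         denominator = match.arg(denominator),
         unassigned = match.arg(unassigned),
         require_complete = isTRUE(require_complete),
         log_level = match.arg(log_level)),
    class = "pte_run_config"
  )
}

read_refinement_actions <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(a) {
    refinement_action(
      type = a$type,
      label = a$label, quote_id = a$quote_id, to = a$to,
      from = a$from, to_label = a$to_label %||% a$to,
      rationale = a$rationale %||% ""
    )
  })
}

#' Run the full consensus-theming pipeline
#'
#' Reads the sort table (and optional corpus, coder and refinement files),
#' validates the study, builds the co-occurrence network, detects consensus
#' communities, applies any scripted refinement, computes agreement against
#' the independent coder when supplied, and writes every artefact under
#' `config$out_dir`: `network.graphml`, `edges.tsv`, `partition.csv`,
#' `themes.json`, `agreement.json`, `layout.csv`, `layout.svg` and a
#' consolidated `report.json` (package version, config echo, seed, Q, K).
#' All machine-readable outputs are byte-reproducible for fixed inputs and
#' seed.
#'
#' @param config A [run_config()].
#' @return The run report (a list of class `pte_run_report`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pte_run_config"))
  lvl <- config$log_level
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  pte_log("info", sprintf("read_sort_table: %s", config$sorts), lvl)
  sorts <- read_sort_table(config$sorts)
  corpus <- if (!is.null(config$corpus)) {
    read_corpus(config$corpus)
  } else {
    ids <- sort(unique(unlist(lapply(sorts, function(s)
      as.integer(names(s$assignment))))))
    quote_corpus(ids)
  }
  study <- sort_study(corpus, sorts)

  pte_log("info", "validate_study", lvl)
  findings <- validate_study(study, require_complete = config$require_complete)
  if (any(findings$level == "error")) {
    pte_stop(sprintf("validate_study: %s", findings$message[findings$level == "error"][1]),
             "pte_format_error")
  }

  pte_log("info", "build_network", lvl)
  net <- build_network(study, unassigned = config$unassigned)
  pte_log("info", sprintf("detect_communities (gamma = %g, seed = %d)",
                          config$resolution, config$seed), lvl)
  part <- detect_communities(net, resolution = config$resolution,
                             seed = config$seed)

  actions <- if (!is.null(config$refinement)) {
    pte_log("info", sprintf("apply_refinement: %s", config$refinement), lvl)
    read_refinement_actions(config$refinement)
  } else list()
  themes <- apply_refinement(part, actions, net = net)

  agreement <- NULL
  if (!is.null(config$coder)) {
    pte_log("info", sprintf("agreement_report: %s", config$coder), lvl)
    coder_sorts <- read_sort_table(config$coder)
    if (length(coder_sorts) != 1L) {
      pte_stop("coder file must contain exactly one rater", "pte_format_error")
    }
    agreement <- agreement_report(themes, coder_sorts[[1]],
                                  denominator = config$denominator)
  }

  pte_log("info", "exporting artefacts", lvl)
  out <- function(f) file.path(config$out_dir, f)
  export_network(net, "graphml", out("network.graphml"), partition = part)
  export_network(net, "edge-tsv", out("edges.tsv"))
  write_partition_csv(themes, out("partition.csv"))
  write_themes_json(themes, out("themes.json"), partition = part)
  layout <- compute_layout(net, part, seed = config$seed)
  utils::write.csv(as.data.frame(layout), out("layout.csv"), row.names = FALSE)
  write_layout_svg(layout, out("layout.svg"))
  if (!is.null(agreement)) write_agreement_json(agreement, out("agreement.json"))

  report <- structure(
    list(
      package_version = as.character(utils::packageVersion("pte")),
      config = list(sorts = config$sorts, corpus = config$corpus,
                    coder = config$coder, refinement = config$refinement,
                    resolution = config$resolution, seed = config$seed,
                    denominator = config$denominator,
                    unassigned = config$unassigned),
      n_quotes = nrow(study$corpus),
      n_raters = study$n_raters,
      n_communities = part$n_communities,
      modularity = part$modularity,
      theme_sizes = stats::setNames(as.list(lengths(themes$themes)),
                                    names(themes$themes)),
      n_refinement_actions = length(themes$provenance),
      validation_warnings = sum(findings$level == "warning"),
      agreement = if (is.null(agreement)) "skipped" else list(
        n = agreement$n,
        overall_percent = agreement$overall_percent,
        per_theme_percent = as.list(agreement$per_theme_percent),
        ari = agreement$ari,
        nmi = agreement$nmi,
        unmapped_themes = agreement$unmapped_themes
      )
    ),
    class = "pte_run_report"
  )
  jsonlite::write_json(unclass(report), out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  pte_log("info", "pipeline complete", lvl)
  invisible(report)
}

#' Render a run report as markdown text
#'
#' @param report A `pte_run_report` from [run_pipeline()].
#' @return Character vector of markdown lines (also printable via `cat`).
#' @export
generate_report <- function(report) {
  stopifnot(inherits(report, "pte_run_report"))
  lines <- c(
    "# Consensus theming run report",
    "",
    sprintf("- Input: %d quotes, %d raters", report$n_quotes, report$n_raters),
    sprintf("- Detected communities: %d (Q = %.4f, gamma = %g, seed = %d)",
            report$n_communities, report$modularity,
            report$config$resolution, report$config$seed),
    sprintf("- Refinement actions applied: %d", report$n_refinement_actions),
    "",
    "## Themes")
  for (lab in names(report$theme_sizes)) {
    lines <- c(lines, sprintf("- %s: %d quotes", lab, report$theme_sizes[[lab]]))
  }
  lines <- c(lines, "", "## Agreement with independent coder")
  if (identical(report$agreement, "skipped")) {
    lines <- c(lines, "- skipped (no coder file supplied)")
  } else {
    ag <- report$agreement
    lines <- c(lines,
      sprintf("- Overall: %.1f%% of %d quotes (ARI %.3f, NMI %.3f)",
              ag$overall_percent, ag$n, ag$ari, ag$nmi))
    for (lab in names(ag$per_theme_percent)) {
      lines <- c(lines, sprintf("- %s: %.1f%%", lab, ag$per_theme_percent[[lab]]))
    }
  }
  lines
}
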