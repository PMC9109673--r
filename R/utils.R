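# Internal helpers shared across the package.

# Signal a classed condition so callers (and the CLI) can map failures to
# exit codes. `class` is the specific condition class, e.g. "pte_parse_error".
pte_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "pte_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a deterministic sub-seed for an independent stream (per rater, per
# coder, per replicate). Linear-congruential mix kept below 2^31 - 1; all
# arithmetic stays exact in doubles.
stream_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index) * 8191
  as.integer(s %% 2147483647) + 1L
}

# quote ids are 1-based integers throughout; parse strictly.
parse_quote_id <- function(x, context = "quote id") {
  x <- trimws(as.character(x))
  ok <- grepl("^[0-9]+$", x)
  if (!all(ok)) {
    bad <- x[!ok][1]
    pte_stop(
      sprintf("non-integer %s %s: ids must be positive integers (quotes are labelled 1..N)",
              context, dQuote(bad)),
      "pte_parse_error"
    )
  }
  id <- as.integer(x)
  if (any(id < 1L)) {
    pte_stop(sprintf("%s must be >= 1", context), "pte_parse_error")
  }
  id
}

`%||%` <- function(a, b) if (is.null(a)) b else a
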