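# pte — Participatory Theme Elicitation from multiple card sorts

Participatory theme elicitation (PTE) brings lay co-researchers — people
with lived experience of the services being studied — into qualitative
analysis: each of R co-researchers independently sorts the same N numbered
quotes into groups of their own devising, and the individual sorts are
combined computationally into consensus themes that the group then
discusses, refines and labels. An independent coder can re-sort the quotes,
and the similarity between the two partitions measures how reproducible the
consensus is.

`pte` implements that computational core for analysts running or evaluating
PTE studies:

* **Sort ingestion** — the three-column long format
  (`quote_id,rater_id,group_label`, or the spreadsheet names
  `Topic,Person,Group`), with validation and exact round-tripping.
* **Co-occurrence network** — nodes are quotes; edge weight
  `w_ij = #{r : g_r(i) = g_r(j)}` counts the raters pairing quotes i and j;
  exported as GraphML or a TSV edge list.
* **Consensus detection** — seeded two-phase greedy maximisation of weighted
  Newman modularity `Q = Σ_c [W_c/(2m) − γ(S_c/(2m))²]`, with resolution γ
  exposed and an exact enumeration oracle (≤ 12 nodes, Rcpp) for
  validation.
* **Documented refinement** — create/move/rename actions with rationales and
  a full provenance trail, modelling the human discussion step.
* **Agreement validation** — contingency table, optimal injective theme
  alignment (exact rectangular assignment), overall and per-theme percent
  agreement, adjusted Rand index, normalised mutual information.
* **Synthetic studies** — a planted-partition generator (defaults: 94
  quotes, 5 themes, 8 raters with 4–12 groups each, plus an independent
  coder) so the whole pipeline is testable without anyone's raw data.
* **Pipeline & CLI** — `run_pipeline()` goes from CSVs to GraphML, theme
  CSV/JSON, agreement JSON, a deterministic force-directed SVG diagram and
  a consolidated run report; `inst/cli/pte.R` wraps it for the shell.

## Worked example

Simulate a study with 10% sorting noise, build the network, detect the
consensus and validate it against the simulated independent coder:

```r
library(pte)
ss  <- generate_study(synthetic_config(misassignment_rate = 0.1, seed = 42))
net <- build_network(ss$study)
net
#> Co-occurrence network: 94 quotes, 8 raters, 1719 weighted edges (m = 5007)
part <- detect_communities(net, seed = 42)
part
#> Consensus partition (greedy-two-phase): 5 communities, Q = 0.5963 (gamma = 1, seed = 42)
#>   sizes: 19, 19, 19, 19, 18
agreement_report(as_theme_set(part), ss$coder)
#> Agreement vs independent coder (N = 94 jointly covered quotes)
#>   overall: 100.0%   ARI: 1.000   NMI: 1.000
#>   Group 1 -> G1: 100.0%
#>   Group 2 -> G2: 100.0%
#>   Group 3 -> G3: 100.0%
#>   Group 4 -> G4: 100.0%
#>   Group 5 -> G5: 100.0%
```

Despite displacing each quote with probability 0.1 per rater, eight noisy
sorts carry enough shared signal that the detected five communities match
the planted themes exactly (ARI 1 against the planted partition), and the
noise-free simulated coder agrees 100% after optimal alignment. The
modularity Q = 0.60 summarises how much more weight falls inside the
communities than a degree-matched random network would place there.

The same run from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "pte.R", package = "pte"))') \
    simulate --out study/ --noise 0.1 --seed 42
Rscript ... run --sorts study/sorts.csv --corpus study/corpus.csv \
    --coder study/coder.csv --out results/ --seed 42
```

See the vignette (`vignettes/consensus-themes.Rmd`) for the model, the
alignment and denominator conventions, the generator's assumptions, and
known limitations.

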