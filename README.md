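# fluxcost

Constraint-based estimation of metabolic gene dispensability in R, built
around the contrast between two ways of pricing a gene deletion in a
genome-scale flux balance model:

- **Gene-loss cost** `c_GLC(g) = (w_wt − w_ΔR) / w_wt` — the standard FBA
  knockout: every reaction for which gene *g* is a *necessary* prerequisite
  (per the boolean gene-protein-reaction rule, GPR) is blocked
  simultaneously, and the relative drop in the biomass optimum `w` is
  reported. Under this convention isoenzymes — genes joined by `or` in a
  GPR — back each other up completely, so deleting one costs nothing.
- **Function-loss cost** `c_FLC(g) = Σ_{r : g ∈ GPR(r)} (w_wt − w_Δr) / w_wt`
  — the sum of single-reaction removal costs over *every* reaction the gene
  participates in, i.e. the opposite assumption that isoenzymes are
  completely non-redundant, and that a multifunctional enzyme is charged
  for each of its functions.

The package implements everything needed to study the consequences of that
switch: SBML Level 3 (FBC) and COBRA-style JSON model input, GPR parsing and
rewriting (`or` → `and` for the non-redundant assumption), an LP-based FBA
engine with flux-variability blocked-reaction detection, minimal-media
enumeration over alternative carbon × nitrogen sources, per-medium Spearman
correlation of cost metrics against rank-averaged evolutionary rates
(dN/dS), two hybrid cost schemes that isolate which gene category drives
metric differences, and pairwise epistasis prediction
(`ε = w_ij − w_i·w_j`) under both isoenzyme semantics, scored against
experimental genetic-interaction tables (confusion matrices,
precision/recall curves, Fisher enrichment).

Deterministic toy-model generators (`make_scenario_model()`,
`make_random_toy_model()`, `make_synthetic_rates()`,
`make_synthetic_interactions()`) reproduce the canonical GPR scenarios —
enzyme complex, isoenzyme pair, multifunctional enzyme — and build seeded
random networks with graded reaction costs, so the entire pipeline is
testable without external data.

## Worked example

The isoenzyme scenario in its simplest form — one essential reaction gated
by `g1 or g2`:

```r
library(fluxcost)
m   <- make_scenario_model("isoenzyme")
med <- attr(m, "default_medium")

solve_fba(m, med)$objective                     # 10  (wild-type growth)
gene_loss_cost(m, "g1", med)                    # 0   (g2 backs g1 up)
function_loss_cost(m, "g1", med)                # 1   (charged the full reaction cost)
gene_loss_cost(m, "g1", med, semantics = "nonredundant")  # 1
```

A full synthetic study — 200-gene random network, all 10 × 5 carbon ×
nitrogen minimal media, rates generated as a noisy decreasing function of
functional burden:

```r
mod <- make_random_toy_model(fixture_spec(seed = 7))
ms  <- enumerate_minimal_media(mod, attr(mod, "default_medium"),
                               attr(mod, "carbon_exchanges")[1],
                               attr(mod, "nitrogen_exchanges")[1])
ms
#> <media_set> 10 carbon x 5 nitrogen sources -> 50 growth-supporting media

ct    <- cost_table(mod, ms)
rates <- make_synthetic_rates(ct, seed = 7)
kh    <- average_rank_rate(rates)
correlation_distribution(ct, "glc", kh)
#> <correlation_distribution> glc: mean rho -0.633 (sd 0.0318) over 50 media
correlation_distribution(ct, "flc", kh)
#> <correlation_distribution> flc: mean rho -0.895 (sd 0.0255) over 50 media
```

The function-loss cost recovers a markedly stronger anticorrelation with the
planted evolutionary rates than the gene-loss cost, because roughly a third
of the genes sit in isoenzyme sets whose deletions the standard knockout
prices at zero.

Epistasis for the isoenzyme pair flips with the semantics — a predicted
synthetic-lethal interaction under full backup, no interaction once each
single deletion is already lethal:

```r
predict_pairwise(m, data.frame(gene_i = "g1", gene_j = "g2"), med,
                 semantics = "redundant")
#>   gene_i gene_j w_i w_j w_ij epsilon predicted_class
#> 1     g1     g2   1   1    0      -1     synergistic
predict_pairwise(m, data.frame(gene_i = "g1", gene_j = "g2"), med,
                 semantics = "nonredundant")
#>   gene_i gene_j w_i w_j w_ij epsilon predicted_class
#> 1     g1     g2   0   0    0       0            none
```

## Command line

A thin CLI over the same functions lives at `inst/cli/fluxcost.R`
(subcommands `fixtures`, `media`, `costs`, `correlate`, `epistasis`; every
run writes a JSON manifest with input/output digests):

```sh
Rscript inst/cli/fluxcost.R fixtures --scenario random --seed 1 --out out/
Rscript inst/cli/fluxcost.R costs --model out/model.json \
    --config media.json --semantics redundant --out out/costs.tsv
```

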