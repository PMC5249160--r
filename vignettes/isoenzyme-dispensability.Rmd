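---
title: "Gene-loss and function-loss costs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-loss and function-loss costs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcost)
```

## The model and its assumptions

Flux balance analysis (FBA) treats a metabolic network as a linear program:
find steady-state reaction fluxes `v` maximizing the flux through a biomass
pseudo-reaction subject to mass balance `S v = 0` and per-reaction bounds
`α_i ≤ v_i ≤ β_i`. The biomass optimum `w` is the fitness proxy. Three
classes of bound constraints are applied: irreversibility from the model
itself, environmental uptake limits from the medium, and knockout
constraints `α_i = 0 ≤ v_i ≤ β_i = 0` on reactions disabled by a gene
deletion.

Which reactions a deletion disables is decided by the boolean
gene-protein-reaction rule (GPR) attached to each reaction: `and` encodes
protein complexes (every subunit required), `or` encodes isoenzymes (any
one suffices). The **gene-loss cost** blocks exactly the reactions for
which the deleted gene is *necessary* — the rule evaluates false with that
gene absent and every other gene present — and reports
`(w_wt − w_ΔR) / w_wt`. Because an isoenzyme partner always satisfies an
`or`, an isoenzyme's gene-loss cost is identically zero: the model assumes
unlimited backup capacity.

The **function-loss cost** makes the opposite assumption: it sums, over
every reaction the gene appears in (anywhere in the GPR), the cost of
removing that reaction alone. Isoenzymes are thereby treated as completely
non-redundant, and a multifunctional enzyme is charged once per function.
For any gene that is neither an isoenzyme nor multifunctional the two
metrics coincide exactly — a useful internal consistency check that the
test suite asserts on every fixture.

Two **hybrid costs** isolate which category drives differences between the
metrics: hybrid 1 applies the function-loss cost only to multifunctional
genes, hybrid 2 only to isoenzyme-associated genes, with the gene-loss cost
everywhere else.

For genetic interactions, relative fitnesses `w = 1 − c` feed the standard
multiplicative epistasis score `ε_ij = w_ij − w_i w_j`. The non-redundant
assumption is implemented for knockouts by rewriting every `or` to `and`
before the necessity test, so deleting any isoenzyme-set member disables
the reaction. Double knockouts evaluate each GPR with both genes absent —
this subsumes the union of the two single-deletion reaction sets (an
isoenzyme pair jointly falsifies a rule neither falsifies alone), which is
the contract we adopt since per-pair GPR interplay is otherwise
underdetermined.

## Isoenzyme sets on nested rules

Real GPRs nest (`(g1 and g2) or g3`). We define the isoenzyme set of a rule
as the genes *individually sufficient* to satisfy it (the rule evaluates
true with only that gene present), requiring at least two such genes; a
lone sufficient gene is not an isoenzyme. This reproduces the plain
`g1 or g2` case and extends to mixed expressions without special-casing.
`or`-of-complexes rules — where no single gene is sufficient — therefore
contribute no isoenzyme set; this is one defensible reading of a convention
the source data leave open, and the gene-classification machinery keeps it
in one place (`isoenzyme_set()`) should a different reading be preferred.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| uptake cap | 10 mmol/gDW/h | import limit on each primary (carbon/nitrogen) source |
| growth tolerance | 1e-6 | biomass flux at or below this counts as no growth |
| flux tolerance | 1e-9 | fluxes below this magnitude count as zero (blocked-reaction test, knockout shortcuts) |
| prediction ε cutoff | 1e-4 | minimum magnitude for a predicted interaction |
| experimental cutoffs | \|ε\| > 0.08, p < 0.05 | intermediate-stringency interaction call |
| fitness filter | wt + 2 sd | pairs with faster-growing single mutants are excluded (FBA cannot predict fitness gains) |
| essentiality threshold | 0.99 | normalized cost at or above which a gene is called essential |

Costs are clipped to [0, 1] per reaction: deletions cannot improve the FBA
optimum, so small negative values are solver noise. Media in which the wild
type cannot grow are never emitted by the enumeration machinery and are
skipped defensively by the cost table.

## Minimal-media enumeration

Starting from a reference minimal medium (one carbon source, one nitrogen
source, secondary nutrients unbounded), alternative sources for each role
are found by removing that role's exchange and exhaustively substituting
every other exchange reaction at the same uptake cap; substitutions that
restore growth are alternatives. The final media set is all carbon ×
nitrogen pairings that support growth. "Metabolites" are operationalized as
exchange reactions — the model's only environmental interface. A metabolite
able to provide both roles may serve as both in one medium (a flag disables
such pairings); substitutes inherit the cap of the source they replace.

## The synthetic data generator

The random fixture (`make_random_toy_model()`) emulates the structural
features the analyses depend on, not yeast's topology. It uses a hub
architecture: alternative carbon sources feed a carbon pool through
gene-associated conversion reactions of random capacity (5–10; nitrogen
1–3, so either element can be limiting), and core "module" reactions drain
both pools into biomass precursors, every one of which the biomass reaction
requires. A configurable fraction of reactions carries a gene-free bypass
of random partial capacity, so single-reaction removal costs take graded
values in [0, 1] rather than being all-or-none, and source-pathway costs
are medium-dependent (a source's genes only matter in media that use it).
GPRs mix isoenzyme `or`-sets of size 2–3 (30% of genes by default),
`and`-complexes of 1–5 subunits, and 10% multifunctional genes — half added
as an extra required subunit elsewhere, half made the sole catalyst of a
bypass, which plants genuine synthetic-lethal partner pairs for the
epistasis analyses. Defaults (200 genes, 10 carbon × 5 nitrogen sources,
hence a 50-medium grid) are the package's standard study conditions; the
acceptance tests run 20 seeded replicates of them, and the full simulation
completes in minutes on one CPU.

Synthetic evolutionary rates are drawn per species as
`k = exp(−a · burden + N(0, σ))` with `burden` the gene's mean function-loss
cost across media, `a = 3`, `σ = 0.6`, five species, and 10% of gene×species
entries deleted to emulate missing orthologs. The anticorrelation between
burden and rate is planted by construction; what the tests genuinely probe
is *which cost metric recovers it better* — the gene-loss cost sees the same
rates but prices isoenzymes at zero, so its per-medium Spearman ρ is
reliably weaker. Rates are log-normal around a deterministic trend; since
all correlation machinery is rank-based, the marginal shape is immaterial.

What passing these tests does *not* show: that real dN/dS ratios behave
like the generator (real rates are noisier, phylogenetically structured,
and not a function of any model quantity), that real networks have the
fixture's cost spectrum, or that experimental interaction screens resemble
the synthetic tables (built from the model's own non-redundant predictions
plus Gaussian noise — useful for self-consistency, labelled synthetic
throughout).

## Numerical choices

The LP engine is a dense bounded-variable two-phase primal simplex
(compiled) with an explicit basis inverse, Dantzig pricing and a Bland's-
rule fallback against degenerate cycling — FBA problems are heavily
degenerate, so the fallback is load-bearing. Optimality uses a reduced-cost
tolerance of 1e-7, pivots below 1e-9 are rejected, and basic values are
refreshed periodically against roundoff drift. Infinite bounds are clamped
to ±1e6. Infeasible knockout programs are reported as zero growth (the
mutant cannot grow); only objective values are contractual — flux vectors
at degenerate optima are not unique. Two exact shortcuts keep cost tables
fast: a reaction carrying zero flux at the wild-type optimum has zero
removal cost (that optimum remains feasible), and a gene whose knockout set
is a single reaction reuses that reaction's cost. The vertex-enumeration
brute force used as the LP oracle in the tests shares none of this code.

Blocked reactions are detected flux-variability style — a reaction is
blocked when its maximum and minimum achievable flux are both zero in every
tested medium (default: the enumerated media plus an all-open environment)
— and genes associated only with blocked reactions are purged from all
analyses.

Tie-breaking: within-set fast/slow isoenzyme labels break rate ties by
identifier order with a warning; a gene in several sets takes its majority
label, ties resolved in the order fast, slow, neutral. Both rules are
arbitrary conventions, logged so downstream users can see when they fired.

## Known limitations

- Backup between isoenzymes is binary (complete or absent); partial,
  condition-dependent backup, enzyme kinetics and expression constraints
  are out of scope.
- The function-loss sum deliberately over-counts overlapping functions; an
  alternative maximum-over-reactions aggregation is available
  (`aggregate = "max"`) but off by default.
- Media contain exactly one source per role; multi-source environments are
  only supported as manually defined rich media.
- The epistasis machinery classifies predictions by magnitude only; FBA is
  deterministic, so no p-value analogue is applied on the prediction side.
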