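---
title: "Selecting a key group of effective components by network pharmacology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting a key group of effective components by network pharmacology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A multi-herb formula contains hundreds to thousands of chemical
components, of which only a subset drives the therapeutic response in a
complex disease. `kgec` implements a network-pharmacology strategy for
finding that subset — the *key group of effective components* (KGEC) —
by linking three layers of evidence: a protein–protein interaction (PPI)
network, a weighted set of pathogenic genes, and per-component target
predictions. The method's premise is that therapeutically relevant
targets are not the raw predicted targets but the *hubs* of the network
formed jointly by targets and pathogenic genes, and that components
should be ranked by how much of that hub set they cover.

## The model, step by step

**1. Weighted disease gene network.** Let `Net_ppi = {N, E}` be the
undirected simple PPI graph and `D_dis` the pathogenic genes, each
weighted by its literature-report count. The weighted gene regulatory
network is the PPI subgraph induced on `D_dis ∩ N`; pathogenic genes
absent from the PPI carry no interaction evidence and are dropped (their
number is logged). `build_weighted_network()` implements this; matching
is exact and case-sensitive after whitespace trimming — alias resolution
is out of scope and must happen upstream.

**2. ADME screening.** Components are screened on three TCMSP-style
properties: oral bioavailability (OB, %), Caco-2 permeability (a
monolayer transport-rate score) and drug-likeness (DL). The defaults are
the standard herbal-screening cutoffs: OB ≥ 30 %, Caco-2 > −0.4,
DL ≥ 0.18. Boundary semantics matter and are asserted in the tests: OB
and DL are inclusive, Caco-2 is strict (a score at −0.4 means *not*
permeable). A `whitelisted` flag admits curator-selected components that
fail the rules but are retained for high content or known bioactivity;
it is an explicit column, never a hard-coded name list. Missing
properties reject a non-whitelisted component by default
(`na_policy = "reject"`), because an unscreenable component is an
unscreened one; `"pass"` is available when the table is known to be
sparse but trusted.

**3. Component–target network.** Target predictions from several tools
are merged by plain union, deduplicated by (component, gene), with the
supporting tool set kept as provenance. No voting rule is applied by
default (`min_tools = 1`): the prediction tools have complementary
coverage and an intersection rule discards most of the signal; stricter
users can raise `min_tools`. The C–T network's two mean degrees —
edges/components and edges/targets — are the standard summary of
multi-target character.

**4. The disease–targets–components network and the optimization
space.** With `L_tar` the predicted targets of active components and
`L_dis` the mapped pathogenic genes, the disease–targets–components
(DTC) network is the PPI induced on `L_tar ∪ L_dis`. Although the name
mentions components, the graph contains only proteins: component
membership is carried by the C–T network, not by graph nodes. With
`k` nodes and average degree `D_avg = (Σ d_i)/k = 2|E|/k`, the
optimization space is

    OptS = { i in DTC : d_i > D_avg },

the *strictly* above-average (hub) nodes, called the effective
proteins. Ties at exactly `D_avg` are excluded — "more than average"
is taken literally, and the strict rule also guarantees `OptS` is a
proper subset whenever the degree distribution is non-constant. On a
degree-regular graph no node qualifies and `extract_optspace()` raises
an error rather than returning an empty space silently.

Two edge rules are offered because "the passed nodes and their edges
were kept" is ambiguous. The default, `induced`, keeps an edge only if
*both* endpoints are hubs, making the optimization space a
self-contained network of effective proteins — which is how it is used
downstream. The alternative `incident` rule keeps every edge touching a
hub; the node table remains the hub set, with non-hub neighbours
appearing only as edge endpoints.

Effective proteins fall into three categories by membership:
*essential common* (`L_tar ∩ L_dis`), *disease-specific*
(`L_dis \ L_tar`) and *component-specific* (`L_tar \ L_dis`). The
categories partition the space exactly; this is asserted on every run.

**5. Contribution index and KGEC.** For component *i*, let `λ_i` be its
targets among the `W` effective proteins, `ω_i` its total target count
and `ν_i = |λ_i|`. The contribution index is the coverage fraction

    CI_i = ν_i / W.

Two selection devices are computed:

* the **dynamic 0-1 knapsack** maximizing `Σ ν_i` subject to
  `Σ ω_i ≤ W`, with the textbook DP
  `c[i, ω] = max(c[i−1, ω], ν_i + c[i−1, ω−ω_i])`, `c[0, ·] = c[·, 0] = 0`,
  a strictly-greater update (so ties prefer earlier components) and
  backtracking for one optimal subset;
* the **coverage accumulation curve**: components are ordered and the
  *union* of their `λ_i` is accumulated, so overlapping target sets are
  not double-counted. The KGEC is the shortest prefix whose union
  coverage reaches the threshold (default 0.90).

The default KGEC cut uses the accumulation curve rather than the
knapsack value, because the quantity being reported — "x % target
coverage of effective proteins" — is a union coverage, which the scalar
`Σ ν_i` objective overstates whenever components share targets. The DP
optimum is reported alongside. Two orderings are available:
`ci_desc` (CI descending, ties by component id — the default, matching
a per-component CI ranking) and `greedy_marginal` (classic greedy
maximum coverage, which dominates the CI ordering at every prefix; this
dominance is property-tested). The capacity default is `W` itself, the
number of effective proteins, the only stated choice for this model.
All tie-breaks, everywhere, are by component id ascending, so runs are
reproducible to the byte.

**6. Enrichment validation.** Over-representation analysis uses the
upper-tail hypergeometric test: for a query of size `n` drawn from a
universe of size `N`, a pathway with `K` members and overlap `k` gets
`p = P(X ≥ k)`, `X ~ Hypergeometric(K, N−K, n)`. The significance
criterion is raw `p < 0.05` by default — the convention of the
enrichment tools this emulates — with Benjamini–Hochberg adjustment
always reported and optionally driving the call (raw-p ORA is
statistically permissive; the BH column is there to say so). The
universe defaults to the union of the GMT's genes, overridable when a
genome-wide background is preferred. The validation statistic is
*pathway coverage*: of the pathways enriched for the pathogenic genes,
the fraction also enriched for the effective proteins (or the KGEC
targets) — `|A ∩ B| / |B|` over pathway name sets.

## The synthetic-data generator

`generate_fixture()` writes the five inputs — PPI edge list, weighted
disease genes, component table, per-tool target predictions, GMT
pathways — from a single seeded RNG stream, in a fixed order, so a
fixed seed yields byte-identical files. Its defaults are the package's
desk-scale study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_ppi_genes` | 500 | large enough for hub structure, small enough for fast tests |
| `ppi_mean_degree` | 6 | sparse scale-free-like interactome density |
| `n_disease_genes` | 100 | a fifth of the genome, as disease gene sets are |
| `weight_max` | 50 | literature-report counts span 1–dozens |
| `n_components` | 60 | a screened formula's component count, desk scale |
| `targets_mean`, `targets_dispersion` | 30, 5 | negative-binomial targets per component; the mean matches the ~30 targets/component of screened herbal components, the dispersion makes promiscuous outliers |
| `frac_targets_in_disease` | 0.3 | enough target/disease overlap for a non-trivial essential-common category |
| `n_pathways`, `pathway_size` | 25, 10–40 | KEGG-like set sizes |

The PPI is a preferential-attachment graph with duplicate edges
collapsed and self-loops dropped — only "undirected simple graph with
heavy-tailed degrees" matters downstream, not the biology of any
particular interactome. Gene symbols are synthetic (`G000001`, …) to
avoid implying real genes. Pathway membership is weighted 6:3:1
(disease gene : target : other) so that disease-relevant enrichment
structure exists for the coverage statistic to measure.

What the generator does **not** emulate: database-specific biases,
correlated tool errors in target prediction, gene-family structure,
pathway overlap hierarchies, or the sizes of real interactomes. Passing
tests on fixtures therefore demonstrates algorithmic correctness and
determinism, not recovery of any published network's node counts —
those depend on database snapshots and are treated as shape references
only.

`simulate_enrichment_case()` plants a known enriched pathway: 15 of 40
query genes are drawn from the first pathway (size 30, universe 500),
the rest uniformly. The expected chance overlap for a random pathway is
40·30/500 = 2.4 genes, so the planted pathway should essentially always
attain the minimum p-value; the suite requires recovery in ≥ 95 % of
200 seeds.

## Numerical choices

* Proton mass 1.00728 Da for `[M+H]+`/`[M−H]−` adducts; the two ions of
  the same molecule differ by exactly 2 × 1.00728.
* Average masses use IUPAC conventional standard atomic weights;
  monoisotopic mode uses most-abundant-isotope masses. MS
  identification tables mix the two styles, so `adduct_mz()` operates
  on whatever MW is supplied rather than recomputing it.
* Ion-label inconsistencies in an identification table (a printed m/z
  one unit *above* the MW in a row labelled `M−H`) are flagged by
  `check_adduct_consistency()`, never silently corrected.
* The knapsack DP table is integer-indexed over the ω dimension; target
  counts are integers so no scaling is needed.
* Degenerate inputs fail loudly: empty PPI files, empty disease/PPI
  intersections, degree-regular DTC graphs, empty reference pathway
  sets and out-of-range thresholds are all errors with specific
  messages, tested as such.

## Problem sizes used by the test suite

The suite runs the full pipeline on 500-gene / 60-component fixtures
(seconds per run), checks the knapsack DP against exhaustive subset
enumeration on 100 random instances with up to 15 components, verifies
ORA p-values against direct binomial-coefficient tail sums to 1e−12,
and checks generator convergence at 2000 components. These sizes were
chosen to exercise every code path at interactive speed.

## Limitations

* Gene identifiers are matched verbatim; no alias or ortholog mapping.
* The enrichment module does no ontology-graph propagation; GO analysis
  is treated as ORA over a term→genes GMT.
* Published node/edge counts from any specific database snapshot are
  not reproducible from synthetic data and are not a package target.
* Raw-p significance at 0.05 is deliberately permissive; use
  `adjust = "BH"` for defensible calls on real data.
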