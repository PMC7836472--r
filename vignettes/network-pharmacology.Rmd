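---
title: "Methods: the netpharm inference chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the netpharm inference chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem and the model

Network pharmacology treats a multi-compound herbal preparation as a
perturbation acting on many protein targets at once. Rather than a single
dose-response model, the object of inference is a chain of discrete
structures:

1. **ADME screen.** Each herb component carries two predicted druggability
   covariates: oral bioavailability (OB, a percentage on the 0–100 scale)
   and drug-likeness (DL, unitless on [0,1]). A component is *active* when
   `OB >= ob_min` and `DL >= dl_min`, both inclusive. The conventional
   thresholds, which are the package defaults, are `ob_min = 30` and
   `dl_min = 0.18`.

2. **Target assembly.** The herb target set is the union of predicted
   targets over the active ingredients. Disease genes are merged from one
   or more portal-style sources. The intersection of the two sets is the
   putative therapeutic-target set. All symbols pass through a single
   deterministic normalizer (trim, Greek-to-Latin transliteration, optional
   alias map, uppercase); no nomenclature service is consulted, so results
   are reproducible offline.

3. **Ingredient–target (I–T) network.** The two-mode graph whose edges join
   active ingredients to therapeutic targets. An ingredient's degree counts
   how many targets it reaches; a target's degree counts how many
   ingredients converge on it. Nodes left without any edge after the
   restriction are excluded, which means an active ingredient whose every
   predicted target lies outside the disease overlap does not appear in the
   network.

4. **PPI network.** A scored interactome (STRING-style combined scores,
   natively 0–1000, normalized here to [0,1]) is restricted to the
   therapeutic targets, filtered at a minimum confidence (default 0.4,
   inclusive), and proteins left without interactions are removed. Hubs are
   ranked by degree with alphabetical tie-breaking so rankings are
   deterministic.

5. **Over-representation analysis (ORA).** For a query of `n` genes drawn
   from a background of `N`, a term annotating `K` background genes, and an
   observed overlap `k`, the p-value is the hypergeometric upper tail

   $$P(X \ge k) \;=\; \sum_{i=k}^{\min(n,K)}
     \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

   accumulated in log-space (via `lchoose` and log-sum-exp), so tails far
   below double-precision underflow of any single term are still exact.
   Benjamini–Hochberg step-up adjustment converts the p-values to FDR
   estimates. The *significance filter applies to the raw p-value*
   (`p <= 0.01` by default) with the FDR reported alongside, which mirrors
   how such studies filter their tables.

6. **Pathway integration.** The published analog of this stage is manual
   curation ("pathways not directly related to the disease were
   eliminated"). That judgment cannot be algorithmized, so it is
   operationalized as an explicit whitelist — by default the eight
   bladder-cancer-relevant KEGG pathways of `bc_pathway_whitelist()` —
   matched against significant pathways by id or case-insensitive name
   keyword. The model records, per retained pathway, which therapeutic
   targets it contains.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `ob_min` | 30 | percent | conventional TCMSP druggability cut |
| `dl_min` | 0.18 | unitless [0,1] | conventional TCMSP druggability cut |
| `ppi_min_confidence` | 0.4 | unit score | STRING "medium confidence"; inclusive |
| `p_cutoff` | 0.01 | probability | raw-p significance filter for ORA |
| `top_terms_n` / `top_proteins_n` | 20 / 30 | count | reporting depth for terms and hubs |

All comparisons at thresholds are inclusive (`>=` / `<=`): ties are
retained, matching the conventions the thresholds come from.

## Numerical and design choices

* **Background universe for ORA.** Defaults to the union of all genes
  annotated anywhere in the collection, overridable by an explicit
  background set. Query genes absent from the background are dropped from
  the effective query size `n` (with a message), keeping the
  hypergeometric model coherent.
* **FDR universe.** BH adjustment runs within one annotation collection at
  a time, across the terms actually tested (those with `k >= 1`). Distinct
  collections (GO:BP vs KEGG, say) are corrected separately, mirroring
  per-analysis result tables.
* **Betweenness.** Reported unnormalized (raw shortest-path pair counts,
  each unordered pair counted once) with an optional normalized variant.
  For the two-mode I–T network it is computed on the combined graph, the
  behavior of desktop network tools. The implementation is `igraph`'s
  exact Brandes algorithm; the test suite checks it against an independent
  all-pairs shortest-path enumeration oracle, exhaustively over every
  labelled graph on up to 5 nodes (an exhaustive sweep over larger node
  counts is combinatorially impossible — there are $2^{28}$ labelled
  8-node graphs — so 6–8-node graphs are covered by seeded random
  sampling).
* **Duplicate scored edges** keep the maximum score: conservative under a
  `>=` filter. Self-loops are dropped.
* **Tie-breaks.** Degree rankings: degree descending, then symbol
  ascending. Enrichment rows: p ascending, then term id ascending. Both
  make regression output byte-stable.
* **Degenerate inputs.** Empty screens, empty gene lists and empty
  enrichment results are values, not errors; an I–T restriction that
  removes every edge, or a query entirely outside the background, aborts
  with a named validation error because every downstream quantity would be
  vacuous.

## The synthetic-data generators

`sim_config()` fixes every generator parameter plus one master seed; each
generator derives a private sub-seed, so a stage rerun in isolation
reproduces its output byte-for-byte. Defaults encode the study conditions
of a single-herb analysis:

* **Ingredients** (`gen_ingredients`): 39 records. OB is truncated
  lognormal on (0, 100] (`meanlog = log 25`, `sdlog = 0.6`), DL is Beta
  (1.5, 3) — families chosen to match the ranges seen in published herb
  tables (OB roughly 37–81, DL 0.28–0.81 among actives). Each record first
  draws a Bernoulli(`active_fraction`, default 7/39) druggability flag and
  then samples OB/DL from the corresponding truncated region, so the
  expected pass-rate of the default screen equals `active_fraction`
  exactly while the marginals keep their families.
* **Target map** (`gen_target_map`): one designated hub ingredient covers
  `hub_fraction` (default 1.0) of the 84-gene target universe — the
  quercetin-like, near-universal binder — while other actives draw degrees
  uniformly from 1–11, creating the multi-ingredient (degree ≥ 2) genes.
* **Disease genes** (`gen_disease_genes`): 7,624 symbols sharing exactly
  `ceiling(overlap_fraction × |herb targets|)` genes with the herb set
  (default fraction 77/84), built by construction rather than by chance.
* **Interactome** (`gen_ppi`): Erdős–Rényi background (`p = 0.4`, scores
  uniform on [0,1]) plus one planted hub wired to 52 partners with scores
  in [0.4, 1], so the hub survives the default filter with its full
  degree. With 77 proteins the background degrees concentrate near
  `76 × 0.4 × 0.6 ≈ 18`, far below the planted 52, which is why hub
  recovery is essentially certain.
* **Annotation** (`gen_annotation`): 89 terms of 10–80 genes drawn from
  the background, plus one planted 80-gene term sharing 40 genes with a
  designated query.

What the generators *do not* emulate: real interactome topology (no
scale-free tail beyond the single planted hub), correlated term
memberships (GO's nesting), symbol aliasing noise, or any chemistry.
Passing tests on synthetic data therefore demonstrate the correctness of
the computations and the recoverability of planted structure — not that
any particular biological conclusion transfers to live database
snapshots.

## The packaged study fixture

`snigrum_fixture()` carries a desk-scale bundle shaped like the published
*Solanum nigrum* / bladder-cancer analysis: the seven printed active
ingredients (values as printed), 32 synthetic screen-failing rows
completing the 39-component table, a 100-row pair table over 77 genes
reconstructed from the printed degree facts (hub ingredient degree 77,
beta-carotene 11, diosgenin 9, NCOA2 degree 4, fourteen degree-2 and
three degree-3 genes), a 7,624-symbol disease list, and a deterministic
synthetic interactome realizing the recorded PPI topology (77 proteins,
697 interactions, IL6 degree 52, and the eight other published hub
degrees) via a frozen graphical degree sequence and
`igraph::realize_degseq`. One arithmetic consequence worth knowing: the
printed degree facts force one active ingredient (solanocapsine) to have
no edge among the 77 overlap genes, so the I–T network contains six
ingredient nodes, not seven.

Quantities that depend on live database releases — the 84-gene predicted
target set, the exact disease-list contents, the interactome edge set,
and counts of significant GO/KEGG terms — are represented only at this
fixture/regression level; the package never claims to re-derive them.

## Statistical validation design

The test suite validates every statistical primitive against an
independent oracle: hypergeometric tails against exhaustive enumeration of
all draws for every `N <= 12` (tolerance 1e-12) and against `phyper` at
larger sizes; BH against a quadratic hand-stepped oracle on 1,000 random
vectors and against `p.adjust`; betweenness against the path-enumeration
oracle described above; set operations against brute-force unions and
intersections.

Two calibration properties deserve comment:

* **Planted-term recovery** uses the fixed design background 2,000 /
  query 60 / planted term 80 sharing 40: the planted overlap is so far
  into the tail (expected null overlap ≈ 2.4) that rank 1 is expected in
  ≥ 99 of 100 seeded runs.
* **Type-I control** checks that, for a query drawn uniformly at random
  from the background, the fraction of null terms with raw `p <= 0.01`
  sits within 3 standard errors of 0.01. Because the hypergeometric test
  is discrete, its attained level is *below* nominal, and for small
  ORA-typical designs (background ~2,000, query ~100) the gap is large
  (attained ≈ 0.006–0.008) — a structural property of discrete tests, not
  an implementation flaw. The validation design therefore uses sizes at
  which the null distribution is nearly continuous: background 20,000,
  query 2,000, twenty null terms of 1,000–4,000 genes, 500 simulations
  (exact attained level ≈ 0.0091, inside the band). These sizes are
  realistic for genome-scale annotation but deliberately at the dense end.

Problem sizes throughout the suite (5-node exhaustive graph sweeps,
1,000 conservation networks of ~20 targets, 100-simulation recovery runs,
500-simulation calibration) are the package's chosen trade-off between
evidential strength and a suite that runs in a couple of minutes on one
core.

## Known limitations

* Symbol normalization is syntactic; without a user alias map, distinct
  aliases of one gene remain distinct.
* ORA assumes exchangeable genes; no correction for gene length, linkage
  or annotation bias, and no GO ancestor propagation (out of scope).
* The pathway "integration" step is a reproducible stand-in for expert
  curation, exactly as configurable — and exactly as subjective — as the
  whitelist it is given.
* Betweenness on weighted graphs is not offered; confidence scores are
  used only for filtering, never as edge weights.
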