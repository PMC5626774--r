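---
title: "CoDReS: model, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CoDReS: model, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codres)
```

## The model

`codres` re-ranks candidate inhibitor drugs from signature-matching
repurposing screens. The unit of analysis is a *stage contrast* — one
disease-vs-reference comparison (e.g. advanced disease vs normal tissue) —
and within each contrast the evidence for a drug is a set of connectivity
scores in $[-1, 1]$, one per (tool, gene-selection method, dataset)
combination. Strongly negative scores mean the drug's expression signature
opposes the disease signature.

Four components enter the composite, each normalized to $[0,1]$ **within
the analyzed batch** of drugs:

* **Inhibition.** Records qualify when score $\le -0.5$. A drug's raw
  aggregate in a stage is $\sum |s|$ over its qualifying records across
  tools, methods and datasets; aggregates are divided by the stage maximum.
  Sum-of-magnitudes is the only reading of "aggregating the total
  inhibition scores" under which the normalized column is positive and at
  least one drug per stage reaches 1, as the published tables show, so
  that is what the package implements.
* **Structural druglikeness.** $1 - v/v_{\max}$ from rule-violation counts
  $v$ reported by a property-prediction tool. No violations $\Rightarrow$
  exactly 1; the worst offender in the batch $\Rightarrow$ exactly 0. An
  all-zero batch scores all 1 (there is no penalty to normalize).
* **Functional relevance.** The mean of a drug's per-target-gene
  enrichment scores (each in $[0,1]$), divided by the batch maximum. A
  drug with no scored targets has mean 0, not an error — the published
  table contains such drugs.
* **Side effects.** Raw burden $S = \sum_{i=1}^{8} N_i \cdot i$ over eight
  severity classes with weight equal to the class index, then
  $1 - S/S_{\max}$ over the *known* profiles. Drugs whose side effects are
  unknown are pinned to 0, the worst score, even though a known drug with
  zero recorded side effects scores 1. The discontinuity is deliberate and
  inherited from the procedure being mirrored: absence of safety evidence
  is treated as risk, not as safety.

The composite is
$\mathrm{CoDReS} = w_{is}\,I + w_{ss}\,St + w_{fs}\,F + w_{ses}\,Se$
with non-negative weights summing to 1, hence $\mathrm{CoDReS}\in[0,1]$
and strict monotonicity in every component with positive weight.

Batch-relativity is a property, not a bug: adding a drug with a larger
$v$ or $S$ to a batch changes every other drug's normalized score. The
test suite pins this behaviour explicitly so it is never "fixed" silently.

## Consensus filtering

Upstream of scoring, two set filters reduce tool noise. Within each
dataset, a drug must be hit (score $\le -0.5$) by at least
`min_tools = 2` of the 3 tools — *distinct tools*: a tool hit under both
gene-selection methods still counts once. Across the datasets of one
stage, the drug must appear in at least `min_datasets = 2` of the 3
per-dataset union lists. Both filters are monotone in their thresholds,
which the suite verifies against a brute-force enumeration oracle.

Consensus membership and the scored universe are decoupled. The published
worked example scores 15–19 drugs per contrast — the union of drugs
carried into the scoring step — while the stated per-stage discovery
counts are 5/7/10/6; the two universes are not reconcilable from the
source text, so `stage_inhibition()` scores every drug with a qualifying
record and flags the consensus members, and the caller chooses.

## Tunable parameters

| parameter | default | where | why this default |
|---|---|---|---|
| `score_max` | −0.5 | `consensus_config()` | the published qualification threshold; boundary *included* because the explicit "≤ −0.5" inequality appears in the filtering rule (the surrounding prose also says "below −0.5"; `strict = TRUE` gives that reading) |
| `min_tools`, `min_datasets` | 2, 2 | `consensus_config()` | "2 out of the 3" tools/datasets |
| `n_up`, `n_down` | 150, 150 | `signature_config()` | input-size limit of connectivity-map query tools |
| `p_max` | 0.05 | `signature_config()` | strict `<`, matching the printed "(p-value < 0.05)" |
| weights | 0.4/0.2/0.2/0.2 | `codres_weights()` | the published drug-mining strategy: downgrade raw potentiality (0.4), split suitability equally (3 × 0.2). Weights are a config field, not a constant — choosing them is framed as a researcher decision |
| `cut_height` | 1.0 | `cluster_config()` | the published dendrogram threshold |

## Clustering

Structural redundancy among top-ranked drugs is handled by hierarchical
clustering of binary fingerprints under the **Soergel distance**
($1-$ Tanimoto for bit vectors — a proper metric, property-tested) with
**Ward linkage**, cutting the dendrogram at height 1 and keeping the
highest-CoDReS member of each flat cluster as its representative.

Ward's criterion on a non-Euclidean distance is mathematically improper;
the package applies the Lance–Williams Ward update directly to the
supplied Soergel distances anyway, because that is what the mirrored
clustering server does — fidelity to the procedure over metric purity.
The agglomeration is implemented in the package itself with a
deterministic first-minimum (index-based) tie-break; `stats::hclust`
(`ward.D`) serves as an *independent* reference oracle in the tests, on
random matrices where ties have probability zero. "Clustering threshold
of 1" is read as the cut height; a fixed-cluster-count alternative can be
obtained by cutting at any height returned in the merge tree.

The fingerprint type and bit length behind the published dendrograms are
unstated, so the published cluster memberships are unreachable by
construction; clustering correctness is validated on synthetic
planted-partition fixtures instead.

## Synthetic data: what it does and does not establish

The generators in `synth_tool_scores()`, `synth_fingerprints()` and
`synth_deg_table()` are pure functions of their seed (the global RNG
stream is saved and restored) and return their planted answer alongside
the data.

* `synth_tool_scores()` emulates the *combinatorics* of a 3-tool ×
  3-dataset screen: a planted fraction (default 0.5) of drugs receives
  qualifying scores (uniform in $[-1,-0.6]$) in exactly 2 tools within
  each of 2 datasets; the rest are silent or single-tool hitters, which
  can never pass the tool consensus. It does **not** simulate
  connectivity-map biology — no cell lines, no signature structure, no
  correlated tool errors. A green consensus test establishes the set
  logic, not the biology.
* `synth_fingerprints()` plants `n_clusters = 3` prototype bitstrings of
  `n_bits = 256` fair-coin bits and flips each member bit independently
  with `flip_prob = 0.01`. Expected within-cluster Soergel distance is
  then about 0.04 against a between-cluster distance near 0.7, i.e.
  within-noise far below between-separation — the regime the recovery
  criterion states. Real fingerprints have correlated bits and uneven
  densities; recovery on this fixture validates the algorithm, not
  chemical clusterability.
* `synth_deg_table()` draws significance uniformly (fraction 0.3 below
  the cutoff) and fold changes $\mathcal{N}(0, 2)$, carrying its own
  top-gene answer key. It does not model probe-level structure or
  p-value/fold-change correlation.

## Numerical choices and degenerate inputs

* **Golden-table tolerance ±0.001.** The packaged component and
  inhibition tables are transcribed at the source's 3-decimal precision,
  so recomputed composites can differ from printed ones by up to half a
  unit in the third decimal (one row, rotenone in the stage 2 vs stage 1
  block, computes to 0.3246 against a printed 0.324). Re-ranking shifts
  are still required to match *exactly*.
* **Ties.** Ranking ties break alphabetically on the canonical drug name;
  this reproduces the published ordering of the one observed inhibition
  tie (azacitidine before etoposide) and makes every ranking
  deterministic. Fold-change ties in gene selection break alphabetically
  too; best-p deduplication of repeated genes happens *before* the top-N
  cut, with ties on p broken by larger |fold change|.
* **Rendered precision.** Written tables carry each real column twice:
  rounded half-up at 3 decimals (the source's precision) and at full
  machine precision, so round-trips are lossless.
* **Degenerate batches.** All-zero violation batches score all 1; all
  means zero ⇒ all functional scores 0; all profiles unknown ⇒ all 0
  with no division; a pair of all-zero fingerprints has Soergel distance
  defined as 0 with a warning; `normalize_inhibition()` on an empty map
  is an error.
* **Name canonicalization.** Lowercase, trim, collapse internal
  whitespace — idempotent, and exact matching only. No synonym or fuzzy
  resolution: the source is silent on cross-tool name reconciliation, and
  fuzzy merging risks false joins. This is this package's explicit
  choice.
* **Discordant genes.** A gene up-regulated under one selection method
  and down-regulated under the other (or reaching cross-dataset consensus
  in both directions) is dropped from both lists with a warning; the
  source never addresses the case.

## Known limitations

* The published per-stage discovery counts (5/7/10/6), the identities in
  the discovery and representative tables, and the published cluster
  memberships depend on external services and databases as they stood at
  analysis time (2015 versions); they are out of reach by construction
  and are covered by property suites instead.
* Per-drug violation counts behind the structural column are not printed;
  the shipped `derived_violations()` fixture is *inferred* (consistent
  with a batch maximum of 16) and clearly labelled synthetic.
* The four per-experiment pathway lists are transcribed from a flattened
  table whose column boundaries are ambiguous in places; the
  transcription honours every explicit statement in the source text and
  reproduces the stated five-pathway core, but individual column
  assignments of two duplicated entries are judgement calls.
* No differential-expression computation, no enrichment computation, no
  fingerprint generation from structures, and no web clients: all
  external-tool outputs enter as tables, which is what makes the pipeline
  reproducible offline.
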