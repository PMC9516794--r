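---
title: "Statistical-network pre-processing of DEG lists: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical-network pre-processing of DEG lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degnet)
```

# The method and its assumptions

degnet consumes four inputs — a per-gene differential-expression table
(symbol, p, adjusted p, log2 fold change), a log2 expression matrix with
case/control labels, a protein–protein interaction (PPI) edge list, and a
GMT pathway collection — and produces, per regulation direction, a small
"relevant" gene set and its hypergeometric pathway over-representation
table.

The pipeline assumes that (i) the DEG table and the expression matrix
describe the same study, joined on uppercase-trimmed gene symbols;
(ii) the expression values are on a scale where rank comparisons between
two genes' per-sample values are meaningful (log2 intensities or log-CPM
both qualify); and (iii) co-regulated genes have similar per-sample value
distributions, so a *failure* to reject the Kruskal–Wallis null for a
gene pair is evidence of co-behaviour. The last assumption is the crux of
the similarity stage: the Kruskal–Wallis p value is repurposed as a
similarity score, with p ≥ 0.005 creating a network edge. Genes on very
different absolute expression levels will never connect under this score
even if perfectly correlated — rank correlation is *not* what is being
measured, distributional similarity is.

## Stage by stage

1. **Filtering** keeps rows with adjusted p ≤ `p_threshold` and
   |log2FC| ≥ `lfc_threshold`, both boundaries inclusive. Duplicate
   symbols collapse to one record (smallest p, ties by larger |log2FC|,
   then probe id — deterministic). The up/down split follows the sign of
   log2FC and is disjoint by construction.
2. **Similarity networks** are built per branch from pairwise
   Kruskal–Wallis tests on the case samples (configurable). The
   statistic is computed in the variance-of-ranks form
   `K = (N−1)·SSB/SST` on midranks, which is algebraically the
   tie-corrected form of the classical `12/(N(N+1))·ΣR²/n − 3(N+1)`
   statistic; p values come from the chi-square approximation with
   g − 1 degrees of freedom. When every observation is identical the
   statistic is defined as 0 (p = 1). The chi-square approximation is
   used at all sample sizes — at the minimum enforced group size of 2 it
   is rough, but it is applied uniformly to every pair, and only the
   comparison of its p value against one fixed threshold matters here.
3. **Essential genes** are the nodes with closeness centrality at or
   below the network mean. Closeness is component-scaled
   (Wasserman–Faust): `CC(v) = ((n_v−1)/Σd)·((n_v−1)/(n−1))` with `n_v`
   the component size, because similarity networks are frequently
   disconnected and raw per-component closeness would not be comparable
   under one global average. Distances are unweighted hop counts; the
   p-value edge weights carry no distance semantics. Isolated nodes score
   0, which places them below any positive average — they are therefore
   always "essential". Note the rule as stated keeps the *peripheral*
   side of the network; `invert_cc_rule = TRUE` flips it to ≥ for
   sensitivity analysis, and on near-complete similarity networks (the
   common case for a tightly co-regulated branch) the two rules coincide
   because all closeness values are equal.
4. **PPI expansion** intersects the essential set with the PPI node set,
   then takes the hop-`radius` (default 1) neighborhood; the community
   subgraph is induced on those members. Scores in the next stage are
   computed on this induced subgraph, not the full PPI — the selection is
   made "from the neighborhoods", and full-PPI centralities would be
   dominated by hubs that have nothing to do with the branch.
5. **Bottleneck selection.** Bottleneck centrality is the
   shortest-path-tree load score: for every root, grow a BFS tree over
   the root's component and give one point to every non-root node whose
   subtree holds more than a quarter of the tree's nodes. BFS neighbor
   expansion is pinned to lexicographic symbol order so parents, subtree
   sizes and hence scores are reproducible across runs and platforms.
   The threshold is a quarter of the *tree* (component) size, so
   disconnected communities score each component on its own scale.
   Selection keeps scores strictly above the community mean; if that set
   is empty (all scores equal — e.g. a union of symmetric components)
   the rule falls back to ≥ with a logged message rather than silently
   emptying the pipeline.
6. **Enrichment** is the upper-tail hypergeometric test (observed
   overlap included), with Benjamini–Hochberg and Bonferroni corrections
   over all tested pathways and deterministic ranking (p, then larger
   overlap, then pathway id). The default universe is the set of genes
   annotated to at least one pathway; a user background (e.g. all array
   genes) is intersected with that universe when supplied. The exported
   TSV adds |log2 p| presentation columns computed from the values as
   reported (3 significant digits).

# Parameters

| key | default | meaning |
|---|---|---|
| `p_threshold` | 0.005 | DEG significance cutoff (adjusted p by default) |
| `lfc_threshold` | 1.5 | minimum \|log2 fold change\| |
| `use_adjusted_p` | TRUE | filter on FDR-adjusted vs raw p |
| `similarity_threshold` | 0.005 | minimum KW p value for a similarity edge |
| `sample_scope` | "cases" | samples used by the pairwise KW tests |
| `invert_cc_rule` | FALSE | flip the closeness selection to ≥ average |
| `radius` | 1 | PPI neighborhood hop radius |
| `combined_mode` | "union" | combined branch: union of relevant sets, full re-processing, or none |
| `dedup_policy` | "min_p" | duplicate-symbol survivor rule |

Two points deserve comment. The filtering threshold and the similarity
threshold are numerically equal (0.005) but are independent knobs — one
bounds a significance level, the other bounds a *similarity* score, and
there is no reason they must move together. And the default `sample_scope`
of `"cases"` reflects that co-regulation under the phenotype is what the
similarity network is meant to capture; `"all"` doubles the sample count
at the cost of mixing two covariance regimes.

# The synthetic study generator

`simulate_study()` emulates the four inputs with a planted ground truth:

* **Expression**: background genes are i.i.d. Normal(baseline = 7,
  noise_sd = 0.2) per sample. Each planted module (default 25 genes up,
  25 down, in a 300-gene universe) additionally receives a per-sample
  latent factor shared across the module, Normal(0, factor_sd = 1), plus
  a ±3 log2-unit shift in the 10 case samples.
* **DEG table**: per-gene Welch two-sample t test (vectorized), BH
  adjustment, log2FC = case mean − control mean.
* **PPI**: a Barabási–Albert preferential-attachment graph (m = 2) over
  all gene symbols, with each module wired as a chain and attached to the
  top-degree hub — every module is connected and reachable.
* **Pathways**: one planted pathway holding both modules plus 10 decoy
  genes, and 49 decoy pathways of 10–40 genes drawn from non-module
  genes.

The latent factor is the load-bearing choice: it makes two module genes'
value vectors nearly identical (their difference is pure technical
noise), so the pairwise KW p value is high and the branch's similarity
network is dense — which is exactly the structure the method is designed
to exploit. Its default of 1.0 (five times the technical noise) models a
strongly co-regulated module; at this setting module pairs clear the
0.005 similarity threshold in well over 95% of studies, which the test
suite verifies empirically over 200 seeds. The factor is shared by cases
and controls, so it inflates the between-sample variance that the t test
sees; at the default 10+10 samples the planted ±3 shift still passes the
0.005/1.5 filter essentially always, but below ~8 samples per group it
often does not — small-fixture tests in the suite use 10+10 for this
reason.

What the generator does **not** emulate: probe-level effects, batch
structure, heteroscedastic intensity-dependent noise, correlated decoy
pathways, and PPI false-positive edges. Passing the recovery test
therefore shows the pipeline's stages compose correctly and that its
selection rules preserve a strong planted signal — not that the method
is robust to the full messiness of real microarray data.

# Numerical and degenerate-input choices

* Kruskal–Wallis: ties via midranks (equivalently the tie-corrected
  statistic); all-identical input → H = 0, p = 1 rather than 0/0.
* Closeness: isolated node → 0; single-node graph → 0.
* Bottleneck: root excluded from its own tree's scoring; per-tree n/4
  threshold; lexicographic BFS tie-break (pinned, documented above).
* Selection rules: closeness uses ≤ (boundary included, so a complete
  graph selects everyone); bottleneck uses strict > with a logged ≥
  fallback.
* Branches with fewer than two genes (or none mapping to the PPI) are
  recorded with a status string and skipped; the other branch proceeds.
* Enrichment p values never underflow to exactly 0 in the |log2 p|
  columns (guarded by the smallest representable double).
* The pipeline proper contains no randomness; rerunning a configuration
  byte-identically reproduces `report.json` and every TSV.

# Problem sizes used in validation

The test suite exercises exhaustive oracles at small n (all two-group
labelings of value sets up to N = 8 against a closed-form rank statistic;
all hypergeometric tails up to N = 12 against draw enumeration), Monte
Carlo calibration of the generator over 200 seeds at reduced gene counts,
100 random study configurations for the cross-branch disjointness
invariant, and 10 full-default studies (300 genes each) for end-to-end
planted-pathway recovery. These sizes were chosen so the whole suite
completes in well under a minute while each check still has the power to
fail: the exhaustive oracles are exact, and the recovery margin at the
default conditions (planted p ~ 1e−11 vs decoys at ~0.3) is many orders
of magnitude.

# Known limitations

* The closeness rule keeps low-closeness nodes, as specified; on sparse,
  stringy similarity networks this selects the periphery, and whether
  that is the intended behaviour of the original description is
  debatable — hence the `invert_cc_rule` escape hatch.
* The KW similarity score is location-based: co-regulated genes at
  different absolute expression levels will not connect. A
  correlation-based similarity is out of scope by design.
* The chi-square p approximation at 2+2 observations is crude; the
  similarity stage should be read as a heuristic edge rule, not
  inference.
* Bottleneck centrality has no single canonical definition in the
  literature; the pinned BFS-tree variant here is the common
  shortest-path-tree load formulation, made deterministic. Scores from
  other tools may differ on tie-heavy graphs.
* The enrichment universe defaults to pathway-annotated genes; with a
  small custom GMT this can make the universe optimistic. Supply a
  background list for a calibrated null.
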