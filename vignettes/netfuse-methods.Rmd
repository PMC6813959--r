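---
title: "Fusing heterogeneous gene networks by inverse mutual rank: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing heterogeneous gene networks by inverse mutual rank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netfuse)
```

## The problem

Genome-scale gene association networks for one organism are published in
mutually incompatible score dialects. A co-expression compendium may
report Pearson correlations (0.5–1, higher is better), a rank-based
co-expression database highest reciprocal ranks (integers 0–200, *lower*
is better), and a Bayesian functional network log-likelihood scores
(about 1–5, higher is better). Each network alone is shallow or biased;
pooled, they would cover far more of the genome — but their scores cannot
be added, and even rescaling them to a common interval would not make a
correlation of 0.8 commensurable with a log-likelihood of 3.

`netfuse` solves this with a rank-based change of scale, a regression
calibration, and an evidence-summing fusion, and then provides the
evaluation, extraction and comparison machinery needed to use the fused
network for guilt-by-association work such as finding candidate
regulators of cell-wall biosynthesis.

## The model

### Inverse mutual rank

For an edge A–B in one source network, let `rank(A,B)` be the position of
B in A's neighbor list when the neighbors are sorted from best to worst
score under that source's polarity (best = 1; ties get the average rank,
so a gene with k neighbors always assigns ranks summing to k(k+1)/2).
The mutual rank is the geometric mean of the two directed ranks,

    MR(A,B) = sqrt(rank(A,B) × rank(B,A)),

and the edge's rescaled score is `1/MR ∈ (0, 1]`, equal to 1 exactly when
the edge is rank-1 in both directions. Two properties make this the right
common currency:

* it depends only on the *ordering* of each gene's neighbors, so any
  strictly monotone transformation of a source's scores — or an entirely
  different scoring dialect — yields the same result;
* it is local: a hub with hundreds of partners assigns small `1/MR` to
  most of them, which automatically discounts promiscuous associations.

Ranks are computed among *listed* neighbors only. Published networks are
distributed as thresholded edge lists, not dense similarity matrices, so
the edge list is taken to be the network. Re-deriving ranks from raw
expression data is out of scope and upstream of this tool. HRR-style
inputs are re-ranked from their stored scores (with lower-is-better
polarity) rather than read directly as ranks, so that all three dialects
pass through exactly the same operation.

### Calibration

Sources differ in quality, so their inverse mutual ranks should not enter
the sum at face value. Each auxiliary network is calibrated against the
reference network (the highest-quality source) by a generalized linear
model — Gaussian family, identity link, **no intercept** — regressing the
reference's `1/MR` on the auxiliary's `1/MR` over the edges both networks
contain. The no-intercept choice reflects the form of the published
combination equations, which contain no constant term: an edge absent
from every source must have score 0, not a baseline offset.

Two fit modes exist because the edge set behind a multi-source
calibration is ambiguous when sources overlap partially:

* `pairwise` (default): each auxiliary is fitted separately on its own
  common-edge set with the reference. This matches the reporting of two
  distinct common-edge counts for two auxiliaries, and uses all available
  common edges per source.
* `joint`: all auxiliaries are fitted simultaneously on the edges common
  to *every* network, matching the two-predictor form of the published
  equation.

Both are exposed and recorded in the run manifest; results on the
synthetic benchmark are nearly identical. Negative fitted coefficients
are retained but flagged with a warning — no truncation rule is imposed.

A related ambiguity is whether the regression operates on MR or 1/MR.
`netfuse` uses 1/MR throughout: the fused score is explicitly a *sum of
inverse* ranks, and the standard extraction cutoff of 0.03 only makes
sense on the inverse scale (1/0.03 ≈ rank 33, i.e. roughly each bait's
top-30 mutual-rank partners). This assumption is stated in the model
files and manifests the CLI writes, not silently applied.

### Fusion: the summed inverse rank

The fused network's edge universe is the union of all source edge sets,
and each edge's score is

    SIR(e) = 1/MR_ref(e)·[e ∈ ref] + Σ_i β_i · 1/MR_i(e)·[e ∈ net_i].

An edge missing from a source contributes zero from that source — no rank
is imputed — so single-source edges survive with whatever weighted
evidence they have. Per-source inverse ranks are carried along as
provenance, and removing a source lowers each affected edge's SIR by
exactly its weighted term (an additivity the test suite asserts).

## Evaluation

### GO-BP term matching

Networks are scored by how often connected genes share a biological
process. An edge is *matched* if its two genes share at least one
retained GO-BP term; edges with an unannotated endpoint are excluded
(they can be neither matched nor unmatched — in typical plant genomes
only ~40% of genes carry BP annotations). Because very general terms
(e.g. broad developmental or metabolic processes) would rubber-stamp
almost any edge, the `n_exclude = 10` most frequent terms — frequency
measured as the number of annotated genes, ties broken by term id — are
removed first. The published analyses name neither the ten terms nor the
selection rule, so this operationalization is a design choice; the
excluded list is always written to the evaluation report and can be
overridden with an explicit list.

Confusion counts at a score cutoff θ use a closed lower bound
(score ≥ θ, consistent with the extraction rule "SIR ≥ 0.03"):
TP = matched ∧ score ≥ θ, FP = unmatched ∧ score ≥ θ, TN/FN below the
cutoff. Precision = TP/N with N = TP+FP the number of predictions;
Recall = TP/TotalTrue with TotalTrue the matched-edge count of the whole
network, fixed across cutoffs. The identities TP+FN = TotalTrue and
FP+TN = TotalFalse hold at every cutoff by construction and are asserted
in the tests.

ROC and precision–recall curves sweep 40 cutoffs. The default grid is 40
evenly spaced *quantiles* of the evaluable-edge score distribution, not
evenly spaced raw values: inverse-rank scores are heavily right-skewed,
and value-spaced grids collapse most of the curve into the first bin.
Value spacing remains available (`grid = "value"`). The curve is anchored
at (0,0) and (1,1) and integrated by the trapezoid rule; on perfectly
separated toys the quantile grid places a cutoff inside the score gap and
the AUC is exactly 1.

### The random control

The null model is a network with the same node universe and edge count
whose edges are drawn uniformly over distinct gene pairs and scored
uniformly on (0, 1]. Its labels are independent of its scores, so its AUC
converges to 0.5; the test suite checks 0.5 ± 0.05 per seed at 10,000
edges on a densely annotated universe (the bound follows the matched-edge
count: with few matched edges the AUC of even a label-independent network
fluctuates visibly, which is why the margin test against the fused
network averages the control over five seeds).

### Topology

Scale-free structure is summarized by regressing `log10 P(k)` on
`log10 k` over the observed (nonzero) degree bins: the slope is the
exponent γ and the fit quality is the regression R². The fit uses the
raw, unbinned degree histogram — the convention behind published bare R²
values is unstated, and raw histograms are the simplest reproducible
choice; at least three distinct degrees are required. Maximum-likelihood
power-law estimation with model selection is deliberately out of scope:
the quantity of interest here is the R²-of-regression notion, not the
best modern estimate of γ. Genome coverage is the fraction of a supplied
gene universe touched by at least one edge; since fusion only adds nodes,
coverage is monotone under fusion.

## Extraction and candidate selection

Two extraction modes serve different questions:

* **Seed–seed** (`extract_seed_subnetwork`): edges with *both* endpoints
  in the bait list, by default without any score cutoff — used to measure
  recall of known associations among curated genes.
* **One-step** (`extract_one_step`): edges with at least one endpoint in
  the bait list and SIR ≥ 0.03 (closed bound: an edge at exactly 0.03 is
  kept, and a reference-only edge at reciprocal rank 30, SIR = 1/30 ≈
  0.0333, survives). Only seed-incident edges are kept — no
  neighbor–neighbor closure — because the published network scale
  (~1.75 edges per node) is consistent with a star-like construction, not
  a closed neighborhood. Bait and non-bait node counts are reported
  separately, since published node counts are ambiguous about whether
  baits are included.

Candidate regulators are the non-seed transcription factors in the
one-step network with at least `min_seed_edges = 5` *distinct* seed
partners ("fewer than five edges with seed genes" excluded). Counts are
broken down by seed category, and the category-degree matrix can be
z-scored per category (population SD; a constant category maps to all
zeros) and ordered by complete-linkage hierarchical clustering of the
z-scored profiles with Euclidean distance — the defaults of the common
heatmap tools whose "default hierarchical clustering" the published
figures invoke. Group labels come from cutting the dendrogram at a
user-chosen number of groups (default 3) rather than being hard-coded.

## Cross-species comparison

For each ortholog group, the partners of all co-orthologs in a species
are pooled by set union (an edge to one's own co-ortholog does not
count), optionally restricted to a partner pool such as the cell-wall
seed list. The two species' counts are compared with a two-sided Fisher
exact test on `[[k₁, N₁−k₁], [k₂, N₂−k₂]]`, computed by full
hypergeometric enumeration. The default totals N are each species'
network node count, following the description of whole-network totals as
the comparison denominator; because the published normalization is not
fully specified, `total_mode = "pool"` switches the denominators to the
partner-pool sizes. Raw p-values are flagged at 0.05 and 0.01 (the
convention of the original analysis); Benjamini–Hochberg adjusted values
are emitted alongside but do not drive the flags.

## The synthetic benchmark

`synthetic_spec()` fixes the study conditions under which the toolkit is
tested; all generators are deterministic under the spec's seed. The
defaults describe a desk-scale benchmark a network methodologist would
consider realistic:

| parameter | default | why |
|---|---|---|
| `n_genes` | 1000 | large enough for stable degree structure, small enough for fast tests |
| `attachment_m` | 2 | preferential-attachment backbone ⇒ scale-free topology, the property the topology module must detect |
| `n_modules`, `module_size` | 6, 10 | planted cliques whose members share a GO term — the co-annotation signal evaluation must reward |
| `overlap` | 0.7 per source | partial edge overlap between sources, so fusion has both shared and private evidence |
| `decoy_rate` | 0.3 | false edges per source, giving non-degenerate ROC curves |
| `n_regulators`, `regulator_degree` | 3, 8 | regulators wired into the seed module above the 5-partner selection threshold |
| `n_decoy_tfs` | 5 | TF-list entries wired to ≤1 seed, which selection must reject |
| `coefficients` | 0.33, 0.025 | planted calibration weights on the published scale |
| `annotated_fraction` | 0.4 | background annotation density matching the ~40% BP coverage typical of plant genomes |
| `n_background_terms` | 30 | generic-term pool; each term annotates more genes than any module term, so the top-10 exclusion removes generic terms, not signal |

The regulators' edges are planted in the *truth graph* (not added after
scoring): source networks are derived from the truth by edge retention
and rescoring, so only edges present before scoring can surface in the
fused network — planting them later would make end-to-end recovery
impossible by construction.

Scores respect each dialect's range and polarity (PCC-like in [0.5, 1];
HRR-like integers in [0, 200], matching the unit increments of published
HRR scores; LLS-like in [1, 5]), with functional (module/regulator) edges
drawn from stochastically better score ranges than backbone edges and
decoys worse still.

Calibration fixtures (`generate_calibration_truth`) draw predictor
inverse ranks uniformly on (0, 1] and set the reference to the planted
linear combination; with noise, draws that would leave the (0, 1]
inverse-rank scale are redrawn (truncated noise). At σ = 0.01 and
n = 5000 this truncation touches a fraction of a percent of edges and
moves the recovered coefficients by far less than the ±0.01 recovery
tolerance.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: biologically structured score noise (batch and
platform effects that correlate across "independent" sources), broad-
versus-narrow GO term hierarchies (terms here are flat sets, as in the
evaluation itself), assortative TF–TF wiring, incomplete and biased
ortholog maps, and the sheer scale (10⁵–10⁶ edges) of genome networks.
The published full-scale numbers (AUC 0.69, 93% genome coverage, the
1,790-node one-step network) depend on the deposited full-size networks
and curated seed lists and are not reproducible from synthetic data; the
suite instead checks the *properties* those numbers instantiate —
coverage monotonicity, AUC above the random control, boundary behavior of
the cutoffs.

## Numerical choices and degenerate inputs

* Ties in neighbor ranking take average (fractional) ranks: the source
  texts are silent on ties, and fractional ranking is deterministic,
  order-independent, and preserves rank sums.
* Score comparisons at cutoffs use ≥ everywhere, consistent with the
  "≥ 0.03" extraction rule.
* Fisher p-values sum hypergeometric probabilities ≤ the observed table's
  probability with the conventional 1 + 1e-7 relative slack against
  floating-point ties (the same convention as `stats::fisher.test`, which
  serves as an independent cross-check in the tests, with a from-first-
  principles binomial-coefficient enumeration as the primary oracle).
* Degenerate cases error loudly rather than guess: empty networks cannot
  be ranked; ROC is undefined when all edges are matched (or all
  unmatched); power-law fits need ≥ 3 distinct degrees; calibration needs
  ≥ 2 common edges per source; a constant category z-scores to zero by
  convention.
* Duplicate edge-list entries with conflicting scores keep the better
  score under the source's polarity with a warning; self-loops are
  dropped with a counted warning. Gene ids are uppercased and stripped of
  transcript suffixes at every ingestion point, because public deposits
  mix locus and transcript identifier forms.

## Problem sizes

The test suite and examples run at deliberately modest sizes — 1,000-gene
synthetic studies, 10,000-edge random controls, exhaustive Fisher
enumeration up to table totals of 40, 100 small networks for the ranking
oracle — chosen so the complete suite finishes in well under a minute of
compute while still exercising every statistical property at sample sizes
where the expected behavior is unambiguous.

## Known limitations

* Calibration assumes an approximately linear relation between sources'
  inverse ranks on common edges; a source whose quality varies strongly
  across the score range would be mis-weighted.
* Only one reference network is supported; re-deriving the reference's
  own scores (e.g. a Bayesian LLS integration) is out of scope.
* GO terms are treated as flat sets: no hierarchy propagation or semantic
  similarity. An edge matched only through a term just below the excluded
  generic terms still counts as matched.
* The ortholog map is consumed as input; no orthology inference is
  attempted, and a gene may belong to at most one group per species.
* PR curves are reported as curves; no single PR-AUC headline number is
  computed.
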