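---
title: "Building and assessing co-functional gene networks with llsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and assessing co-functional gene networks with llsnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llsnet)
```

## The model

llsnet builds a genome-scale *co-functional* gene network: an undirected,
weighted graph in which an edge asserts that two genes participate in the
same biological process, and the weight quantifies the strength of the
combined evidence.  The construction has three stages.

**1. A gold standard from annotations.**  Two genes form a positive pair
when they share a functional annotation term supported by a reliable
evidence code (by default IDA, IMP, IPI, TAS -- direct assay, mutant
phenotype, protein interaction, traceable author statement; computational
IEA-style codes are excluded).  Terms outside a size window (default 2 to
300 member genes) are dropped: singleton terms carry no pairs and giant
generic terms would swamp the positives with uninformative combinations.
Negatives are *implied*: both genes annotated (in the retained-term
universe) but the pair not positive.  This universe-based definition avoids
penalising unannotated genes, whose status is simply unknown.

**2. Log-likelihood calibration of each evidence layer.**  Every data type
-- co-expression, co-inheritance, gene neighborhood, orthology-transferred
links -- produces raw pairwise scores on its own scale.  Each layer is made
commensurable by benchmarking against the gold standard: pairs are binned
along the raw score and each bin receives the log-likelihood score

$$LLS = \ln \frac{P(L\mid E)/P(\lnot L\mid E)}{P(L)/P(\lnot L)},$$

the log odds of functional linkage $L$ within the evidence stratum $E$
relative to the prior odds.  Natural logarithm throughout, so the unit is
nats; $LLS = 0$ means the stratum is exactly as informative as knowing
nothing.  The prior odds are taken from the gold standard as a whole (all
positives versus all implied negatives).  This matters for layers with
selective coverage: a transferred-network layer that covers almost only
positive pairs would score near zero against its *own* pair population, yet
is precisely the kind of evidence the integration should reward.  A
`prior = "layer"` option restores the within-layer convention.

**3. Weighted-sum integration.**  A pair's per-layer LLS values
$L_0 \ge L_1 \ge \dots$ are combined as

$$WS = L_0 + \sum_{i \ge 1} \frac{L_i}{D \cdot i}, \qquad D \ge 1,$$

so the strongest line of evidence enters in full and each additional line
is discounted by rank.  $D$ models redundancy between data types: $D = 1$
treats lines of evidence as close to independent, $D \to \infty$ trusts
only the single best line.  The same formula integrates *within* a data
type (the per-dataset co-expression networks; the distance- and
probability-based neighborhood measures) and *across* the component
networks.  `grid_search_D()` can pick $D$ by maximising the area under the
precision-coverage curve on a held-out half of the gold standard, split at
the term level so all pairs of one term stay on one side.

## Evidence layers

**Co-expression.**  Expression series are screened twice, mirroring the
two-filter selection protocol: a series must contain at least 12 samples
(`min_samples = 12`; correlations from fewer conditions are too unstable to
rank), and its correlation layer must show gold-standard signal -- the best
bin of the benchmarked layer must reach `retain_threshold` (default 0.5
nats).  Pearson correlation is the default measure; per gene only the
strongest `top_n = 100` partners are kept, since only the high-correlation
strata carry signal and the full pair matrix is quadratic.  Retained
datasets are calibrated individually and merged with the weighted sum, so a
pair co-expressed in several independent series accumulates evidence.

**Phylogenetic profiling.**  Co-inheritance is measured as the mutual
information between two genes' presence/strength profiles, computed
*within* each taxonomic domain (values discretised into `n_bins = 2`
equal-width bins over [0, 1]).  Inheritance regimes differ sharply between
domains, and pooling them dilutes domain-specific signal; each domain's MI
is benchmarked separately and a pair takes the maximum of its per-domain
LLS values (a weighted-sum combination is available).  Genes present in
fewer than two genomes are excluded as uninformative.

**Gene neighborhood.**  For prokaryotic genomes, conserved chromosomal
proximity of two genes' orthologs is operon-like evidence of functional
coupling.  Distances are gene-count ordinals on a circular chromosome
(robust to genome-size variation, no base-pair calibration needed).  Two
measures are computed per pair over the genomes where both orthologs share
a chromosome: the mean of $1/d$ (distance measure), and
$-\sum \ln P(D \le d)$ with $P(D \le d) = \min(1, 2d/(m-1))$ under uniform
placement on a circular chromosome of $m$ genes (probability measure --
how unlikely the observed proximity is by chance; exact for odd $m$,
capped at 1 otherwise).  Each measure is benchmarked separately and the
two LLS values are combined with the weighted sum; chromosomes with fewer
than three genes are skipped.

**Associalogs.**  Edges of a source-species functional network transfer to
every target pair whose endpoints are orthologous to the source endpoints;
when several source edges collapse onto one target pair the maximum weight
is kept (order-independent, preserves the strongest evidence).  Transferred
weights are calibrated to the *source* gold standard, so the layer is
re-benchmarked against the target gold standard before integration.
`project_network()` uses the same expansion but carries weights unchanged:
it serves an already-integrated network for a related species where no
target gold standard exists, and therefore performs no re-calibration.

## Assessment and search

`precision_coverage_curve()` ranks edges by weight and reports, at each
rank cutoff, the precision over *evaluable* edges (both endpoints covered
by the reference catalog) against the fraction of the coding genome covered
by the retained nodes.  The genome size is always an explicit input --
inferring it from the network would flatter small networks.

`set_connectivity_auc()` asks how well the network interconnects a gene
set.  Each member is held out in turn, every gene is scored by its summed
edge weight to the remaining members, and the held-out member is ranked
against all non-member genes (rank-sum formula, ties averaged); the AUC is
the mean over members.  The hold-one-out form is deliberate: ranking all
genes in a single pass scores members against one fewer potential partner
than non-members, which at a few hundred nodes biases the null AUC
measurably below 0.5 (about 0.46 for sets of 10 in a 200-gene network).
With the hold-one-out form the held-out member and every negative are
scored against exactly the same reduced set, so the null expectation is 0.5
by exchangeability.  At genome scale the two forms agree to about $10^{-3}$.

Null comparisons use `randomize_network()`.  The default mode permutes
node labels over the fixed topology, preserving every structural property
and destroying only the assignment of genes to positions -- the right null
for asking whether *annotations* are placed non-randomly.  A
degree-preserving edge-swap mode is available when the topology itself is
in question.  `auc_null_comparison()` runs a set collection against
replicate nulls and applies a paired Wilcoxon signed-rank test of observed
AUC versus per-set mean null AUC.  Null expectations are always estimated
from an ensemble of shuffles, never a single permutation: with ten sets of
ten genes on a 200-gene network, a single shuffle's mean AUC has a standard
deviation near 0.05, so one permutation cannot certify calibration.

The two guilt-by-association searches are thin, deterministic layers over
the network: `find_new_members()` ranks non-query genes by summed edge
weight to the query set (ties broken by gene identifier) and reports the
query set's own interconnectivity AUC as a guide-set quality diagnostic;
`infer_functions()` scores catalog terms over a query gene's neighbors
either by summed edge weight (default -- uses edge confidence) or by the
hypergeometric upper tail with Benjamini-Hochberg FDR.
`topn_retrieval_rate()` cross-validates the gene-centric search: the
evaluated gene is removed from every term before scoring, so its own
annotations cannot leak into the prediction.

## The synthetic world

`make_world()` plants `k = 10` disjoint modules of `m = 10` genes on 100
background genes, and the input generators endow within-module pairs with
signal in every layer: a shared latent expression factor giving
within-module correlation `rho = 0.8` (generated as
$\sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$, so the target correlation is
exact in expectation and checkable analytically); a per-module, per-domain
inheritance pattern copied with 10% flips; operon-like position blocks in
50% of 40 prokaryotic genomes; a source-species network containing every
within-module pair plus 10% spurious edges; one annotation term per module;
and three expression series of 20, 12 and 11 samples -- the last
deliberately below the size filter so the rejection rule is exercised on
every build.  Decoy catalog terms are drawn from background genes only, so
each module gene has exactly one true term and the random-baseline
retrieval rate has the closed form $n \cdot \bar t / |catalog|$.

These are the package's reference study conditions; all tests and the
acceptance script run on them (200 genes, ~4,000 integrated edges, ~20,000
candidate pairs per context layer).  What the generator does *not* emulate:
microarray noise structure (batch effects, probe biases), overlapping or
hierarchically nested modules and terms, paralog ambiguity in orthology
maps, and genome-scale sparsity.  Passing tests demonstrate that the
machinery recovers planted signal and that its null statistics are
calibrated -- not that any particular biological dataset will yield a
network of a given quality.

## Numerical choices and degenerate inputs

* Equal-count binning (default 20 bins) is robust to skewed raw-score
  distributions; when ties collapse the quantile edges (e.g. binary
  scores) the binning falls back to split points between distinct values.
* Empty bins are filled by linear interpolation from neighboring bins and
  flagged.
* A per-cell pseudocount of 0.5 prevents infinite LLS in pure bins.
* Isotonic (weighted pool-adjacent-violators) smoothing of the bin LLS is
  on by default: the true stratum-wise odds should be monotone in the raw
  score, and sparsely populated bins otherwise produce noise reversals.
* Unordered pairs are stored canonically (lexicographically smaller gene
  first); gene identifiers are opaque, case-sensitive strings with no
  alias resolution.
* Ties everywhere break deterministically by identifier; grid searches
  return the smallest tied parameter.
* Edge weights are serialised at 17 significant digits, so writing and
  re-reading a network is bit-exact and repeated builds with one seed are
  byte-identical.
* Constant expression rows, genes absent from profile matrices, and
  chromosomes of fewer than 3 genes are excluded with a report rather than
  propagating NaN.

## Limitations

The evidence-code vocabulary, bin count, per-layer LLS floor (`min_lls`),
weighted-sum floor (`min_ws`) and `D` are configuration, not estimates:
defaults are reasonable for the reference conditions but should be
re-examined on real data, ideally with `grid_search_D()` and the
precision-coverage curve on an independent reference.  The ontology graph
is not traversed (annotations are taken as already propagated or flat), and
the integrator's $D$ is a single global redundancy factor -- correlated
evidence between specific layer pairs is not modelled explicitly.
Orthology maps are consumed as given; paralog expansions beyond the stated
many-to-many collapse rule are out of scope.
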