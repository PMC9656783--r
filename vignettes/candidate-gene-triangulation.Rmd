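---
title: "Triangulating candidate disease genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating candidate disease genes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genetriage)
```

genetriage implements a multi-evidence candidate-gene workflow for
case/control transcriptomics: literature mention mining, cross-dataset
effect-size meta-analysis, thresholded co-expression networks, overlap
enrichment, gene-list comparison, and tree-ensemble biomarker ranking.
This vignette is the package's own account of the underlying methods —
what is modelled, which parameters matter, where the design was genuinely
open and what was decided, and what the synthetic-data tests do and do not
demonstrate about real data.

## The mention miner

The miner is a dictionary recognizer, not an NER model. Text is split on
non-alphanumeric boundaries with hyphens kept word-internal (so
`HLA-DRB1` is one token), stop phrases are removed case-insensitively,
runs of identical consecutive tokens are collapsed, and surviving tokens
are compared **exactly and case-sensitively** against catalog symbols and
aliases. Three choices deserve justification:

* *Case sensitivity.* Human gene symbols are case-significant and collide
  with English words when lower-cased (`set`, `cat`, `impact`). Exact
  matching trades recall on sloppily-cased text for precision; for
  curated abstract text this is the right trade.
* *Article-level counting.* A gene repeated ten times in one abstract is
  one unit of literature attention. `filter_frequent()` therefore counts
  distinct articles and applies a **strict** `> min_articles` comparison
  (default 50), so a gene in exactly 50 articles is excluded.
* *Blacklist.* Some official symbols are ordinary words; no dictionary
  recognizer can disambiguate them from context. A default blacklist
  ships (`default_blacklist()`), is configurable, and the corpus
  generator can plant exactly such ambiguity decoys (recorded separately
  from the mention truth) so blacklist behaviour is testable.

## Effect-size meta-analysis

Public expression repositories describe their two-group comparisons at
dataset level; to combine several datasets the package uses the canonical
effect-size route rather than p-value combination:

1. Per dataset, markers are collapsed to genes — by default the marker
   with maximal variance (`collapse = "mean"` is available). Max-variance
   selection is a common convention when probe annotations are richer
   than the gene-level question; it avoids diluting a responsive probe
   with dead ones.
2. Hedges' g (case minus control) with the small-sample correction
   J = 1 − 3/(4(n₁+n₂−2)−1) and variance (n₁+n₂)/(n₁n₂) + g²/(2(n₁+n₂)).
   Genes with zero pooled variance in a dataset are skipped there.
3. DerSimonian–Laird random-effects pooling: τ² = max(0, (Q − df)/C) with
   fixed-effect weights 1/v; random-effects weights 1/(v + τ²); z test,
   two-sided normal p. A fixed-effect mode exists
   (`meta_analyze(method = "fixed")`), and with τ² = 0 the random-effects
   estimate reduces to it exactly. Random effects is the default because
   heterogeneity across platforms and cohorts is the rule, not the
   exception.
4. Benjamini–Hochberg adjustment across pooled genes; DEG selection uses
   an **inclusive** `fdr <= alpha` threshold with `alpha = 0.001` as the
   default operating point.

Genes measured in fewer than `min_datasets = 2` datasets are excluded:
"pooling" a single study is vacuous, though the floor is configurable
down to 1.

## TMM normalization

Before biomarker modelling, samples are equalized with the
trimmed-mean-of-M-values recipe: reference sample = the one whose
library-size-scaled upper quartile is closest to the mean; M and A
computed over markers nonzero in both samples; double trim (30% of M each
side, 5% of A each side); composition factor = 2 to the precision-weighted
mean of the surviving M values, with inverse delta-method variances as
weights.

`tmm_factors()` returns, per sample, the **scale factor actually divided
out during normalization** — the composition factor multiplied by the
library size, rescaled to geometric mean 1. On this scale all factors are
1 for identical samples, and a sample that is a uniform two-fold copy of
another receives exactly twice its factor, which is the behaviour a user
dividing columns by "the normalization factor" expects. The
library-size-free composition factors (the convention of count-based DE
tooling) are preserved in the `composition` attribute; the test suite
verifies them against an independent implementation of the same published
recipe to 1e-10. TMM is defined on non-negative data with a meaningful
library-size notion; `assemble_features(normalize = "none")` is the
escape hatch for data where that premise fails.

## Co-expression networks

Edges require |r| ≥ `r_min` (default 0.5) **and** p ≤ `p_max` (default
0.01, raw). Two deliberate readings:

* The magnitude filter applies to **|r|**, not signed r — strong negative
  co-expression is biologically meaningful and a signed rule would
  silently delete it.
* Edge p-values are **not** multiplicity-adjusted; the filter is a
  descriptive screen, not an inference, and the conventional raw-0.01
  cutoff is used as stated.

Networks are built per platform group over the samples pooled within the
group (whether to pool or average per-dataset correlations was open;
pooling uses all samples and matches how the feature tables are built).
Genes with zero variance are skipped and recorded, never silently
imputed. Boundary behaviour is exact: r = 0.49 fails at r_min = 0.5
regardless of p, and p = 0.02 fails at p_max = 0.01 regardless of r.

## Enrichment

The test statistic is the one-sided hypergeometric upper tail
P(X ≥ overlap) — equivalently a one-sided Fisher test — with the
annotated universe of the supplied GMT as the background. Alongside the
−log₁₀(BH-adjusted p) column the table reports two descriptive ratios:
share = 100·|L∩T|/|L| (how much of the studied list belongs to the term)
and intersection = 100·|L∩T|/|T| (how much of the term the list covers).
Both satisfy share·|L| = intersection·|T| = 100·overlap exactly; rounding
to two decimals happens only at serialization. Terms smaller than
`min_term_size` (default 5) are not tested, and BH runs across exactly
the tested terms.

## Comparing gene lists

With only a start coordinate per gene, "distance" is start-to-start — the
only well-defined choice for a single-coordinate catalog — and the
proximity bound is **strict** (< 1 Mbp by default). A gene present in
both lists is a distance-0 pair (excludable by flag). Because "genes from
each list that are close to each other" can be counted as pairs or as
distinct genes, the report carries both counts. A shared "locus" is a
fixed-width bin (floor(start / bin_size), default 1 Mbp) occupied by both
lists; the bin width is a parameter, since locus granularity is
inherently a modelling choice.

## Biomarker models

Feature tables combine same-platform datasets column-wise on the
intersection of their markers restricted to the selected genes (union of
literature-frequent genes and DEGs, mirroring how the evidence streams
feed the models). The 70/30 split is stratified by largest-remainder
allocation, so the training class proportions are always within one
sample of the target, with the overall training size ⌈0.7·n⌉.

Three algorithms: a single decision tree, a random forest
(mean-decrease-in-Gini importances), and extra-trees. The "extra-trees
regressor on a binary label" reading — a regression forest on a 0/1 class
encoding whose predictions are thresholded at 0.5 — is adopted because it
is the only faithful interpretation of naming a regressor for a
classification task; its impurity importances feed the same rankings.
Accuracy comes with a 95% **Wilson score** interval (well-behaved at
small n and at accuracy 1.0, unlike the Wald interval). Importances are
reported raw and rescaled to sum to 100 per model, since single-tree
importances are on an arbitrary scale and only relative magnitudes
transfer across algorithms. Ensembles default to 500 trees; every
stochastic step takes an explicit seed, and the extra-trees fit is pinned
to one thread so results do not depend on scheduling.

Local explanations follow the LIME template: Gaussian perturbations
around the instance scaled by background feature SDs, an exponential
kernel on the standardized distance with width 0.75·√d (the conventional
default; d = feature count), and a weighted ridge fit with a negligible
penalty (1e−6 of the total kernel mass) so a linear black box is
recovered essentially exactly. Weights are per unit of each feature;
zero-variance background features are excluded with a message. Because
the background enters only through its SDs, explanations are invariant to
location shifts of background features.

Recurrence tallies count marker-level appearances in each report's top-k;
a gene's tally aggregates over its markers, so a gene carried by two
markers in one report counts twice — matching marker-level counting and
guaranteeing gene count ≥ the max of its markers' counts.

## The synthetic-data generator

The generator emulates exactly what the downstream stages consume, with
recorded ground truth:

* *Corpora* are bags of decoy tokens from a fixed common-English
  vocabulary with gene symbols spliced in as standalone tokens. Token
  realism suffices because mining is token-level; no sentence grammar, no
  MEDLINE XML, no positional structure is simulated.
* *Expression* is Gaussian on a log2-like intensity scale around
  per-gene baselines (N(7, 1) by default, echoing typical microarray
  log-intensities), per-sample noise SD 1, planted DEG shifts applied
  before noise and sign-consistent across datasets. Correlation blocks
  use one latent factor per block with loading √r — the simplest model
  with a controllable expected pairwise correlation. A negative-binomial
  count mode exists to exercise TMM. Default study shape: three datasets
  on two platform groups with 10–20 samples per class, matching the scale
  of small public case/control series.
* *Catalogs* place at least one same-chromosome pair under 1 Mbp and one
  far pair, so proximity logic always has both cases to exercise.
* *Annotation sets* are uniform random draws; a planted term can embed a
  chosen gene subset (optionally avoiding a given list) to make
  enrichment recovery checkable by construction.

What passing on this generator shows: the statistical machinery is
implemented correctly — planted signals of stated size are recovered at
the stated thresholds, and null inputs stay null. What it does not show:
robustness to probe-level artifacts, batch effects, annotation bias,
non-Gaussian heavy tails, or the vocabulary drift of real abstracts; none
of these are simulated, deliberately.

## Numerical and reproducibility choices

* Degenerate inputs fail loudly (zero pooled SD, zero-variance vectors,
  all-zero samples) or are skipped and recorded (degenerate network
  genes, zero-variance explanation features) — never silently imputed.
* Ties break lexicographically everywhere a ranking is emitted
  (frequency tables, hub degrees, importances), making outputs stable
  across platforms.
* All generators and stochastic stages run under `withr::with_seed`, so
  they are deterministic given (seed, arguments) and do not disturb the
  caller's RNG stream.
* `run_pipeline()` hashes the configuration (minus the output path) and
  stamps every stage manifest with it: reruns under the same
  configuration reuse cached stage outputs and are byte-identical, and an
  output directory holding a different configuration's results is
  refused rather than mixed. The run report deliberately contains no
  timestamps.
* The test suite and the acceptance script use deliberately modest
  problem sizes — corpora of tens to hundreds of articles, catalogs of
  30–20,000 genes, datasets of 20–40 samples, 50-seed null batteries —
  chosen so the full battery completes in well under a minute while
  leaving each statistical check adequately powered.

## Known limitations

* The miner does no synonym expansion beyond the supplied alias table,
  no fuzzy matching, and no relation extraction; corpora must be
  pre-fetched (two-column TSV or MEDLINE-like text).
* Meta-analysis assumes matrices are already on a log-like scale
  (`log2_transform = TRUE` is available for counts); probe-level
  preprocessing and batch correction are out of scope.
* Enrichment backgrounds are the supplied GMT universe; results are not
  comparable across different annotation collections, and the package
  refuses to intersect enrichments computed against different ones.
* Single-coordinate proximity ignores gene length and orientation.
* Accuracies from one 70/30 split carry the variance of that split;
  repeated splitting with different seeds (and inspecting the spread) is
  the supported remedy.
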