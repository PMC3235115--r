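---
title: "Methods: feature selection for pyroglutamate site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature selection for pyroglutamate site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrosite)
```

## The prediction problem

Pyrrolidone carboxylic acid (pyroglutamate) forms by cyclization of a
glutamine residue. For glutamines in the interior of a protein, whether
a given Q is modified is assumed here to be decided by its local
sequence and structural context: the 10 residues on either side, their
evolutionary conservation, disorder propensity, secondary structure,
solvent accessibility and a handful of physicochemical summaries.
`pyrosite` casts site prediction as binary classification of 21-residue
windows centred on candidate glutamines and — just as importantly —
asks *which* context features carry the signal, via mutual-information
feature ranking and incremental feature selection.

N-terminal pyroglutamate formation is a deliberately separate problem:
most proteins carrying an N-terminal site are too short for a full
upstream flank, and the package only considers sites at position ≥ 2
(the `min_internal_pos` argument; raise it to be stricter about what
counts as "internal", the default 2 excludes only the initiator
residue).

## Dataset construction

`build_positive_set()` extracts one window per annotated internal site
and removes exact duplicate 21-mers, keeping the first occurrence in
input order. Deduplication operates on the full window string, not on
the site identity; two annotations in homologous contexts collapse to
one training fragment. `build_negative_set()` pools every internal,
unannotated glutamine, drops windows identical to a positive fragment
or to an earlier candidate, and draws `ratio × n_positive` windows
uniformly without replacement (default ratio 5, mirroring the class
imbalance of curated PCA annotations, where unmodified internal
glutamines outnumber modified ones severalfold). The draw is governed
by an explicit integer seed recorded on the result, because an
unseeded subsample cannot be reproduced or audited.

Windows shorter than the full width are padded with `-`. Pads are
contiguous prefixes/suffixes by construction and contribute zero to
every feature except the carbon-count deviation (below).

## The 727-column feature space

`build_schema()` fixes the column order once and for all as a pure
function of the flank: sites ascending, and within a site PSSM (20,
alphabetical), amino-acid factors (5), disorder, secondary structure
(helix, strand, other), accessibility (buried, exposed),
interface/surface propensity (2), gain/loss, carbon deviation. The
centre site hosts a constant residue, so its residue-identity families
(factors, interface/surface, gain/loss) are dropped: 27 columns there,
35 at each of the 20 flanking sites, 727 in all. Names follow the
`AA<site>-<feature>` convention (`AA10-Pssm_A`,
`AA2-Codon Diversity`, ...), so ranked lists read naturally as
site/feature pairs.

Feature families and their sources:

* **PSSM conservation** — the first 20 numeric columns (the log-odds
  block) of PSI-BLAST's ASCII matrix, reordered to the package's
  alphabet. The log-odds block is the conventional choice for
  conservation features; the percentage block would change scales but
  not the machinery. No scaling is applied by default: the cosine
  distance is scale-sensitive, so any standardization should be an
  explicit, recorded decision rather than a hidden default.
* **Amino-acid factors** — Atchley's five-factor summary of amino-acid
  physicochemistry (polarity, secondary-structure propensity,
  molecular volume, codon diversity, electrostatic charge), embedded
  from the published factor solution.
* **Disorder** — one score per residue in [0, 1], as produced by
  disorder predictors such as VSL2 (parsed from a TSV track; the
  predictor itself is never invoked).
* **Secondary structure / accessibility** — 3-state and 2-state calls
  (SSpro-style), one-hot encoded; for every non-pad site exactly one
  SS column and one ACC column is 1.
* **Interface/surface conservation propensity and evolutionary
  gain/loss** — single values per amino acid. These two tables are the
  least standardized inputs in the literature; the package embeds
  documented defaults (hydrophobic/aromatic residues most conserved at
  interfaces; the universal gain/loss ordering with Cys/Met/His gained
  and Pro/Ala/Glu/Gly lost) and `load_property_tables()` accepts
  user replacements for any table, which is the supported route when a
  specific published table must be matched.
* **Side-chain carbon deviation** — the residue's side-chain carbon
  count minus the mean count over its own window; pads enter with the
  20-residue mean (3.35 carbons), so an all-pad window deviates
  nowhere. The sign convention (residue − window mean) is one of two
  readings of "deviation from the mean"; it is recorded in the matrix
  sidecar metadata, and a global sign flip of this one family leaves
  cosine-distance ranking and symmetric discretization unchanged.
  The 21 values of any window sum to zero — a useful validity check
  carried by the tests.

## mRMR ranking

Relevance and redundancy are both plug-in mutual information in bits
over discretized columns. The default discretization is the
three-state mean ± σ rule (below μ − kσ, between, above μ + kσ; k = 1),
matching common practice for mRMR on continuous features; an
equal-frequency binning and a pass-through for already-categorical
data are provided. Boundary values fall in the outer states, and a
constant column maps to a single category (its MI with anything is 0).

Selection is greedy: round 1 takes the feature with maximal
relevance; round h maximizes relevance minus the mean MI with the
h − 1 already-selected features (the difference form, the original
mRMR default; the quotient form is exposed as `variant = "miq"`). Ties
are broken toward the lowest original column index so rankings are
deterministic. The full permutation is returned with per-round
criterion scores; note the criterion is not monotone in h and its
absolute values are not comparable across rounds.

One behavioural subtlety worth knowing: an exact duplicate of an
already-selected column is heavily penalized in round 2 (its
redundancy equals its entropy), but as more features are selected the
*mean* redundancy dilutes, so a duplicate is guaranteed to rank
strictly after its twin — not necessarily last.

## Classification, jackknife, IFS

The nearest-neighbour rule uses D(x, y) = 1 − cos(x, y) ∈ [0, 2] and
assigns the label of the closest training sample, breaking distance
ties toward the lower sample index. `nna_distance()` refuses zero
vectors (the cosine is undefined); inside the vectorized jackknife and
IFS sweeps, a zero-norm row (possible when a small feature subset is
all-zero for a sample, e.g. a single one-hot column) is instead
assigned zero similarity — distance 1 — to everything, so a sweep over
sparse prefixes cannot abort.

Jackknife (leave-one-out) evaluation predicts each sample from all
others and accumulates TP/TN/FP/FN. Metrics follow the standard
formulas; when any factor of the MCC denominator is zero the MCC is
reported as 0 (the usual convention for degenerate margins), and a
zero-denominator sensitivity or specificity is likewise 0.

IFS evaluates prefixes of the ranking of sizes 1, 1 + stride, ...
(stride 1 by default; the full set is always included) and records the
metrics per prefix. The optimal subset is the *smallest* prefix
attaining the maximum MCC — a determinism rule needed because MCC
plateaus are common. Implementation-wise the Gram matrix is updated
incrementally as columns are appended (one rank-one update per
feature), making a stride-1 sweep over hundreds of features cost a few
seconds rather than a fresh O(n²p) evaluation per prefix; each
recorded row is identical (up to floating-point summation order) to an
independent `jackknife()` on that prefix, which the tests check
directly.

`pyrosite_fit()` wraps discretize → rank → IFS into a single model
object with `print`, `summary`, `plot` (the IFS curve) and `predict`
(nearest neighbour on the optimal subset) methods.

## The synthetic generator

Real inputs require external tools (PSI-BLAST against a large
database, disorder and secondary-structure predictors), so the package
ships two seeded generation routes:

* the **window + profile route** (`generate_windows()`,
  `synthesize_profiles()`, `generate_fixture()`) emulates the input
  formats end to end — FASTA, site tables, ASCII PSSM files, track
  TSVs — with integer PSSM scores ~ round(N(0, 3)), uniform disorder,
  and categorical SS/ACC draws; an optional bias shifts PSSM scores
  around positive sites to plant a recoverable label signal;
* the **direct matrix route** (`generate_matrix()`) skips encoding and
  plants a mean shift of `effect_size` column standard deviations on
  chosen informative columns (class-tilted category probabilities for
  one-hot families when a schema is supplied), leaving all other
  columns label-independent unit-variance noise.

The default planted-signal condition — 100 positives at 1:5 imbalance
(600 samples), 10 informative columns among 200, 3σ separation — is
strong enough that the informative columns are cleanly separable, and
the suite verifies over repeated seeds that mRMR surfaces at least 8
of the 10 in its top 20 ranks and that IFS reaches MCC ≥ 0.9 with an
optimum between 5 and 40 features. What these generators do *not*
emulate is real evolutionary structure: PSSM columns are independent,
there are no sequence motifs, compositional biases or
between-feature correlations beyond the planted signal. Passing tests
therefore demonstrate that the machinery recovers signal it should
recover, not that any particular performance level will be reached on
curated PCA data, whose headline metrics depend on the external
annotation tools.

## Problem sizes and costs

The test suite and the acceptance script run at deliberately modest
sizes chosen to exercise every code path: oracle cross-checks at ≤ 8
features × ≤ 80 samples (mRMR) and 20 samples (jackknife), the
planted-signal condition at 600 × 200, and dataset-assembly arithmetic
at the full 1998-sample scale (pure string work). A stride-1 IFS sweep
at 600 × 200 takes on the order of two seconds; the `stride` parameter
exists for much wider matrices, at the cost of only sampling the IFS
curve.

## Known limitations

* Performance numbers on curated PCA datasets are not reproducible
  from this package alone: the PSSM/disorder/SS/ACC inputs come from
  external predictors and databases whose versions dominate the
  result. The package reproduces exactly the schema and
  dataset-assembly arithmetic, and substitutes planted-signal recovery
  for headline-metric reproduction.
* The gain/loss and interface/surface tables are documented defaults,
  not canonical constants; override them when matching a specific
  published encoding.
* The plug-in MI estimator is biased upward at small n; rankings are
  still well-behaved because all features share the estimator, but
  criterion scores should not be read as calibrated information
  content.
* Only the jackknife evaluation mode is shipped, and only the
  1-nearest-neighbour classifier; both match the method being
  dissected rather than the state of the art in classification.
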