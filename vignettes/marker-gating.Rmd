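---
title: "Mining and applying marker tables: the methods behind gatescribe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and applying marker tables: the methods behind gatescribe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatescribe)
```

## The problem

Flow and mass cytometry quantify tens of protein markers on 10^4^–10^6^
single cells. Analysts traditionally label cell populations by *manual
gating* — sequential thresholding on two-dimensional intensity plots — which
is slow, low-dimensional and operator-dependent. Marker-table classifiers
replace the drawn gates with a declarative table: for each cell type, which
markers are positive (`+`), medium (`m`), negative (`-`) or irrelevant
(`*`). gatescribe implements both directions of this idea:

* **annotation** — given a marker table (written by hand or mined), label
  every cell of a dataset;
* **training** — given an annotated reference dataset, mine a minimal
  marker table that a human can read, audit and edit.

The package assumes intensities are already compensated and
variance-stabilised (an explicit `arcsinh_transform()` is offered, cofactor
5 being the mass-cytometry convention); spectral unmixing and
Logicle/biexponential transforms are upstream concerns out of scope.

## Calling expression levels per marker

The core primitive is a per-marker univariate Gaussian mixture
$p(x) = \sum_{i=1}^{G} \phi_i\, \mathcal{N}(x \mid \mu_i, \sigma_i)$ fitted
by expectation-maximisation, with $G = 2$ components for markers only ever
used as positive/negative and $G = 3$ when a medium level is in play
(`required_levels()` derives $G$ from the table). Cells take the symbol of
the maximum-a-posteriori component, symbols ordered by the component means
(`-` lowest, `+` highest). Two parameterisations are supported, following
standard mixture practice: equal variance (`"E"`, one shared
$\sigma$) and variable variance (`"V"`, one $\sigma_i$ per component). The
right choice is data-dependent — equal variance is more robust when one
component is sparse, variable variance adapts to unequal population
spreads — so it is a user-facing parameter, defaulting to `"E"`.

Numerical choices (all deliberate, all documented in `fit_marker_gmm()`):

* initialisation at the $(i-0.5)/G$ sample quantiles, uniform weights,
  pooled standard deviation — deterministic, so fits are reproducible
  without random restarts;
* convergence when the relative log-likelihood change drops below 1e-8,
  at most 500 iterations; the best iterate is returned with
  `converged = FALSE` when the cap is hit;
* standard deviations floored at 1e-4 of the pooled value to keep
  single-point components from collapsing;
* exact posterior ties assign the lower-mean component — deterministic and
  conservative towards `-`;
* all-identical input is a degeneracy error, not a fit.

### Ranked-set sampling of the informative tail

Cytometry markers are often heavily skewed: a dominant negative mode and a
sparse positive tail (or the mirror image). To keep the sparse mode from
being swallowed, the fitting sample can be preconditioned by ranked-set
sampling (`use_rss`): per cycle, draw $m^2 = 4$ points, arrange them into
two ranked sets of two, and keep the first-ranked unit of the first set
(leftmost stratum) and the second-ranked unit of the second set (rightmost
stratum). The strata are the extreme order statistics of the marker — for
a Uniform(0,1) marker their means are exactly 1/3 and 2/3, which the test
suite checks. `select_tail_sample()` keeps the stratum opposite the skew
(rightmost for positive skewness, leftmost otherwise, with skewness
exactly 0 — e.g. a symmetric sample — taking the leftmost branch), and the
mixture is fitted on that stratum while symbols are assigned to *all*
cells under the fitted model.

Decisions the procedure's description leaves open, resolved here once:

* draws are with replacement, so the cycle count may exceed a quarter of
  the dataset; the default `n_cycles = min(n, 50000)` keeps preconditioning
  linear in the dataset size;
* ranking uses exact values with stable ordering (no tie jitter);
* the mixing weights estimated on the tail-biased stratum are used as-is
  for assignment; they are biased towards the selected tail, which shifts
  the decision boundary *towards* the dominant mode — the intended "zoom"
  effect. No reweighting pass is applied.

Empirically (and by design of the defaults), the equal-variance mode does
not benefit from RSS while the variable-variance mode does, so `use_rss`
defaults to off under `"E"` and on under `"V"` throughout the package.

## The marker-table grammar

An entry is a comma-separated list of token groups over markers:

* `CD14+,CD3-` — two AND tokens, fixing two markers;
* `CD11b+|CD11c+|` — an OR group: at least one token holds;
* `CD11b+^CD11c+^` — an XOR group: exactly one token holds;
* `CD19*` or simply omitting a marker — wildcard.

`hi`/`mid`/`lo` spellings are accepted and normalised to `+`/`m`/`-`
(labels and tables in the wild use both). Operator groups need at least
two tokens, may not mix `|` and `^`, and may not contain `*`; XOR over
more than two tokens means *exactly one holds*. Two CSV dialects exist:
a *wide* one (rows = cell types, columns = markers, blank = wildcard) and
a *compact* one (`cell_type,signature`) — only the latter can express
OR/XOR. Both round-trip through `read_marker_table()` /
`write_marker_table()`.

A concrete *signature* assigns one symbol to every marker of the table's
universe; an entry *expands* to the set of concrete signatures satisfying
it. Expansion is combinatorial (the product of level counts over the
unconstrained markers), so entries are represented by their membership
predicate; `expand_cell_type()` materialises on demand and refuses beyond
12 free markers. Matching never materialises anything.

Because wildcards and operators let several entries claim the same
signature, matching uses an ordered dictionary (`build_dictionary()`).
Priority is: more markers at high or medium expression in the defining
entry first, then more constrained markers overall, then table order. The
first component is the domain rule — the gate that *asserts* expression
beats the gate that merely tolerates it; the latter two are this package's
deterministic tie-breaks. Since the key depends only on the entry, lookup
over entry predicates is exactly equivalent to lookup over materialised
records, which is what the brute-force oracle in the test suite verifies
on randomly generated tables.

## Training: mining a table from a reference

`extract_marker_table()` builds the reference's signature matrix, then
walks all unordered pairs of cell types in lexicographic (C-locale) name
order — the pair order is fixed because the update guard below makes the
result order-dependent, and reproducibility wins. For each pair it fits a
binary classification tree (rpart) on the ordinally encoded symbols
(`- < m < +`), scores each marker by the total goodness-of-split of the
primary splits it owns, and takes the arg-max as the pair's top
discriminant (ties to matrix column order). Each of the two entries then
records the marker's *modal* symbol over that type's cells (ties towards
higher expression) — **unless the entry already constrains the marker**,
in which case it is left untouched.

That per-entry guard is a deliberate design choice where the procedure
could also be read as "skip the pair when either entry has the marker".
The per-entry reading is the one that keeps three-level designs workable:
when a base type is split into `<base>_<marker>-` / `mid` / `hi` variants,
every pair among the variants selects the same marker, and only the
per-entry update lets all three variants record their own symbol (the
both-entries guard would always leave one variant without it). It also
preserves minimality — a marker still only ever enters an entry as some
pair's top discriminant — and never overwrites an existing symbol.

Medium expression is opt-in by labelling convention
(`detect_medium_markers()`): a marker is modelled with $G = 3$ iff some
base type appears with all three suffixed variants. Tree settings (depth
3, minimum leaf 5, no surrogate splits) suit three-level ordinal features
with no missing data; cells labelled `unknown`/`unclassified` are excluded
from training by default. Types below a 20-cell floor are rejected:
pairs that small cannot support the tree's leaf-size constraint.

## Annotation: sampling, matching, refinement

`annotate_cells()` runs four stages:

1. **SRS** — classify only a `srs_fraction` subsample directly (default
   0.1, with a 500-cell floor for tiny inputs): a small subset suffices to
   pin each cluster, and the rest is cheaper to label by similarity.
2. **Signatures and matching** — mixture signatures for the sampled cells;
   each matches the highest-priority dictionary entry it satisfies, or
   `unclassified`.
3. **Reject option (optional)** — mutual nearest neighbours between the
   matched (A) and unmatched (U) sampled cells, with each cell's
   $k$-neighbourhood computed in the pooled set. A genuinely novel
   population fills its neighbourhoods with itself and forms *no*
   cross-set pairs, so U cells with no pairs become confident unknowns
   (U′, labelled `unknown`); matched cells with more than $k/2$ pairs
   into U are ambiguous (likely matching errors) and are re-queried. The
   pooled-neighbourhood definition is essential: if neighbourhoods were
   restricted to the opposite set, every cell would always have $k$
   cross-neighbours and arbitrarily distant clusters would still pair.
4. **k-NN refinement** — majority vote (ties to the single nearest
   neighbour) among the $k$ nearest training cells, training on A (or
   A′ ∪ U′ under the reject option) and querying everything else,
   including the unsampled cells. Distances are Euclidean over the raw
   transformed intensities of the table's markers — symbols are too
   coarse for neighbourhoods.

Defaults: `k = 10` for both MNN and k-NN (a common neighbourhood size at
cytometry densities; the ambiguity threshold "more than half of k" is
configurable in spirit but fixed here), `reject_option = FALSE`,
`srs_fraction = 0.1`. Every stochastic stage derives its stream from the
single `seed`, so runs are bit-reproducible; with full sampling, no reject
option and every cell matched, the pipeline provably reduces to direct
dictionary matching (tested).

Unsampled cells are pure k-NN queries: they take no part in the MNN stage,
which only compares cells whose signatures were actually computed.

## Evaluation

`overall_accuracy()` is the percentage of exact label matches;
`per_label_prf()` computes one-vs-rest precision, recall and F1 per
*reference* label with zero-denominator fractions defined as 0 (a label
never predicted scores 0 rather than dropping out); `median_f1()`
summarises. Unknown/unclassified are ordinary labels for these metrics —
merging rare populations into an unknown bucket is standard practice —
and `evaluate_annotation()` reports the median F1 both with and without
the unknown class, since either convention is defensible.

## What the synthetic generator does and does not show

`generate_dataset()` draws each cell's type from stated proportions,
instantiates a concrete signature uniformly from the type's expansion
(wildcards therefore exercise every branch), and draws marker values from
the Gaussian component of each level symbol. The standard study
conditions used across the tests and the acceptance script are: the
four-type/six-marker immune design of `example_generator_spec()` (level
means 0 and 1.8, sd 0.3 — a 6-sd separation at which level calls are
essentially noise-free, so failures indicate logic errors rather than
noise), n = 20 000 cells, 10 % direct sampling; the three-level design of
`example_medium_spec()` adds a `mid` component at 1.8 between 0 and 3.6;
planted unknown populations sit at least 8 pooled sds from every defined
level on at least one marker (verified at generation time). An optional
monotone `x \mapsto s(e^{x/s}-1)` map induces positive skew for
exercising the RSS path.

This emulates exactly the data model the level-calling step assumes.
Real cytometry data adds what the generator omits — spillover between
channels, doublets and debris, acquisition-time drift, non-Gaussian and
overlapping components, correlated markers. Passing tests therefore
demonstrate correctness of the algorithms under their own model, not
field performance; on real data the variance mode, RSS and the reject
option need to be chosen by inspecting the marker distributions.

## Known limitations

* The number of mixture components per marker is dictated by the table
  (or the label suffixes), never estimated from the data; a marker that
  is genuinely trimodal but declared binary will be mis-thresholded.
* The variance parameterisation is global, not per marker.
* Signature generation treats markers independently; correlated spillover
  violates that.
* The wide CSV dialect cannot express OR/XOR entries.
* The FCS reader covers list-mode floating-point FCS 3.0/3.1 files only —
  integer-mode files from older instruments are rejected rather than
  converted.
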