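# gatescribe

Marker-table gating, mining and annotation for flow and mass cytometry
data.

Cytometry experiments measure protein markers on single cells, and the
classic way to assign cell types — manual gating — is slow and
operator-dependent. gatescribe automates it around a **marker table**: per
cell type, a pseudo-gating strategy stating whether each informative marker
is positive (`+`), medium (`m`), negative (`-`) or unconstrained (`*`),
with optional OR (`CD11b+|CD11c+|`) and XOR (`CD11b+^CD11c+^`) conditions.
Unlike purely reference-based classifiers, the table stays human-readable
and editable; unlike purely manual tables, it can be **mined automatically
from an annotated reference dataset**.

The method, in brief:

* per marker, expression levels are called with a univariate Gaussian
  mixture `p(x) = Σ φᵢ N(x | μᵢ, σᵢ)` (G = 2, or 3 when a medium level is
  used; equal- or variable-variance parameterisation), cells taking the
  symbol of the maximum-a-posteriori component; skewed markers can be
  preconditioned by ranked-set sampling of the tail opposite the skew;
* cell signatures are matched against an ordered dictionary expanded from
  the table (wildcards and OR/XOR resolved by priority: more `+`/`m`
  markers first, then more constrained markers, then table order);
* a 10 % random subsample is classified directly and the rest labelled by
  k-NN refinement; with the *reject option*, mutual-nearest-neighbour
  confident sets let genuinely novel populations keep the label
  `unknown`;
* training mines the table from an annotated reference via pairwise
  classification trees, always recording only each pair's most
  discriminant marker (three-level markers are declared by
  `<base>_<marker>-/mid/hi` label suffixes);
* evaluation reports overall accuracy plus one-vs-rest precision, recall,
  F1 and median F1.

## Worked example

Generate a seeded four-population benchmark (CD4/CD8 T cells, B cells,
monocytes over six markers), mine a marker table from it, annotate, and
score:

```r
library(gatescribe)

spec <- example_generator_spec(n_cells = 20000, seed = 1)
ds   <- generate_dataset(spec)

mined <- extract_marker_table(ds$matrix, ds$labels, seed = 42)
print(mined)
#> marker_table: 4 cell type(s) over 3 marker(s)
#>   Bcell: CD19+,CD3-
#>   Monocyte: CD19-,CD3-
#>   Tcell_CD4: CD3+,CD4+
#>   Tcell_CD8: CD3+,CD4-

ann <- annotate_cells(ds$matrix, mined, srs_fraction = 0.1, seed = 7)
table(ann$provenance)
#>             direct unsampled->refined
#>               2000              18000

ev <- evaluate_annotation(ann$label, ds$labels)
cat(sprintf("accuracy: %.2f%%  median F1: %.3f\n", ev$accuracy, ev$median_f1))
#> accuracy: 99.73%  median F1: 0.997
```

The mined table is minimal: of the six markers, only the three needed to
separate the four types appear (CD3 splits T from non-T, CD4 the T
subsets, CD19 B cells from monocytes), each with the correct sign; the
uninformative wildcard marker (CD56) never enters. 2 000 cells (10 %) were
classified directly from their signatures; the other 18 000 were labelled
by 10-nearest-neighbour refinement, and 99.73 % of all 20 000 cells match
the generating labels, with per-label F1 ≥ 0.996.

With a novel population planted away from every table-defined level,
`annotate_cells(..., reject_option = TRUE)` leaves it labelled `unknown`
instead of forcing it into a table type.

## Command line

The same pipeline is scriptable via the installed `gatescribe` launcher
(or `Rscript -e 'gatescribe::run_cli()' --args ...`):

```sh
gatescribe simulate --output bench --n-cells 20000 --seed 1
gatescribe train    --input bench_expression.csv --labels bench_labels.csv \
                    --output mined.csv --seed 42
gatescribe annotate --input bench_expression.csv --marker-table mined.csv \
                    --output annotation.csv --seed 7
gatescribe evaluate --input annotation.csv --labels bench_labels.csv \
                    --output metrics.csv
```

Key flags: `--variance {E,V}` (mixture parameterisation, default E),
`--rss {on,off,auto}` (ranked-set tail preconditioning; auto = on under
V), `--srs-fraction` (default 0.1), `--reject-option`, `--k` (default 10),
`--seed`, `--arcsinh-cofactor`, `--dialect {wide,compact}`. Identical
arguments with a fixed seed produce byte-identical outputs.

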