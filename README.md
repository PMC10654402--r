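# swcforge

Digital reconstructions of neuronal and glial morphology — skeletons of
sample points with position, thickness, connectivity and structural
domain — circulate in dozens of tracing-software formats, which
hampers reuse. The SWC text format is the community's common ground:
seven whitespace-delimited columns per traced point

```
index  type  x  y  z  radius  parent
```

with `type` coding the structural domain (1 soma, 2 axon, 3 basal
dendrite, 4 apical dendrite, ...), coordinates and radius in
micrometers by convention, and `parent = -1` marking a root. In a
standardized file the first sample is a root, indices run 1..N, and
every parent precedes its children.

`swcforge` gives R users, and shell users through a thin CLI, three
things:

- **Validation and repair.** An ordered battery of specification
  checks — column shape, line counts, soma presence, invalid parents,
  malformed index/type/coordinate/radius fields, row order — each with
  its deterministic correction, in check-only or repair mode.
- **Soma contour handling.** Files that trace the cell-body perimeter
  are detected with a curvature test: for a soma section A, P1..Pn-2,
  C the remote point B = argmax_i(‖A−Pi‖ + ‖C−Pi‖) defines the angle
  θ = ∠ABC; sections with θ < 90° are contours and are collapsed to a
  single point at the contour centroid with radius equal to the mean
  center-to-point distance, while θ ≥ 90° frustum stacks are retained.
- **Conversion.** Readers for NeuronJ `.ndf`, Neurolucida `.asc`,
  NEURON `.hoc`, Eutectic `.nts`, KNOSSOS `.nml`, NeuroML v1/v2 and
  extended SWC, all funneled through a segment-path intermediate
  representation, with SWC defaults (radius 0.5, type 0, z 0 where a
  format stores none) inserted so converted files always standardize
  cleanly.

A deterministic synthetic-morphology generator
(`generate_morphology()`, `render_fixture()`, `corrupt_swc()`) makes
the whole pipeline testable without any external data.

## Worked example

```r
library(swcforge)

bad <- c("# a malformed tracing",
         "1 1 0.0 0.0 0.0 5.0 -1",
         "3 3 2.0 0.0 0.0 -1.0 1",
         "2 3 1.0 0.0 0.0 1.0 99",
         "4.00 2 3.0 0.0 0.0 1.0 3")
res <- standardize(read_swc(bad)$morphology)
res
#> <swc_standardization> is_standard: FALSE; 6 log entries
#> [warning] Number of Lines: fewer than 20 lines (4); check file integrity
#> [warning] Invalid Parent: parent 99 does not exist; sample made a root point (lines 4)
#> [info] Index/Parent Integer: float-formatted index '4.00' reformatted as integer (lines 5)
#> [warning] Radius Positive Double: radius '-1.0' set to 0.5; check file integrity (lines 3)
#> [info] Sorted Order: 2 root points present (multi-tree file)
#> [warning] Sequential Index: index values not in sequential order starting from 1; renumbered

writeLines(write_swc(res$morphology))
#> # a malformed tracing
#> 1 1 0.0 0.0 0.0 5.0 -1
#> 2 3 2.0 0.0 0.0 0.5 1
#> 3 2 3.0 0.0 0.0 1.0 2
#> 4 3 1.0 0.0 0.0 1.0 -1
#> # swcforge-note: radius at original line 3 set to 0.5
```

The log reads top to bottom in execution order: the parent pointing at
a nonexistent index 99 turned that sample into a root, the negative
radius became the 0.5 default (with a footer note marking the inserted
value), the float-formatted index was reformatted, and the rows were
renumbered 1..N with parents ahead of their children. `is_standard`
is `FALSE` because corrections were needed; running `standardize()`
again on the result applies none.

Converting a batch from the shell:

```sh
Rscript inst/cli/swcforge.R convert tracings/*.asc tracings/*.hoc --out converted/
Rscript inst/cli/swcforge.R check converted/*.swc
```

`convert` writes one standardized `.swc` and one `.log` per input and
exits 0/1/2 for all/some/none succeeded; `check` verifies SWC files
without touching them.

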