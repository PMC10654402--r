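---
title: "Standardizing and converting neural morphology reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing and converting neural morphology reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swcforge)
```

## The SWC data model

A skeletonized reconstruction of a neuron or glial cell is a tree of
sample points. The SWC text format stores one point per line with seven
whitespace-delimited fields: a sequential **index** starting at 1, an
integer **type** coding the structural domain (0 undefined, 1 soma,
2 axon, 3 basal dendrite, 4 apical dendrite, 5 custom, 6 unspecified
neurite, 7 glia process, above 7 user-defined), the **x, y, z**
coordinates and the **radius** (half the local thickness) as floats,
conventionally in micrometers, and the **parent** index, `-1` for a
root. Lines starting with `#` before the data form a free-text header
(commonly metadata tags such as `#creature` or `#region`); lines after
the data form a footer, which is also where extended-SWC signal columns
and synapse blocks (`#start synapse` ... `#end synapse`, nine fields
per record) live. Files are plain ASCII.

`read_swc()` deliberately keeps the raw field tokens of every data
line: the checks below need to distinguish `1` from `1.00` from `abc`,
which the numeric view alone cannot do.

## The check battery

`standardize()` runs a fixed, ordered sequence of checks; in repair
mode each check applies its correction, in check-only mode
(`repair = FALSE`) nothing is ever mutated and only the log is
returned. The order matters: parent repair must precede sorting, and
sorting must precede soma-contour analysis, which assumes a
well-formed tree.

1. **Missing Field** — a row without exactly seven fields is an
   unrepairable, terminal error: such files usually indicate
   truncation or a mislabeled format, and every later check assumes a
   rectangular table.
2. **Number of Lines** — zero data rows is a terminal error; fewer
   than 20 rows earns an integrity warning (tracings that small are
   almost always fragments).
3. **Number of Soma Samples** — a warning when no type-1 point exists.
4. **Invalid Parent** — a parent referencing a nonexistent index
   (including a point naming itself) is rewritten to `-1`, turning the
   point into a root. This is always repairable and loses no points.
5. **Index/Parent Integer** — float-formatted integers (`3.00`) are
   reformatted silently-with-info; genuinely non-integer or
   non-numeric values are errors, and the whole file is refused rather
   than dropping rows, since a corrupt index makes the tree ambiguous.
6. **XYZ Double** — NaN/NA coordinates (any capitalization) become
   `0.0`, with a warning and a footer note
   (`# swcforge-note: <field> at original line <n> set to <value>`)
   so the inserted default remains visible in the output file.
7. **Radius Positive Double** — a negative, zero, NaN, NA or
   non-numeric radius becomes `0.5`, with the same warning-plus-note
   treatment.
8. **Non-Standard Type** — numeric reformatting as for indices;
   non-numeric types become 0 ("undefined"). Additionally, some
   tracing tools emit types 5 and 6 at bifurcations and terminals as
   *topology markers* rather than domains; at those nodes a 5 or 6 is
   replaced by the parent's type. A 5 or 6 at a continuation point is
   left alone — type 6 is a legitimate "unspecified neurite". Types
   above 7 are treated as legal custom codes and only noted.
9. **Sequential Index / Sorted Order** — rows are re-sorted so the
   first sample is a root, indices run 1..N, and every parent precedes
   its children. Rather than looping alternate renumber/rearrange
   passes until a fixed point, the implementation does one
   deterministic pre-order traversal from each root (children in
   original file order, multiple roots kept in file order), which
   satisfies the same contract in a single pass and makes the output
   order reproducible. A file with no root at all cannot be sorted and
   is an unrepairable error. Mutual parent cycles — unreachable from
   any root but with every parent index present — are broken by
   promoting the first cycle row to a root, logged as an invalid
   parent.
10. **Soma Contours** — see below.

`is_standard` is `TRUE` only when the battery found no errors and
applied no content-changing correction; advisory warnings (short file,
no soma) do not count against it. Because every correction is
convergent, standardizing an already-repaired morphology applies zero
corrections — the idempotence property the test suite exercises over
200 defect-seeded fixtures.

Multiple roots (multi-tree files) are accepted throughout and noted
informationally: they are common in converted contour-bearing formats,
where neurites and soma outlines are separate top-level objects.

## Soma contours

Some tracing software outlines the cell-body perimeter instead of
placing soma points along its axis. A *soma section* is a run of three
or more contiguous type-1 points whose first point is a root and whose
last point is the first bifurcation or terminal along the chain.
Writing the section as A, P1..Pn-2, C, the *remote point* B is the
interior point with the largest `||A-P|| + ||C-P||` (ties broken at
the lowest position; distances are 3-D, so tilted contours are handled
without projection). The curvature angle is the angle at B in the
triangle A-B-C, computed from the clamped normalized dot product in
double precision.

- angle ≥ 90°: the section is a stack of frustums along the soma axis
  and is retained as is (the boundary case is deliberately retained);
- angle < 90°: the section closes back on itself — a contour — and is
  replaced by a single point at the mean of all section points, with
  radius equal to the mean distance of the points from that center.
  For a regular polygon this recovers the circumcenter and
  circumradius exactly.

Runs shorter than three points, and soma runs that end by flowing into
a non-soma continuation rather than at a bifurcation or terminal, are
exempt from the test; soma points deeper in the tree are never tested
(noted informationally). When several contours are present each is
collapsed and the resulting points are chained in file order — first
point a root, each next point parented to the previous — which is the
simplest connected reading of a "series of points"; the choice is
recorded in the log. Neurites that were attached anywhere on a
replaced contour are re-parented to that contour's collapsed point. A
degenerate section whose remote point coincides with an endpoint
cannot be tested and is retained for manual review. If all contour
points coincide the collapsed radius would be zero and is raised to
0.5, mirroring the radius rule.

## Converters and their pinned dialects

Source formats are mapped through a common intermediate
representation: a forest of `segment_path` objects (polylines with a
domain code, optional per-point radius, and an attachment point on a
parent path). `paths_to_morphology()` flattens the forest depth-first,
merging junction points duplicated by hierarchical formats (tolerance
1e-6) and inserting the SWC defaults — radius 0.5, type 0 — wherever
the source stores nothing, so no converted sample ever has an unset
field. Coordinates are copied verbatim: units are metadata, and no
axis flips or scaling are applied.

Each reader pins one documented dialect; unknown non-structural
constructs (spines, markers, colors, text annotations) are skipped
with a note, while malformed structural constructs are errors:

- **NeuronJ NDF** — `// Tracing` blocks of alternating x/y coordinate
  lines. The format is a 2-D projection without thickness, so z = 0
  and radius = 0.5 uniformly; tracing labels map to domain codes.
- **Neurolucida ASC** — parenthesized trees `((Dendrite) (x y z d)
  ... )` with `|`-separated daughter branches and quoted-string
  contours; `CellBody` contours become soma paths that the curvature
  test then collapses. Stored values are diameters, halved on import.
- **NEURON HOC** — `create`/`connect`/`pt3dadd` geometry subset;
  array declarations expand; section names containing
  soma/axon/dend/apic choose the type; `child(1)` orientation reverses
  the child's points; the connect fraction selects the nearest sample
  of the parent section. Only the NEURON-native variation is pinned —
  the format has many vendor variations and the others are out of
  scope here.
- **Eutectic NTS** — reverse-engineered point-per-line dialect with
  type mnemonics; tree origins (MTO/DTO/BTO/TTO/SOS) choose domains
  (axon / basal / apical / unspecified / soma outline), BP pushes a
  branch point on a stack and the end mnemonics (NE, MAE, TAE, BAE,
  SOE) pop it, so the next point resumes at the most recent open
  branch. Thickness is halved into radius.
- **KNOSSOS NML** — XML node/edge lists; each connected component is
  re-rooted at its lowest node id (the format marks no root), cycles
  are rejected, and the format stores no domain, so type 0.
- **NeuroML** (v2 `<neuroml>` and v1 `<morphml>`, namespaces
  stripped) — distal points become samples; a parentless segment's
  proximal point becomes the tree root, and a zero-length root segment
  (the spherical-soma convention) becomes a single sample;
  `segmentGroup`/`cable` names choose domains.
- **ESWC** — columns beyond the seventh are moved to footer lines
  keyed by the index as parsed from the source; renumbering, if the
  file later needs it, does not rewrite those keys.

Format detection prefers the file extension and falls back to content
sniffing; the two unrelated `.nml` schemas are separated by the XML
root element, and SWC versus ESWC by the column count of the first
data row.

Converted morphologies always pass through `standardize()`, so
conversion artifacts (contour somata, unsorted rows) are repaired in
the same pipeline as native SWC defects.

## The fixture generator

`generate_morphology()` exists so every stage is testable without
external data. It is deterministic by construction: randomness comes
from R's Mersenne-Twister with inversion normals, explicitly selected
and restored, so a given `fixture_spec` and seed are byte-stable
across platforms. Defaults (two neurite trees, two bifurcations each,
jitter SD 0.1 µm, branch directions on a 25° cone, log-normal step
lengths around 3 µm, radii tapering by 0.85 per branch order) are
chosen to look like a small dendritic arbor; they are realism dressing
only — the tests rely on topology and field values, not on
morphometric statistics, and the generator makes no claim of
biological realism (no literature branch-angle distributions, no
domain-specific taper). Soma styles map to the four arrangements the
pipeline must distinguish: a single point, a collinear frustum stack
(curvature angle 180°, retained), one 8-point circular contour
(acute, collapsed), or two stacked contours (collapsed to a chain).
Coordinates are stored to three decimals, so "exact" recovery
assertions on generated data carry a 1e-3 tolerance; the exact-recovery
property proper is tested on analytically constructed polygons.

What passing these tests shows — and does not. The renderers emit one
pinned dialect per format, so round-trip equality demonstrates that
converter logic (topology rebuilding, junction merging, default
insertion, diameter halving) is correct for those dialects; it cannot
certify behavior on the full variation space of real-world exports,
which differ in undocumented ways. ASC cannot express attachment of
neurites to a soma, so ASC round-trips use fixtures with detached
trees, which is also how the real format arranges them.

`corrupt_swc()` seeds exactly one defect per requested check id into
an otherwise standard file and records the ground truth, which gives
the battery a coverage test: each check fires on its dedicated fixture
and stays silent on clean ones. Combinations that cannot coexist (an
empty file plus anything, a missing field plus later checks, scaling
indices plus re-sorting) are rejected rather than silently under-seeded.

## Numerical choices

- Floats are written as the shortest decimal that parses back to the
  same double, always with a decimal point; integers (index, type,
  parent) are written without one. This makes repair idempotent at
  the byte level.
- The arccosine argument is clamped to [-1, 1]; angles are reported in
  degrees in [0, 180].
- The remote-point argmax tie-break takes the lowest interior
  position, making the curvature test deterministic on symmetric
  contours (a square section ties between its two interior corners).
- Junction merging uses a 1e-6 Euclidean tolerance — far below
  tracing precision but tolerant of decimal round-tripping.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated
data: fixtures of roughly 15-70 samples, 200 defect-seeded files for
the idempotence suite, 50 fixtures by four formats for the round-trip
suite, 100 random rotations for rigid-motion invariance, and polygons
with 3-12 vertices for exact contour recovery. These sizes were chosen
to exercise every code path many times over while keeping a full run
comfortably interactive.

## Known limitations

- One pinned dialect per source format (plus the NeuroML v1/v2 pair);
  binary and proprietary containers (Neurolucida DAT/NRX, Imaris IMS,
  Amira AM, SNT traces, compressed matrices) are out of scope.
- No reverse conversion from SWC to the source formats.
- Standard-compliant files can still encode biologically wrong
  reconstructions (mis-attached branches, unrealistic radii); the
  battery checks format, not anatomy.
- Subcellular annotations (spines, varicosities, puncta), markers and
  anatomical boundaries are intentionally dropped on conversion.
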