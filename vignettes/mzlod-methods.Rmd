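---
title: "Serving LC-MS point clouds at a fixed detail level: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serving LC-MS point clouds at a fixed detail level: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzlod)
```

## The problem

An MS1 map is a cloud of centroided observations, each a triple
(m/z, retention time, intensity). Files routinely hold millions of such
points, while an interactive viewer can render only a few thousand at
once. A useful backend must therefore answer, quickly and repeatably:
*"give me exactly n points that faithfully represent the data inside
this (m/z, RT) rectangle"* — where the n points must be real stored
observations, because an analyst uses them to judge and annotate actual
signals, not renderings of aggregates. Holding n fixed regardless of
viewport (the *detail level*) keeps rendering load, and therefore
perceived performance, uniform across a whole session.

`mzlod` implements that contract in three layers: a streaming mzML
reader, a level-of-detail index built once per dataset (*static
summarization*), and a per-query reduction to the exact point budget
(*dynamic summarization*), fronted by a stateless HTTP JSON API. A
seeded synthetic generator supplies realistic MS1 fixtures so that every
layer is testable offline.

## Streaming mzML extraction

mzML wraps each scan's m/z and intensity vectors as base64-encoded,
optionally zlib-compressed, little-endian IEEE float arrays, annotated
with controlled-vocabulary terms for precision (MS:1000523/MS:1000521),
compression (MS:1000574/MS:1000576), array role (MS:1000514/MS:1000515)
and scan start time (MS:1000016, in seconds or minutes). Because whole
files can reach tens of gigabytes, a reader that materializes the
document (as DOM parsers do) pays memory proportional to file size; a
single-pass reader pays only for one spectrum at a time.

`mzml_stream()` reads the file in fixed 64 KiB chunks, locates each
`<spectrum>…</spectrum>` span in the buffer, decodes it immediately and
discards everything behind it. Consequences that the test suite pins
down:

- the first record is available long before the file has been read
  (under a quarter of the bytes on the fixtures used in testing);
- memory is bounded by one spectrum plus one chunk, independent of
  spectrum count;
- the trailing byte-offset index of an `indexedmzML` wrapper is simply
  ignored — the reader is sequential by design, so both wrapped and
  plain documents take the identical code path.

Retention times are normalized to seconds at parse time whatever the
file declares; the original unit is recorded in the observed dialect.
One internal time convention prevents axis-scale bugs downstream.
Errors are strict by intent: a declared `encodedLength` or
`defaultArrayLength` that disagrees with the decoded payload raises an
integrity error rather than a warning, because silently truncated
arrays corrupt the point cloud they feed. Malformed spectrum XML is
reported with the byte offset at which the element began. Unrecognized
precision or compression terms (integer arrays, numpress) are refused
as unsupported dialects. Binary arrays that are neither m/z nor
intensity are skipped without error, for forward compatibility.

A deliberately conventional whole-document reader, `reference_parse()`,
serves as the in-package oracle: the suite holds the two parsers to
record-for-record identity on every dialect combination, and
additionally cross-checks against proteowizard (`mzR`) as a third,
independently developed implementation. Profile and centroid spectra
are treated uniformly — every array entry becomes a point — since the
downstream index is agnostic to how peaks were produced.

## Static summarization: the level-of-detail index

`build_lod_tree()` prepares a dataset once so that any later query is
cheap:

1. **Culling.** Points with intensity strictly below the floor
   (default 1 arbitrary unit) are dropped as noise. The boundary is
   inclusive — intensity exactly 1 survives — resolving the ambiguity
   between "above the threshold" and "below 1 is noise" in favour of
   keeping boundary signal.
2. **Partitioning.** Retained points are split recursively into
   bounding boxes: at each level the current set is ordered along one
   axis (alternating m/z and RT by depth, ties broken by the other axis
   then id) and cut into `branching` near-equal contiguous runs.
   Recursion stops at `leaf_capacity` points. Median-style splits give
   a balanced, input-order-independent, fully deterministic tree.
3. **Sampling.** Every internal node keeps references (row indices into
   the one shared point table — never copies) to the S most intense
   points of its subtree, ties broken on ascending (mz, rt, id).
   Because each child's sample already contains its subtree's top S,
   the parent's sample is computed from the pooled child samples, and
   the property "a node's sample is the top-S of its descendants" holds
   exactly at every level — the tests verify it by full traversal.

Intensity-ranked sampling (rather than uniform random sampling) is a
design choice: it is deterministic, keeps the visually dominant signal
at every zoom level, and makes results at growing budgets nest inside
one another. The `seed` in `lod_config()` is stored in the index header
so a rebuild is reproducible by contract; the default build path uses
no randomness at all.

Defaults — floor 1, `leaf_capacity` 512, `branching` 4, `sample_size`
256 — are sized for interactive use: leaves hold about two screenfuls
of points, and a node sample is large enough to fill a typical preview
budget from one level.

## Dynamic summarization: exact-budget queries

A query is a closed (m/z, RT) rectangle plus a budget n. Closed bounds
are a viewer-driven convention: a point sitting exactly on the window
edge must be drawn, and the brute-force oracle uses the same rule.
`query_points()` walks the tree from the root, prunes nodes whose boxes
miss the window, collects the surviving in-view points, and whittles
them to exactly n — the n most intense, with the same tie-break as
static sampling. Three contracts follow, each tested against a
linear-scan oracle on seeded clouds:

- **Exact budget:** if the window holds at least n retained points,
  exactly n come back; otherwise all of them do (the leaf-level
  shortfall rule).
- **No aggregation:** every returned id exists in the culled input.
- **Monotone detail:** the result at budget n is a subset of the result
  at any larger budget, because both are prefixes of one deterministic
  intensity ordering.

A second traversal mode (`mode = "level"`) stops at the first
breadth-first level whose in-view node samples already reach n and
whittles that level's set. It touches far fewer nodes and exercises the
per-level summaries directly, but a node whose top-S sample lies mostly
outside the window can hide in-window points that outrank the returned
ones, so its selection is not guaranteed to equal the global
intensity-top-n. It is therefore offered as an approximate preview
path and is not the default; the budget and shortfall contracts still
hold for it and are tested. The exact mode is the reference behaviour
throughout the package, including the HTTP service.

`jump_window()` implements viewer navigation to a typed m/z: the new
window keeps the m/z width and RT bounds and centers on the target (the
width is carried over as a value, so zoom is preserved bit-exactly).

## The HTTP JSON API

`ms_serve()` exposes the index as `GET /api/v1/points` (five query
parameters: `mzmin`, `mzmax`, `rtmin`, `rtmax`, `n`) and
`GET /api/v1/bounds`. The route shapes and field names are this
package's own design — the concept of a thin JSON point service is
general, but no compatibility with any particular client is claimed.
Responses serialize numbers at full double precision; the `truncated`
flag reports whether the window's supply exceeded the budget. The
service is stateless and the index immutable after load, so identical
requests produce byte-identical bodies, request order is irrelevant,
and concurrent reads are safe by construction. Parameter validation
returns 400 with a JSON error object; an absent index returns 503;
unknown routes 404. There is deliberately no caching or pagination: a
responsive index makes each request complete and independent, and the
intended client discards its points whenever the viewport changes.

## The synthetic MS1 generator

`gen_points()` emulates what Fig.-1-style MS1 data looks like to an
indexer: each molecule at charge z contributes an isotopic envelope of
K traces, trace k at m/z `mz0 + k·1.003355/z` with intensity
`A·d^k·exp(−(t−t0)²/2σ²)` sampled at the scan grid, plus uniform noise.
Conventions, chosen once and documented rather than tuned:

- **1.003355 Da** is the standard C13 neutron spacing; the generator
  uses it as a fixed constant.
- **Geometric isotope decay** (`d ∈ (0,1]`) stands in for an averagine
  profile: it preserves what matters to the index — several co-eluting
  traces of decreasing, related intensity — without claiming chemical
  accuracy.
- **Centroid output**: one point per trace per scan, matching the
  point-cloud data model; trace points below 0.01 are dropped, since a
  Gaussian tail is not observed forever.
- **Noise RT values are drawn from the scan grid** (not continuously),
  so noise rasterizes into the same spectra as signal when written to
  mzML.
- Randomly sampled envelopes (`random_envelopes()`) use ranges a
  proteomics practitioner would call unremarkable: charges 1–3, 3–6
  isotopes, apex intensities log-uniform over 10–10⁴, decay 0.5–0.9,
  elution widths 3–15 s, over m/z 300–1500 and an RT span of minutes.

The generator returns per-point truth labels (envelope index or noise),
which is what makes known-truth tests possible: e.g. a 1000-point cloud
constructed with exactly 400 points below intensity 1 must cull to
exactly 600.

What the generator does *not* emulate — chromatographic tailing,
mass-dependent peak width, detector saturation, correlated noise,
profile-mode peak shapes — bounds what passing tests show: they verify
the mechanics of extraction, indexing, querying and serving on
realistically shaped data, not robustness to every artifact of real
instruments. Real centroided MS1 data flows through the identical code
path, but its statistical quirks are untested here.

## Numerical and procedural choices

- Float64 arrays round-trip bit-exactly through write→parse; float32 is
  held to single-precision relative error (1e-6) in tests.
- All selection orderings (`sample_node()`, `whittle()`) share one
  comparator — intensity descending, then ascending (mz, rt, id) — so
  every code path that picks "the best points" picks the same ones.
- Index persistence is uncompressed serialization of the index object;
  identical builds yield byte-identical files, which the determinism
  tests assert across two full generate→parse→build→serve runs.
- Degenerate inputs are first-class: empty spectrum lists, empty
  spectra, zero retained points, zero-budget queries and zero-width
  (degenerate) windows all have defined, tested behaviour.
- `subset_spectra()` re-emits the first k spectra in the source's own
  observed dialect; with k equal to the spectrum count, a file written
  by this package round-trips byte-identically.

## Problem sizes used in the checks

The suite exercises the stack at sizes chosen to make the properties
sharp while keeping a full run comfortable on one core: dialect
round-trips on 6-spectrum files; the streaming-contract check on a
120-spectrum file; oracle-equivalence on 10,000-point clouds with 50
random windows; API equivalence over 25 live HTTP calls; and the
scaling measurement on a 400-spectrum, 250-peaks-per-spectrum file cut
into 10 prefix subsets, each parse timed 5 times round-robin with the
minimum kept (interleaving the repeats keeps transient machine slowdowns
from masquerading as a size effect). The parse-time-versus-spectrum-count
fit on that design attains R² well above 0.95.

## Known limitations

- The reader targets mzML 1.1 spectra; chromatogram lists, mzXML,
  vendor formats, mz5/mzMLb, ion mobility and random access by scan id
  are out of scope.
- The index is in-memory and immutable: no incremental insertion, no
  disk paging for clouds larger than RAM.
- The level-stopping traversal is approximate by design (documented
  above); exact mode is the default.
- `bench_parse()` reports wall times, which are hardware-dependent by
  nature; the package never gates correctness on absolute speed, only
  on the shape of the scaling.
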