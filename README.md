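# mzlod

Interactive visualization of an LC-MS map is a rendering-budget problem:
a single MS1 run holds far more centroided points than any viewer can
draw, yet an analyst inspecting isotopic envelopes wants to pan, zoom and
jump across the whole (m/z, RT) plane and always see *real* data points —
never binned or averaged surrogates. `mzlod` is the backend for that
workflow: it streams points out of mzML, indexes them into a hierarchical
level-of-detail structure, and answers every viewport query with an exact
requested number of genuine points, locally or over an HTTP JSON API.

The package has five cooperating parts:

- **Streaming mzML reader** — a single-pass parser (`mzml_stream()`,
  `stream_spectra()`) that decodes each `<spectrum>` element as soon as its
  closing tag arrives, with constant memory in file size. It handles
  32/64-bit floats, zlib-compressed and plain binary arrays, plain and
  `indexedmzML` documents, and second- or minute-declared retention times
  (always normalized to seconds). A whole-document DOM reader
  (`reference_parse()`) exists purely as an independent correctness oracle,
  and an mzML writer (`write_mzml()`, `subset_spectra()`) covers fixture
  generation and prefix subsetting.
- **Level-of-detail index** — `build_lod_tree()` performs *static
  summarization*: the cloud is culled at an intensity floor (default 1 —
  points below it are treated as noise), partitioned into recursive
  bounding boxes (median splits alternating m/z and RT), and every
  internal node keeps references to the S most intense points of its
  subtree, so each tree level is a progressively coarser faithful sketch
  of the data.
- **Viewport queries** — `query_points()` performs *dynamic
  summarization*: prune by bounding box, collect the in-view points, and
  whittle them to exactly `n` — the `n` most intense, ties broken on the
  smaller (mz, rt, id). If the window holds fewer than `n` retained
  points, all of them are returned. `jump_window()` re-centers a viewport
  on a target m/z while preserving zoom and RT position.
- **HTTP JSON service** — `ms_serve()` exposes
  `GET /api/v1/points?mzmin=&mzmax=&rtmin=&rtmax=&n=` and
  `GET /api/v1/bounds`, stateless, over an immutable loaded index.
- **Synthetic MS1 generator** — `gen_points()` / `gen_mzml()` build seeded
  point clouds of isotopic envelopes (isotope k at
  `mz0 + k · 1.003355/z` Th, Gaussian elution in RT, geometric isotope
  decay) plus uniform noise, with per-point truth labels — so the whole
  stack is testable with no instrument data.

## Worked example

```r
library(mzlod)

# 1. simulate a run: 8 envelopes + 2000 noise points, and write it as mzML
cfg <- gen_config(seed = 42,
                  envelopes = random_envelopes(8, seed = 42, rt_range = c(0, 300)),
                  noise_count = 2000, rt_range = c(0, 300))
gen_mzml(cfg, "demo.mzML", mzml_dialect("float64", "zlib", indexed = TRUE))

# 2. stream it back and index it
pts  <- spectra_to_points(stream_spectra("demo.mzML", ms_level = 1))
tree <- build_lod_tree(pts)
tree
#> <mz_lod_tree> 3527 points retained of 5388 (floor 1), depth 2, 21 nodes
#>   m/z [300.486, 1499.21] Th x RT [0, 300] s

# 3. query a viewport for exactly 100 real points
w <- view_window(400, 900, 50, 250)
q <- query_points(tree, w, n = 100)
nrow(q)                       # 100 — the point budget, exactly
#> [1] 100
range(q$intensity)            # the 100 most intense points in view
#> [1]   22.71141 2681.94380

# 4. jump to another m/z, keeping zoom and RT position
jump_window(w, 1200)
#> <view_window> m/z [950, 1450] Th x RT [50, 250] s

# 5. serve it
srv <- ms_serve(tree, port = 4567)
# curl 'http://127.0.0.1:4567/api/v1/points?mzmin=400&mzmax=900&rtmin=50&rtmax=250&n=100'
srv$stop()
```

The retained count (3527 of 5388) is the static cull at intensity 1: the
generator placed most noise below that floor. The query returns exactly
the requested 100 points, each a stored observation inside the window,
selected deterministically by intensity.

The same stack is scriptable from a shell via `inst/cli/mzlod`
(`gen | index | query | serve | subset | bench`), e.g.

```sh
mzlod gen --out f.mzML --seed 42 --envelopes 20 --noise 5000
mzlod index --in f.mzML --out f.idx
mzlod query --index f.idx --mz-min 400 --mz-max 500 --rt-min 0 --rt-max 600 -n 1000
```

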