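---
title: "Parameter sweeps, stain deconvolution and the table-lens algebra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameter sweeps, stain deconvolution and the table-lens algebra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweeplens)
```

## The data model

`sweeplens` replaces trial-and-error parameter tweaking with an exhaustive,
offline Cartesian sweep. Each real-valued input parameter is described by a
`parameter_spec(name, lo, hi, n_samples)`; its interval is sampled with
`n_samples` evenly spaced values including both endpoints. Sampling is
computed as the exact convex combination `lo(1-t) + hi·t`, `t = k/(n-1)`, so
endpoints are reproduced exactly and a symmetric interval with an odd sample
count contains an exact zero — important because for corrective parameters
the midpoint *is* the identity ("no change"), and downstream equality-based
operations (context selection, bin structure) rely on sampled values being
shared constants rather than recomputed floats.

`expand_param_grid()` enumerates all combinations with the *last* parameter
varying fastest. The order is arbitrary but must be canonical: `record_id`
is defined as the row number in this enumeration, which makes sweeps
reproducible across runs and lets two runs of the same configuration be
compared byte-for-byte.

A *data record* is one combination plus, for every input image, the plugin's
declared output measures and output channel images. `run_sweep()` validates
the plugin's output against its declaration on every invocation and aborts on
the first failure (with record id, image index and parameter values named)
rather than skipping: a silently sparse grid would corrupt every downstream
rank/correlation computation. Manifests are persisted as a JSON header plus a
flat `records.csv` (parameters left, measures right, matching the on-screen
column convention); reals are serialised with 17 significant digits so a
write/read cycle is bit-faithful.

## Colour deconvolution with corrective parameters

The case-study plugin models transmitted light with the Beer–Lambert law.
Optical density is `OD = −log10(I/I0)` per channel, with intensities clamped
below at `eps = 1` (8-bit scale) so saturated-black pixels map to a large
finite OD instead of infinity. Absorbances of the two dyes add, so the OD
image is a linear mixture of per-stain density fields along unit stain
vectors (defaults: the Ruifrok–Johnson H&E calibration,
`he_stain_vectors()`).

The corrective parameters `p1` (hematoxylin) and `p2` (eosin) are defined
here as **in-plane rotation angles** (radians): each stain vector is rotated
within the plane spanned by the two base vectors, then the 3×3 stain matrix
is completed with the normalised cross product of the rotated vectors and
inverted. This parameterisation was chosen over per-component additive deltas
because it is the minimal one-degree-of-freedom deformation that (a) keeps
the vector on the unit sphere, (b) stays inside the two-stain mixing plane,
and (c) has an exact identity at 0 — matching the convention that the 6th of
11 samples on a symmetric interval "represents no change". The sweep default
`[-0.5, 0.5]` rad spans clearly-wrong to clearly-wrong through the identity.

Quality is measured by the statistics of *negative* coefficients, which are
physically impossible and appear exactly when the deconvolution matrix
mismatches the image's true mixture: per stain, the percentage of negative
pixels, and the mean and standard deviation of the negative values. Three
conventions the statistics rely on:

* computed on the **raw** coefficients — negative values are the object of
  study, so the display-only clamp (coefficients ≥ 0 in the reconstructed
  single-dye images) never feeds the measures;
* **population** standard deviation, since the negative pixels are the whole
  population of interest, not a sample;
* no negatives at all ⇒ percentage = mean = sd = 0, keeping the measure
  columns well-defined on perfect records instead of propagating NaN.

A useful geometric fact, verified by the tests: rotating the *eosin* vector
drives *hematoxylin* coefficients negative (eosin absorbance gets
misattributed), and vice versa. The inverse relationship between `p2` and
`m1` is therefore expected structure, not an artefact.

## What the synthetic data emulates — and what it does not

`generate_structured_densities()` builds per-stain density fields from
Gaussian bumps: stain 1 gets small, strong bumps (nuclei-like; default 24
bumps, peak 0.8 OD, radius 5 px) and stain 2 broader, weaker ones
(cytoplasm-like; 10 bumps, 0.4 OD, 14 px), plus a uniform baseline of
0.02 OD per stain representing the slight absorption of a blank slide and
mounting medium. The baseline also keeps densities strictly positive, so the
sign of a recovered coefficient is meaningful at floating-point precision:
with exact zeros, roundoff of order 1e-16 would make the sign of a
ground-truth-zero coefficient arbitrary. Defaults target 256×256 images,
where total densities stay in the realistic ≤ ~2 OD range; a 1000×1000 size
is available for full-scale runs.

`generate_two_stain_image()` applies the forward Beer–Lambert map and
returns the ground truth alongside the image, so tests can assert an exact
round trip: matched deconvolution (`p1 = p2 = 0`) recovers densities to
< 1e-6 in the float pipeline, and to < 0.02 OD after 8-bit quantisation for
densities up to ~1.5 OD. `generate_nuclei_image()` places non-overlapping
bright disks by rejection sampling (bounded at 10,000 attempts) with known
count and centres.

What the generators do **not** emulate: real tissue texture, chromatic
aberration and scanner colour profiles, stain co-localisation, touching
nuclei, uneven illumination. Passing tests therefore demonstrate that the
machinery is correct — sampling, mixing, inversion, statistics, sorting,
rendering — not that any particular parameter setting is optimal for real
slides.

## The table-lens algebra

All interaction state lives in a `result_table` (ordering, visibility, sort
keys, selection) and every operation is a pure function, so scripted
pipelines are deterministic and composable.

* **`multi_sort`** appends a key and re-sorts lexicographically ascending in
  key-application order, ties broken by `record_id`. Earlier sorts are
  maintained: rows equal on earlier keys form contiguous bins reordered only
  internally — the nested step pattern that exposes multi-way parameter
  effects. Ascending order and the record-id tie-break are conventions chosen
  for determinism.
* **`smart_sort`** scores each parameter by the mean over measure columns of
  |Pearson r| on the visible records, with r defined as 0 when either column
  is constant (degenerate filters would otherwise yield NaN). The
  highest-scoring parameter becomes the sole sort key, ties broken by
  leftmost column. A variance-weighted aggregate (`weighting = "variance"`,
  each |r| weighted by the measure's variance) is provided as the alternative
  reading of "aggregate correlation"; the unweighted mean is the default
  because it is scale-free across measures with different units.
* **`context_selection`** returns the maximal contiguous run (in the current
  ordering, over visible rows) sharing the cursor column's value, using exact
  equality — safe because grid values are shared sampled constants.
* **`filter_interval`** hides records outside a closed interval and composes
  with previous filters by intersection (resettable with `reset_filters`);
  the selection is pruned so it always remains a subset of the visible set.
* **`domain_coverage`** reports, per column, which parts of the column's
  domain a row set occupies, as maximal unions of display bins (default 64
  bins; point values widen to one bin so they remain visible).

## Rendering

Both renderers compose pixel arrays directly — no graphics device, no fonts —
so identical state produces byte-identical PNGs on any platform. The tabular
view draws one row per visible record (parameters left, measures right),
encoding each value linearly on the column's min–max domain; rows taller than
4 px become bars, otherwise single-pixel line marks (the 4-px threshold is
the point below which a bar's outline consumes the row). Constant columns
render at mid-scale rather than erroring. Filter strips under each column
darken the currently visible part of the domain.

The image grid blends each output image onto its input with linear alpha
compositing `α·out + (1−α)·in`; the region of interest is cropped from input
and output alike *before* blending, and nearest-neighbour magnification is
applied last so blending always happens at native resolution. At α ∈ {0, 1}
the 8-bit output reproduces the source PNGs bit-for-bit (quantisation rounds
half-up, and stored 8-bit values are exact multiples of 1/255).
`render_single_record()` shares the cell-composition path with the grid, so
its strip equals the corresponding grid row exactly. PNG carries all
bit-exact contracts; SVG (rect elements for the table, embedded raster for
grids) and self-contained HTML are structural conveniences.

## Nuclei fixture

The five-parameter detector (Gaussian smooth → threshold → fill enclosed
holes ≤ `hole_fill` px equivalent diameter → 8-connected components → keep
components with equivalent diameter in `[min_diameter, max_diameter]`) is a
concrete stand-in exposing the two parameters that matter analytically
(minimal nucleus diameter, lower threshold) plus three conventional ones.
Components use 8-connectivity and holes 4-connectivity (the standard
complementary pair); equivalent diameter is that of the circle with the
component's area. On noise-free disk images the object count is monotone
non-increasing in both `min_diameter` and `lower_threshold`, which the tests
assert alongside exact recovery on 50 random layouts.

## Problem sizes and numerical choices

The test suite and the acceptance script use 256×256 images for the full
11×11 two-image deconvolution sweep, 64–160 px images elsewhere, 100 random
tables of up to 200 rows for the sorting/correlation oracles, and 50 nuclei
layouts — sizes at which every oracle can be brute-forced while the suite
stays fast. Other fixed choices: intensity clamp `eps = 1` before the OD
log; stain-matrix conditioning guard at `rcond < 1e-8`; manifest reals at 17
significant digits; Cartesian enumeration with the last parameter fastest;
sweep image filenames `images/rec<id>_in<i>_ch<k>.png`.

## Limitations

* No stain-vector *estimation*: the package evaluates corrections to a given
  matrix, it does not learn vectors from images.
* No adaptive resampling of the parameter space; the grid is fixed upfront.
* The nuclei detector does not declump touching nuclei (no watershed).
* Renders are static; there is no windowed application or event loop.
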