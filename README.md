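# sweeplens

Systematic exploration of algorithm parameter spaces for biomedical image
analysis. Instead of tweaking parameters one trial at a time, `sweeplens`
samples every real-valued input parameter on an interval, runs the algorithm
on every combination and every input image, and persists the results as
*data records* — one parameter combination together with its output measures
and output images. The records are then explored with a deterministic
table-lens algebra (nested multi-column sorting, correlation-driven smart
sorting, context-sensitive run selection, interval filtering, domain-coverage
strips) and rendered as a static tabular visualisation and blended
image-browser grids. Every interactive gesture of a GUI-style workflow has a
scripted, reproducible equivalent here.

The package is aimed at image-analysis practitioners who need to choose
operating points for pipeline parameters — and to show *why* a chosen point
is good — rather than at any single segmentation or deconvolution method.

## The case-study backend: colour deconvolution of H&E histology

Stained tissue transmits light according to the Beer–Lambert law. With
per-channel background intensity `I0_c` and per-stain densities `D_s`,

    I_c = I0_c · 10^(−Σ_s D_s · v_{s,c}),      OD_c = −log10(I_c / I0_c),

where `v_s` is the unit optical-density vector of stain `s` (hematoxylin
stains nuclei, eosin stains cytoplasm/connective tissue; reference vectors
after Ruifrok & Johnson). Absorbances add, so in OD space the image is a
linear mixture and per-pixel stain contributions are recovered by inverting
the 3×3 stain matrix (third row: normalised cross product of the two stain
vectors).

Two corrective parameters `p1` and `p2` rotate the hematoxylin and eosin
vectors within the plane the base vectors span; `p1 = p2 = 0` is "no change",
which is exactly the 6th sample when each is swept 11 times on a symmetric
interval. A mismatched matrix produces physically impossible *negative*
coefficients, so deconvolution quality is measured per stain by

* `m1`, `m4` — percentage of negative coefficients (stain 1, stain 2),
* `m2`, `m5` — mean of the negative coefficients,
* `m3`, `m6` — population standard deviation of the negative coefficients.

Sweeping `p1 × p2` (11 × 11 = 121 records) over two input images yields 12
measures and 4 output images per record. A second backend, a five-parameter
thresholding nuclei detector (`nuclei_plugin()`), reproduces the
object-counting analysis pattern (5 parameters × 3 samples = 243 records).

Synthetic generators provide ground truth for everything: two-stain
histology-like images by forward Beer–Lambert mixing of known density
fields, and nuclei photomicrographs with known disk counts.

## Worked example

```r
library(sweeplens)

specs <- list(parameter_spec("p1", -0.5, 0.5, 11),
              parameter_spec("p2", -0.5, 0.5, 11))
imgs <- lapply(1:2, function(i)
  generate_two_stain_image(generate_structured_densities(
    shape = c(256, 256), seed = i))$image)
man <- run_sweep(specs, imgs, deconvolution_plugin(), seed = 1,
                 out_dir = "he_sweep")
man
#> <sweep_manifest> plugin 'stain_deconvolution': 121 records, 2 parameters,
#>   12 measures, 2 input images

ss <- smart_sort(result_table(man))
ss$parameter                 # parameter most correlated with the measures
#> [1] "p1"
round(ss$scores, 3)          # mean |Pearson r| against all 12 measures
#>    p1    p2
#> 0.354 0.332

tab <- filter_interval(ss$table, "m1_i1", 0, 5)   # keep low-negativity runs
sum(tab$visible)
#> [1] 66
cursor <- which(tab$records$p1 == 0 & tab$records$p2 == 0)
rows <- context_selection(tab, cursor, "p1")      # the whole p1 = 0 bin
length(rows)
#> [1] 6
tab <- select_rows(tab, rows)
tab$records[tab$selection[1:4], c("record_id", "p1", "p2", "m1_i1", "m4_i1")]
#>    record_id p1  p2 m1_i1 m4_i1
#> 61        61  0 0.0     0     0
#> 62        62  0 0.1     0     0
#> 63        63  0 0.2     0     0
#> 64        64  0 0.3     0     0

render_table(tab, render_spec(row_height = 6), "table.png")
render_image_grid(man, tab$selection, render_spec(blend_alpha = 0.6),
                  "grid.png", table = tab)
```

The smart sort ranks each parameter by the mean absolute Pearson correlation
with all measure columns over the visible records; the filter hides records
whose stain-1 negative-coefficient percentage on image 1 exceeds 5%; the
context selection grabs the maximal contiguous run of rows sharing the
cursor's `p1` value (here: the six surviving no-change-`p1` records), and the
grid renders their four output images per record blended onto the inputs.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "sweeplens.R", package = "sweeplens")` — see its header
for the `sweep run` / `table` / `render` / `demo` subcommands.

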