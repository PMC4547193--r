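# pixel counts by colour are the structural handle on the fontless renders
count_colour <- function(img, col, tol = 0.5 / 255 + 1e-6) {
  m <- abs(img[, , 1] - col[1]) < tol & abs(img[, , 2] - col[2]) < tol &
    abs(img[, , 3] - col[3]) < tol
  sum(m)
}

simple_table <- function() {
  df <- data.frame(record_id = 1:5, p1 = c(0, 0.25, 0.5, 0.75, 1),
                   m1 = c(1, 3, 5, 2, 4))
  result_table(df, "p1", "m1")
}

test_that("table render dimensions follow the layout arithmetic", {
  d <- withr::local_tempdir()
  tab <- simple_table()
  for (rh in c(3L, 8L)) {
    path <- file.path(d, paste0("t", rh, ".png"))
    render_table(tab, render_spec(row_height = rh, col_width = 40, gap = 2),
                 path)
    img <- png::readPNG(path)
    expect_identical(dim(img)[1], 10L + 5L * rh + 6L)   # header + rows + strip
    expect_identical(dim(img)[2], 5L + 2L * 40L + 2L)   # margin + 2 columns
  }
})

test_that("row height switches between bar and line encoding at 4 px", {
  d <- withr::local_tempdir()
  tab <- simple_table()
  bar_col <- c(0.27, 0.45, 0.70)
  p5 <- file.path(d, "bar.png"); p3 <- file.path(d, "line.png")
  render_table(tab, render_spec(row_height = 5), p5)
  render_table(tab, render_spec(row_height = 3), p3)
  bar_px <- count_colour(png::readPNG(p5), bar_col)
  line_px <- count_colour(png::readPNG(p3), bar_col)
  # bars fill runs of pixels; line marks are a single pixel column per row
  expect_identical(line_px, 5L * 3L)
  expect_gt(bar_px, line_px)
  # at exactly the threshold (4 px) a line chart is still used
  p4 <- file.path(d, "at4.png")
  render_table(tab, render_spec(row_height = 4), p4)
  expect_identical(count_colour(png::readPNG(p4), bar_col), 5L * 4L)
})

test_that("bars map values linearly and constant columns sit mid-scale", {
  d <- withr::local_tempdir()
  df <- data.frame(record_id = 1:2, p1 = c(0, 1), m1 = c(7, 7))
  tab <- result_table(df, "p1", "m1")
  path <- file.path(d, "c.png")
  render_table(tab, render_spec(row_height = 8, col_width = 40, gap = 2),
               path)
  img <- png::readPNG(path)
  bar_col <- c(0.27, 0.45, 0.70); mes_col <- c(0.55, 0.55, 0.55)
  # p1 rows: min value -> minimal bar (1 px), max -> full width (40 px)
  row1 <- img[10 + 4, , ]; row2 <- img[10 + 8 + 4, , ]
  p1_len1 <- sum(abs(row1[, 1] - bar_col[1]) < 1e-3)
  p1_len2 <- sum(abs(row2[, 1] - bar_col[1]) < 1e-3)
  expect_identical(p1_len1, 1L)
  expect_identical(p1_len2, 40L)
  # constant measure: both rows at mid-scale (20 px)
  m_len1 <- sum(abs(row1[, 1] - mes_col[1]) < 1e-3 &
                  abs(row1[, 3] - mes_col[3]) < 1e-3)
  expect_identical(m_len1, 20L)
})

test_that("sorted order, hidden rows and selections shape the render", {
  d <- withr::local_tempdir()
  tab <- simple_table()
  p_all <- file.path(d, "all.png")
  render_table(tab, render_spec(row_height = 6), p_all)
  filt <- filter_interval(tab, "m1", 3, 5)
  p_f <- file.path(d, "filtered.png")
  render_table(filt, render_spec(row_height = 6), p_f)
  expect_identical(dim(png::readPNG(p_f))[1] + 2L * 6L,
                   dim(png::readPNG(p_all))[1])
  sel <- select_rows(tab, 2L)
  p_s <- file.path(d, "sel.png")
  render_table(sel, render_spec(row_height = 6), p_s)
  expect_gt(count_colour(png::readPNG(p_s), c(0.85, 0.15, 0.15)), 0L)
  empty <- filter_interval(tab, "m1", 99, 100)
  expect_error(render_table(empty, render_spec(), file.path(d, "e.png")),
               "no visible")
})

test_that("rendering is deterministic", {
  d <- withr::local_tempdir()
  tab <- simple_table()
  p1 <- file.path(d, "a.png"); p2 <- file.path(d, "b.png")
  render_table(tab, render_spec(row_height = 7), p1)
  render_table(tab, render_spec(row_height = 7), p2)
  expect_identical(readBin(p1, "raw", 1e6), readBin(p2, "raw", 1e6))
})

test_that("grid blend endpoints reproduce the source images bit-for-bit", {
  d <- withr::local_tempdir()
  man <- make_deconv_sweep(d, n_samples = 2L, shape = c(24, 24))
  g1 <- file.path(d, "a1.png")
  render_image_grid(man, 1L, render_spec(blend_alpha = 1, gap = 2), g1)
  img <- png::readPNG(g1)
  out1 <- png::readPNG(file.path(d, man$image_refs$path[1]))
  # record row 1 starts below the 24-px top strip + 2-px gap
  cell <- img[27:50, 1:24, ]
  expect_identical(cell, out1)
  g0 <- file.path(d, "a0.png")
  render_image_grid(man, 1L, render_spec(blend_alpha = 0, gap = 2), g0)
  img0 <- png::readPNG(g0)
  in1 <- png::readPNG(file.path(d, man$input_images[1]))
  expect_identical(img0[27:50, 1:24, ], in1)
})

test_that("mid blends average the sources pixel-wise", {
  d <- withr::local_tempdir()
  # constant input 100 and constant output 200 -> blended 150
  inp <- matrix(100, 8, 8)
  const_plugin <- sweep_plugin("const", "m", 1L, function(image, params)
    list(measures = list(m = 0), channels = list(array(200, c(8, 8, 3)))))
  man <- run_sweep(list(parameter_spec("a", 0, 1, 1)), list(inp),
                   const_plugin, seed = 1, out_dir = d)
  p <- file.path(d, "blend.png")
  render_single_record(man, 1L, render_spec(blend_alpha = 0.5), p)
  img <- png::readPNG(p) * 255
  expect_true(all(img == 150))
})

test_that("grid layout is selection rows x (images x channels) columns", {
  d <- withr::local_tempdir()
  man <- make_deconv_sweep(d, n_samples = 3L, shape = c(20, 20))
  p <- file.path(d, "grid.png")
  sel <- c(4L, 1L, 9L, 2L, 7L)
  render_image_grid(man, sel, render_spec(gap = 2), p)
  img <- png::readPNG(p)
  # rows: top strip + 5 selected records; columns: 4 cells + coverage panel
  expect_identical(dim(img)[1], 6L * 20L + 5L * 2L)
  expect_identical(dim(img)[2], 4L * 20L + 3L * 2L + 2L + 64L)
  # grid row order equals selection order: row r equals that record's strip
  single <- file.path(d, "one.png")
  render_single_record(man, 9L, render_spec(gap = 2), single)
  one <- png::readPNG(single)
  y0 <- 3L * (20L + 2L) + 1L  # third selected record
  expect_identical(img[y0:(y0 + 19L), 1:(4L * 20L + 3L * 2L), ], one)
})

test_that("region of interest and magnification reshape the cells", {
  d <- withr::local_tempdir()
  man <- make_deconv_sweep(d, n_samples = 2L, shape = c(30, 30))
  p <- file.path(d, "roi.png")
  render_single_record(man, 1L,
                       render_spec(roi = c(5, 3, 10, 8), magnification = 2,
                                   gap = 2), p)
  img <- png::readPNG(p)
  expect_identical(dim(img)[1], 16L)            # 8 * 2
  expect_identical(dim(img)[2], 4L * 20L + 3L * 2L)
  expect_error(render_single_record(man, 1L,
                                    render_spec(roi = c(25, 25, 10, 10)),
                                    file.path(d, "bad.png")),
               "bounds")
  expect_error(render_single_record(man, 99L, render_spec(),
                                    file.path(d, "bad2.png")), "invalid")
  expect_error(render_image_grid(man, integer(), render_spec(),
                                 file.path(d, "bad3.png")), "non-empty")
})

test_that("svg and html formats carry the same structure", {
  d <- withr::local_tempdir()
  tab <- simple_table()
  svg <- file.path(d, "t.svg")
  render_table(tab, render_spec(row_height = 6, format = "svg"), svg)
  txt <- readLines(svg)
  expect_match(txt[1], "<svg")
  expect_gt(sum(grepl("<rect", txt)), 10L)
  html <- file.path(d, "t.html")
  render_table(tab, render_spec(row_height = 6, format = "html"), html)
  expect_match(paste(readLines(html), collapse = ""), "data:image/png;base64")
  man <- make_deconv_sweep(d, n_samples = 2L, shape = c(16, 16))
  gsvg <- file.path(d, "g.svg")
  render_image_grid(man, 1L, render_spec(format = "svg"), gsvg)
  expect_match(paste(readLines(gsvg), collapse = ""), "<image")
})
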