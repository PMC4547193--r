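# Static renderers for the two coordinated views: the tabular visualisation
# (one row per record; parameter columns left, measure columns right; bar or
# line encoding depending on row height) and the image-browser grid (input
# images atop columns of blended output images, with optional region of
# interest, magnification, and domain-coverage strips). Rendering composes
# pixel arrays directly — no graphics device, no fonts — so identical state
# yields byte-identical PNG output.

#' Rendering parameters
#'
#' @param row_height Table row height, px (>= 1). Rows taller than
#'   `bar_line_threshold` px are drawn as bars, otherwise as line marks.
#' @param bar_line_threshold Bar/line switch, px (default 4: bar chart iff
#'   the vertical space per row is more than four pixels).
#' @param blend_alpha Output/input blend weight in `[0, 1]`:
#'   `alpha * output + (1 - alpha) * input`.
#' @param roi Optional region of interest `c(x, y, w, h)` in input-image
#'   pixels (1-based), applied to inputs and outputs alike before blending.
#' @param magnification Scale factor (> 0), applied last (nearest neighbour).
#' @param format `"png"` (bit-exact contracts), `"svg"` or `"html"`
#'   (structural only).
#' @param col_width Table column width, px.
#' @param gap Gap between columns/cells, px.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(row_height = 8, bar_line_threshold = 4,
                        blend_alpha = 0.5, roi = NULL, magnification = 1,
                        format = c("png", "svg", "html"), col_width = 40,
                        gap = 2) {
  format <- match.arg(format)
  if (row_height < 1) stop("'row_height' must be >= 1")
  if (blend_alpha < 0 || blend_alpha > 1)
    stop("'blend_alpha' must be in [0, 1]")
  if (magnification <= 0) stop("'magnification' must be > 0")
  if (!is.null(roi) && (length(roi) != 4L || any(roi[3:4] < 1)))
    stop("'roi' must be c(x, y, w, h) with positive size")
  structure(list(row_height = as.integer(row_height),
                 bar_line_threshold = bar_line_threshold,
                 blend_alpha = blend_alpha, roi = roi,
                 magnification = magnification, format = format,
                 col_width = as.integer(col_width), gap = as.integer(gap)),
            class = "render_spec")
}

# -- painter: a white canvas plus a log of drawn rectangles (for SVG) --------

new_painter <- function(h, w) {
  env <- new.env(parent = emptyenv())
  env$canvas <- array(1, dim = c(h, w, 3L))
  env$rects <- list()
  env$h <- h; env$w <- w
  env
}

draw_rect <- function(p, x, y, w, h, col) {
  x0 <- max(1L, as.integer(x)); y0 <- max(1L, as.integer(y))
  x1 <- min(p$w, as.integer(x + w - 1L)); y1 <- min(p$h, as.integer(y + h - 1L))
  if (x1 < x0 || y1 < y0) return(invisible(NULL))
  for (c in 1:3) p$canvas[y0:y1, x0:x1, c] <- col[c]
  p$rects[[length(p$rects) + 1L]] <-
    list(x = x0, y = y0, w = x1 - x0 + 1L, h = y1 - y0 + 1L, col = col)
  invisible(NULL)
}

painter_svg <- function(p) {
  hex <- function(col) grDevices::rgb(col[1], col[2], col[3])
  rects <- vapply(p$rects, function(r) sprintf(
    '<rect x="%d" y="%d" width="%d" height="%d" fill="%s"/>',
    r$x - 1L, r$y - 1L, r$w, r$h, hex(r$col)), character(1))
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            p$w, p$h),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#ffffff"/>',
            p$w, p$h),
    rects, "</svg>")
}

write_canvas <- function(canvas, path, format, svg_lines = NULL,
                         title = "sweeplens") {
  if (format == "png") {
    png::writePNG(pmin(pmax(canvas, 0), 1), path)
  } else if (format == "svg") {
    if (is.null(svg_lines)) svg_lines <- raster_svg(canvas)
    writeLines(svg_lines, path, useBytes = TRUE)
  } else {
    tmp <- tempfile(fileext = ".png")
    png::writePNG(pmin(pmax(canvas, 0), 1), tmp)
    b64 <- jsonlite::base64_enc(readBin(tmp, "raw", file.size(tmp)))
    unlink(tmp)
    writeLines(c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
                 sprintf("<title>%s</title></head><body>", title),
                 sprintf("<img alt='%s' src='data:image/png;base64,%s'/>",
                         title, gsub("\n", "", b64)),
                 "</body></html>"), path, useBytes = TRUE)
  }
  invisible(path)
}

# SVG wrapper embedding the canvas as a raster (used for image grids)
raster_svg <- function(canvas) {
  tmp <- tempfile(fileext = ".png")
  png::writePNG(pmin(pmax(canvas, 0), 1), tmp)
  b64 <- gsub("\n", "", jsonlite::base64_enc(readBin(tmp, "raw",
                                                     file.size(tmp))))
  unlink(tmp)
  c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                   'xmlns:xlink="http://www.w3.org/1999/xlink" ',
                   'width="%d" height="%d">'),
            dim(canvas)[2], dim(canvas)[1]),
    sprintf(paste0('<image width="%d" height="%d" ',
                   'xlink:href="data:image/png;base64,%s"/>'),
            dim(canvas)[2], dim(canvas)[1], b64),
    "</svg>")
}

# -- tabular visualisation ---------------------------------------------------

TABLE_HEADER_H <- 10L
TABLE_FILTER_H <- 6L
TABLE_SEL_MARGIN <- 5L

col_param_bar <- c(0.27, 0.45, 0.70)
col_measure_bar <- c(0.55, 0.55, 0.55)
col_param_head <- c(0.84, 0.88, 0.95)
col_measure_head <- c(0.93, 0.90, 0.85)
col_selected <- c(0.85, 0.15, 0.15)
col_strip_on <- c(0.25, 0.25, 0.25)
col_strip_off <- c(0.90, 0.90, 0.90)

# value -> [0,1] within the column's domain over all records; constant
# columns map to mid-scale
column_fraction <- function(values, domain) {
  if (domain[2L] == domain[1L]) return(rep(0.5, length(values)))
  (values - domain[1L]) / (domain[2L] - domain[1L])
}

#' Render the tabular visualisation
#'
#' One row per visible record in the current ordering; parameter columns are
#' drawn left of measure columns. Each cell encodes the record's value
#' linearly on the column's domain: as a left-anchored bar when
#' `row_height > bar_line_threshold` px, otherwise as a line mark. Selected
#' rows are flagged in the left margin; a strip beneath each column shows
#' which parts of its domain are currently visible (the filter strip).
#'
#' @param table A [result_table()] with at least one visible record.
#' @param spec A [render_spec()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
render_table <- function(table, spec = render_spec(), path) {
  stopifnot(inherits(table, "result_table"), inherits(spec, "render_spec"))
  disp <- table$ordering[table$visible[table$ordering]]
  if (length(disp) == 0L) stop("no visible records to render")
  cols <- table_columns(table)
  nc <- length(cols)
  rh <- spec$row_height; cw <- spec$col_width; gap <- spec$gap
  h <- TABLE_HEADER_H + length(disp) * rh + TABLE_FILTER_H
  w <- TABLE_SEL_MARGIN + nc * cw + (nc - 1L) * gap
  p <- new_painter(h, w)
  bar_mode <- rh > spec$bar_line_threshold
  coverage <- domain_coverage(table, which(table$visible))
  for (j in seq_len(nc)) {
    cn <- cols[j]
    x0 <- TABLE_SEL_MARGIN + (j - 1L) * (cw + gap) + 1L
    head_col <- if (cn %in% table$param_columns) col_param_head
                else col_measure_head
    draw_rect(p, x0, 1L, cw, TABLE_HEADER_H - 2L, head_col)
    v <- table$records[[cn]]
    domain <- range(v)
    frac <- column_fraction(v[disp], domain)
    bar_col <- if (cn %in% table$param_columns) col_param_bar
               else col_measure_bar
    for (r in seq_along(disp)) {
      y0 <- TABLE_HEADER_H + (r - 1L) * rh + 1L
      if (bar_mode) {
        len <- max(1L, round(frac[r] * cw))
        draw_rect(p, x0, y0, len, max(1L, rh - 1L), bar_col)
      } else {
        x <- x0 + round(frac[r] * (cw - 1L))
        draw_rect(p, x, y0, 1L, rh, bar_col)
      }
    }
    # filter strip: dark where the visible records cover the domain
    ys <- TABLE_HEADER_H + length(disp) * rh + 2L
    draw_rect(p, x0, ys, cw, TABLE_FILTER_H - 2L, col_strip_off)
    for (k in seq_len(nrow(coverage[[cn]]))) {
      iv <- coverage[[cn]][k, ]
      fl <- column_fraction(c(iv$lo, iv$hi), domain)
      xs <- x0 + floor(fl[1L] * (cw - 1L))
      xe <- x0 + ceiling(fl[2L] * (cw - 1L))
      draw_rect(p, xs, ys, xe - xs + 1L, TABLE_FILTER_H - 2L, col_strip_on)
    }
  }
  sel_pos <- match(intersect(disp, table$selection), disp)
  for (r in sel_pos) {
    y0 <- TABLE_HEADER_H + (r - 1L) * rh + 1L
    draw_rect(p, 1L, y0, TABLE_SEL_MARGIN - 1L, max(1L, rh - 1L),
              col_selected)
  }
  write_canvas(p$canvas, path, spec$format, svg_lines = painter_svg(p),
               title = "sweeplens table")
}

# -- image grid --------------------------------------------------------------

crop_roi <- function(img, roi) {
  if (is.null(roi)) return(img)
  x <- roi[1L]; y <- roi[2L]; w <- roi[3L]; h <- roi[4L]
  if (y + h - 1L > dim(img)[1L] || x + w - 1L > dim(img)[2L] ||
      x < 1L || y < 1L)
    stop("ROI exceeds image bounds")
  img[y:(y + h - 1L), x:(x + w - 1L), , drop = FALSE]
}

scale_nearest <- function(img, mag) {
  if (mag == 1) return(img)
  d <- dim(img)
  nh <- max(1L, round(d[1L] * mag)); nw <- max(1L, round(d[2L] * mag))
  ri <- pmin(d[1L], pmax(1L, floor(((seq_len(nh)) - 0.5) / mag) + 1L))
  ci <- pmin(d[2L], pmax(1L, floor(((seq_len(nw)) - 0.5) / mag) + 1L))
  img[ri, ci, , drop = FALSE]
}

# read an image referenced by a manifest, as [0,1] RGB
read_manifest_image <- function(manifest, rel_path) {
  dir <- attr(manifest, "dir")
  if (is.null(dir)) stop("manifest has no directory; read it with ",
                         "read_manifest() or set attr(, 'dir')")
  path <- file.path(dir, rel_path)
  if (!file.exists(path)) stop("missing image file: ", path)
  to_rgb(read_image(path)) / 255
}

# blended cell for (record, input, channel); inputs_01 are preloaded [0,1]
# RGB inputs; returns [0,1] RGB after roi+blend+magnification
record_cell <- function(manifest, record_id, input, channel, inputs_01,
                        spec) {
  refs <- manifest$image_refs
  sel <- refs$record_id == record_id & refs$input == input &
    refs$channel == channel
  if (!any(sel)) stop("no output image for record ", record_id, ", input ",
                      input, ", channel ", channel)
  out <- read_manifest_image(manifest, refs$path[which(sel)[1L]])
  inp <- inputs_01[[input]]
  if (!identical(dim(out), dim(inp)))
    stop("output image shape differs from its input image")
  a <- spec$blend_alpha
  cell <- a * crop_roi(out, spec$roi) + (1 - a) * crop_roi(inp, spec$roi)
  scale_nearest(cell, spec$magnification)
}

grid_geometry <- function(manifest, spec) {
  n_inputs <- length(manifest$input_images)
  n_channels <- if (nrow(manifest$image_refs)) max(manifest$image_refs$channel)
                else 1L
  inputs_01 <- lapply(manifest$input_images, read_manifest_image,
                      manifest = manifest)
  cell_dim <- dim(scale_nearest(crop_roi(inputs_01[[1L]], spec$roi),
                                spec$magnification))
  list(n_inputs = n_inputs, n_channels = n_channels, inputs_01 = inputs_01,
       cell_h = cell_dim[1L], cell_w = cell_dim[2L],
       n_cols = n_inputs * n_channels)
}

place_cell <- function(canvas, cell, x0, y0) {
  canvas[y0:(y0 + dim(cell)[1L] - 1L), x0:(x0 + dim(cell)[2L] - 1L), ] <- cell
  canvas
}

GRID_PANEL_W <- 64L
GRID_STRIP_H <- 4L

#' Render the image-browser grid
#'
#' A top strip shows the input images; below it, one row per selected record
#' (top-to-bottom in selection order). Column `(i, k)` holds the `k`-th
#' output image produced on the `i`-th input image, alpha-blended onto that
#' input (`alpha * output + (1 - alpha) * input`). The region of interest is
#' cropped from input and output alike before blending; magnification is
#' applied last. A side panel draws the selection's domain-coverage strips
#' (dark where the selected records' parameter/measure values lie).
#'
#' @param manifest A [sweep_manifest()] with a directory attribute (e.g. from
#'   [read_manifest()] or [run_sweep()]).
#' @param selection Ordered record row indices (non-empty).
#' @param spec A [render_spec()].
#' @param path Output file.
#' @param table Optional [result_table()] carrying the interaction state for
#'   the coverage strips; defaults to a fresh table over the manifest.
#' @return `path`, invisibly.
#' @export
render_image_grid <- function(manifest, selection, spec = render_spec(),
                              path, table = NULL) {
  stopifnot(inherits(manifest, "sweep_manifest"),
            inherits(spec, "render_spec"))
  selection <- as.integer(selection)
  if (length(selection) == 0L) stop("selection must be non-empty")
  if (any(is.na(selection) | selection < 1L |
            selection > nrow(manifest$records)))
    stop("selection contains invalid record indices")
  g <- grid_geometry(manifest, spec)
  gap <- spec$gap
  n_rows <- length(selection)
  w_cells <- g$n_cols * g$cell_w + (g$n_cols - 1L) * gap
  h <- (n_rows + 1L) * (g$cell_h + gap) - gap
  w <- w_cells + gap + GRID_PANEL_W
  canvas <- array(1, dim = c(h, w, 3L))
  for (j in seq_len(g$n_cols)) {
    i <- (j - 1L) %/% g$n_channels + 1L
    x0 <- (j - 1L) * (g$cell_w + gap) + 1L
    top <- scale_nearest(crop_roi(g$inputs_01[[i]], spec$roi),
                         spec$magnification)
    canvas <- place_cell(canvas, top, x0, 1L)
  }
  rec_ids <- manifest$records$record_id
  for (r in seq_len(n_rows)) {
    rid <- rec_ids[selection[r]]
    y0 <- r * (g$cell_h + gap) + 1L
    for (j in seq_len(g$n_cols)) {
      i <- (j - 1L) %/% g$n_channels + 1L
      k <- (j - 1L) %% g$n_channels + 1L
      cell <- record_cell(manifest, rid, i, k, g$inputs_01, spec)
      canvas <- place_cell(canvas, cell,
                           (j - 1L) * (g$cell_w + gap) + 1L, y0)
    }
  }
  # coverage panel
  tab <- table %||% result_table(manifest)
  cov <- domain_coverage(tab, selection)
  x0 <- w_cells + gap + 1L
  y <- 2L
  for (cn in names(cov)) {
    if (y + GRID_STRIP_H > h) break
    canvas[y:(y + GRID_STRIP_H - 1L), x0:(x0 + GRID_PANEL_W - 3L), ] <- 0.9
    v <- tab$records[[cn]]
    domain <- range(v)
    strips <- cov[[cn]]
    for (k in seq_len(nrow(strips))) {
      fl <- column_fraction(c(strips$lo[k], strips$hi[k]), domain)
      xs <- x0 + floor(fl[1L] * (GRID_PANEL_W - 3L))
      xe <- x0 + ceiling(fl[2L] * (GRID_PANEL_W - 3L))
      canvas[y:(y + GRID_STRIP_H - 1L), xs:min(xe, w), ] <- 0.25
    }
    y <- y + GRID_STRIP_H + 2L
  }
  write_canvas(canvas, path, spec$format, title = "sweeplens image grid")
}

#' Render the image row of a single record
#'
#' The static analogue of a hover preview: a one-row strip of the record's
#' blended output cells, pixel-identical to the corresponding row of
#' [render_image_grid()] (same ROI, blend and magnification path).
#'
#' @param manifest A [sweep_manifest()] with a directory attribute.
#' @param record Record row index.
#' @param spec A [render_spec()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
render_single_record <- function(manifest, record, spec = render_spec(),
                                 path) {
  stopifnot(inherits(manifest, "sweep_manifest"))
  record <- as.integer(record)
  if (length(record) != 1L || record < 1L ||
      record > nrow(manifest$records))
    stop("invalid record index")
  g <- grid_geometry(manifest, spec)
  gap <- spec$gap
  w <- g$n_cols * g$cell_w + (g$n_cols - 1L) * gap
  canvas <- array(1, dim = c(g$cell_h, w, 3L))
  rid <- manifest$records$record_id[record]
  for (j in seq_len(g$n_cols)) {
    i <- (j - 1L) %/% g$n_channels + 1L
    k <- (j - 1L) %% g$n_channels + 1L
    cell <- record_cell(manifest, rid, i, k, g$inputs_01, spec)
    canvas <- place_cell(canvas, cell, (j - 1L) * (g$cell_w + gap) + 1L, 1L)
  }
  write_canvas(canvas, path, spec$format, title = "sweeplens record")
}
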