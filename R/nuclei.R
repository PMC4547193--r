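# Nuclei detection fixture: a five-parameter thresholding detector on
# grayscale photomicrograph-like images, exposing the analysis pattern of a
# parameter sweep over a cell-counting pipeline (object counts as measures,
# outline overlays as output images). Deliberately simple — no declumping of
# touching nuclei; it is a sweep subject, not a competitive segmenter.

# connected-component labels of a logical matrix via igraph; connectivity 8
# (default, foreground) or 4 (used for background holes)
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  h <- nrow(mask); w <- ncol(mask)
  verts <- which(mask)
  lab <- matrix(0L, h, w)
  if (length(verts) == 0L) return(lab)
  pos <- integer(h * w); pos[verts] <- seq_along(verts)
  id <- matrix(seq_len(h * w), h, w)
  edge_pairs <- function(ia, ib, keep) cbind(ia[keep], ib[keep])
  e <- list()
  if (w > 1L) e[[length(e) + 1L]] <- edge_pairs(  # right
    id[, -w], id[, -1L], mask[, -w] & mask[, -1L])
  if (h > 1L) e[[length(e) + 1L]] <- edge_pairs(  # down
    id[-h, ], id[-1L, ], mask[-h, ] & mask[-1L, ])
  if (connectivity == 8L && h > 1L && w > 1L) {
    e[[length(e) + 1L]] <- edge_pairs(            # down-right
      id[-h, -w], id[-1L, -1L], mask[-h, -w] & mask[-1L, -1L])
    e[[length(e) + 1L]] <- edge_pairs(            # down-left
      id[-h, -1L], id[-1L, -w], mask[-h, -1L] & mask[-1L, -w])
  }
  edges <- do.call(rbind, e)
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, rbind(pos[edges[, 1L]], pos[edges[, 2L]]))
  lab[verts] <- igraph::components(g)$membership
  lab
}

# fill background holes (4-connected, not touching the border) whose
# equivalent diameter is <= max_diameter px
fill_holes <- function(mask, max_diameter) {
  if (max_diameter <= 0 || !any(mask) || all(mask)) return(mask)
  holes <- label_components(!mask, connectivity = 4L)
  border <- unique(c(holes[1L, ], holes[nrow(holes), ],
                     holes[, 1L], holes[, ncol(holes)]))
  border <- border[border > 0L]
  areas <- tabulate(holes)
  fill <- setdiff(which(2 * sqrt(areas / pi) <= max_diameter &
                          areas > 0L), border)
  if (length(fill)) mask[holes %in% fill] <- TRUE
  mask
}

#' Detect nuclei by smoothing, thresholding and size filtering
#'
#' Pipeline: Gaussian smooth (`smoothing_sigma`, skipped when 0) → binarise
#' at `lower_threshold` → fill enclosed holes with equivalent diameter <=
#' `hole_fill` → 8-connected components → keep components whose equivalent
#' diameter (diameter of the circle with the component's area) lies in
#' `[min_diameter, max_diameter]`. The outline image is the input (as RGB)
#' with the 1-px boundaries of surviving components marked in red.
#'
#' @param image Grayscale H x W matrix, 0..255 scale.
#' @param smoothing_sigma Gaussian sigma, px (>= 0).
#' @param lower_threshold Intensity threshold (0..255); pixels strictly above
#'   it are foreground.
#' @param min_diameter,max_diameter Equivalent-diameter band, px.
#' @param hole_fill Largest hole equivalent diameter to fill, px.
#' @return List with `count` (integer), `outline` (H x W x 3, 0..255),
#'   `labels` (H x W integer matrix of surviving components).
#' @export
detect_nuclei <- function(image, smoothing_sigma = 1, lower_threshold = 100,
                          min_diameter = 6, max_diameter = 30,
                          hole_fill = 0) {
  if (!is.matrix(image))
    stop("'image' must be a single-channel (grayscale) matrix")
  if (min_diameter > max_diameter)
    stop("'min_diameter' must be <= 'max_diameter'")
  if (any(c(smoothing_sigma, lower_threshold, min_diameter, max_diameter,
            hole_fill) < 0))
    stop("all detection parameters must be >= 0")
  sm <- image
  if (smoothing_sigma > 0)
    sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(image / 255),
                                            sigma = smoothing_sigma)) * 255
  mask <- sm > lower_threshold
  mask <- fill_holes(mask, hole_fill)
  lab <- label_components(mask, connectivity = 8L)
  outline <- to_rgb(image)
  if (max(lab) == 0L)
    return(list(count = 0L, outline = outline,
                labels = matrix(0L, nrow(image), ncol(image))))
  areas <- tabulate(lab)
  eqd <- 2 * sqrt(areas / pi)
  keep <- which(eqd >= min_diameter & eqd <= max_diameter)
  lab[!(lab %in% keep)] <- 0L
  if (length(keep)) {
    h <- nrow(lab); w <- ncol(lab)
    pad <- matrix(0L, h + 2L, w + 2L)
    pad[2:(h + 1L), 2:(w + 1L)] <- lab
    ctr <- pad[2:(h + 1L), 2:(w + 1L)]
    boundary <- ctr > 0L &
      (pad[1:h, 2:(w + 1L)] != ctr | pad[3:(h + 2L), 2:(w + 1L)] != ctr |
         pad[2:(h + 1L), 1:w] != ctr | pad[2:(h + 1L), 3:(w + 2L)] != ctr)
    r <- outline[, , 1L]; g <- outline[, , 2L]; b <- outline[, , 3L]
    r[boundary] <- 255; g[boundary] <- 0; b[boundary] <- 0
    outline[, , 1L] <- r; outline[, , 2L] <- g; outline[, , 3L] <- b
  }
  list(count = length(keep), outline = outline, labels = lab)
}

#' Nuclei-detection sweep plugin
#'
#' Adapter exposing [detect_nuclei()] under the [sweep_plugin()] contract:
#' five swept parameters (`smoothing_sigma`, `lower_threshold`,
#' `min_diameter`, `max_diameter`, `hole_fill`), one measure per input image
#' (`object_count`) and one output channel (the outline overlay).
#'
#' @return A [sweep_plugin()] named `"nuclei_detection"`.
#' @export
nuclei_plugin <- function() {
  run <- function(image, params) {
    if (length(dim(image)) == 3L) {
      if (dim(image)[3] == 1L) image <- image[, , 1L]
      else stop("nuclei detection expects a single-channel image")
    }
    res <- detect_nuclei(image,
                         smoothing_sigma = params$smoothing_sigma,
                         lower_threshold = params$lower_threshold,
                         min_diameter = params$min_diameter,
                         max_diameter = params$max_diameter,
                         hole_fill = params$hole_fill)
    list(measures = list(object_count = as.numeric(res$count)),
         channels = list(res$outline))
  }
  sweep_plugin("nuclei_detection", measure_names = "object_count",
               n_channels = 1L, run = run, settings = list())
}
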