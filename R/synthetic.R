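# Synthetic inputs with known ground truth: two-stain histology-like RGB
# images produced by forward Beer-Lambert mixing of known density fields, and
# grayscale photomicrograph-like images of bright disks with known object
# counts. All generators are pure functions of (parameters, seed).

# evaluate an expression with a private, restored RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

#' Bundle per-stain density fields for forward mixing
#'
#' @param densities List of H x W matrices of stain densities (OD units,
#'   non-negative, same shape).
#' @param vectors Stain OD vectors used for mixing (one row per density
#'   field).
#' @param I0 Background intensity per channel (scalar or length 3).
#' @param noise_sd Additive Gaussian noise in intensity units (0 = none).
#' @param seed Seed for the noise.
#' @return An object of class `density_field`.
#' @export
density_field <- function(densities, vectors = he_stain_vectors(), I0 = 255,
                          noise_sd = 0, seed = 1L) {
  stopifnot(is.list(densities), length(densities) >= 1L)
  dims <- lapply(densities, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("density fields must share one spatial shape")
  if (any(vapply(densities, function(d) any(d < 0 | !is.finite(d)),
                 logical(1))))
    stop("densities must be non-negative and finite")
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != length(densities))
    stop("need one stain vector per density field")
  vectors <- vectors / sqrt(rowSums(vectors^2))
  if (length(I0) == 1L) I0 <- rep(I0, 3L)
  structure(list(densities = densities, vectors = vectors, I0 = I0,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "density_field")
}

#' Generate smooth blob-structured stain density fields
#'
#' Emulates the spatial structure of H&E-stained tissue: stain 1
#' (hematoxylin-like) gets small, strong Gaussian bumps mimicking nuclei;
#' stain 2 (eosin-like) gets broader, weaker bumps mimicking cytoplasm and
#' connective tissue. A small uniform baseline absorption (blank slide +
#' mounting medium) keeps densities strictly positive everywhere.
#'
#' @param shape `c(height, width)` in pixels.
#' @param n_blobs Integer vector, bumps per stain (default 24 nuclei-like,
#'   10 cytoplasm-like).
#' @param amplitude Peak density per bump, per stain (OD units).
#' @param sigma Bump radius per stain (px).
#' @param baseline Uniform baseline density per stain (OD units).
#' @param vectors,I0,noise_sd Passed to [density_field()].
#' @param seed Seed controlling bump placement (and noise downstream).
#' @return A [density_field()].
#' @export
generate_structured_densities <- function(shape = c(256, 256),
                                          n_blobs = c(24, 10),
                                          amplitude = c(0.8, 0.4),
                                          sigma = c(5, 14),
                                          baseline = 0.02,
                                          vectors = he_stain_vectors(),
                                          I0 = 255, noise_sd = 0, seed = 1L) {
  if (length(shape) != 2L || any(shape < 1)) stop("invalid 'shape'")
  n_blobs <- rep_len(as.integer(n_blobs), 2L)
  amplitude <- rep_len(amplitude, 2L)
  sigma <- rep_len(sigma, 2L)
  h <- shape[1L]; w <- shape[2L]
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  densities <- with_seed(seed, lapply(1:2, function(s) {
    d <- matrix(baseline, h, w)
    if (n_blobs[s] > 0L) {
      cy <- stats::runif(n_blobs[s], 1, h)
      cx <- stats::runif(n_blobs[s], 1, w)
      for (b in seq_len(n_blobs[s]))
        d <- d + amplitude[s] *
          exp(-((yy - cy[b])^2 + (xx - cx[b])^2) / (2 * sigma[s]^2))
    }
    d
  }))
  density_field(densities, vectors = vectors, I0 = I0, noise_sd = noise_sd,
                seed = seed)
}

#' Forward Beer-Lambert mixing of a density field
#'
#' Produces the RGB image a slide with the given stain densities would
#' transmit: per pixel and channel,
#' `I_c = I0_c * 10^(-sum_s D_s v_{s,c}) + noise`, clipped to `[0, I0_c]`.
#' The ground-truth densities are returned alongside the image so
#' deconvolution accuracy can be scored exactly.
#'
#' @param field A [density_field()].
#' @return List with `image` (H x W x 3, 0..I0 scale), `densities` (the
#'   ground truth), `vectors` and `I0`.
#' @export
generate_two_stain_image <- function(field) {
  stopifnot(inherits(field, "density_field"))
  d <- dim(field$densities[[1L]])
  od <- array(0, dim = c(d, 3L))
  for (s in seq_along(field$densities))
    for (c in 1:3)
      od[, , c] <- od[, , c] + field$densities[[s]] * field$vectors[s, c]
  img <- array(0, dim = c(d, 3L))
  for (c in 1:3) img[, , c] <- field$I0[c] * 10^(-od[, , c])
  if (field$noise_sd > 0) {
    img <- img + with_seed(field$seed,
                           array(stats::rnorm(length(img), 0, field$noise_sd),
                                 dim = dim(img)))
  }
  for (c in 1:3) img[, , c] <- pmin(pmax(img[, , c], 0), field$I0[c])
  list(image = img, densities = field$densities, vectors = field$vectors,
       I0 = field$I0)
}

#' Generate a synthetic nuclei photomicrograph
#'
#' Places `n_disks` non-overlapping bright disks (rejection sampling) on a
#' dark background and optionally adds Gaussian noise, emulating fluorescence
#' photomicrographs of stained cell nuclei. Ground-truth count and centres
#' are returned for scoring detection.
#'
#' @param shape `c(height, width)` px.
#' @param n_disks Number of nuclei.
#' @param diameter Disk diameter, px.
#' @param intensity Disk intensity (0..255).
#' @param background Background intensity (0..255).
#' @param noise_sd Additive Gaussian noise sd in intensity units.
#' @param seed Seed for placement and noise.
#' @param min_gap Minimum edge-to-edge gap between disks, px.
#' @param max_tries Rejection-sampling budget; exceeded placement errors.
#' @return List with `image` (H x W matrix, 0..255), `count`, `centers`
#'   (n x 2 matrix of (y, x)).
#' @export
generate_nuclei_image <- function(shape = c(256, 256), n_disks = 12,
                                  diameter = 10, intensity = 200,
                                  background = 20, noise_sd = 0, seed = 1L,
                                  min_gap = 4, max_tries = 10000L) {
  if (length(shape) != 2L || any(shape < 1)) stop("invalid 'shape'")
  h <- shape[1L]; w <- shape[2L]
  r <- diameter / 2
  if (2 * r + 2 > min(h, w) && n_disks > 0)
    stop("disks do not fit within the image")
  with_seed(seed, {
    centers <- matrix(numeric(0), 0L, 2L)
    tries <- 0L
    while (nrow(centers) < n_disks) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n_disks, " non-overlapping disks in ",
             max_tries, " attempts")
      cy <- stats::runif(1, r + 1, h - r)
      cx <- stats::runif(1, r + 1, w - r)
      if (nrow(centers) == 0L ||
          all(sqrt((centers[, 1L] - cy)^2 + (centers[, 2L] - cx)^2) >=
              diameter + min_gap))
        centers <- rbind(centers, c(cy, cx))
    }
    img <- matrix(background, h, w)
    if (n_disks > 0L) {
      yy <- matrix(seq_len(h), h, w)
      xx <- matrix(seq_len(w), h, w, byrow = TRUE)
      for (b in seq_len(n_disks)) {
        inside <- (yy - centers[b, 1L])^2 + (xx - centers[b, 2L])^2 <= r^2
        img[inside] <- intensity
      }
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
    img <- pmin(pmax(img, 0), 255)
    list(image = img, count = as.integer(n_disks), centers = centers)
  })
}
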