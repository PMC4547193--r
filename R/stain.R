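# Colour deconvolution of dye-stained tissue images in optical-density (OD)
# space, with a corrective in-plane rotation of each stain vector and
# negative-coefficient quality measures.
#
# Model: transmitted intensity follows the Beer-Lambert law,
#   I_c = I0_c * 10^(-sum_s D_s * v_{s,c}),
# where D_s is the density of stain s and v_s its unit OD(R,G,B) vector.
# Absorbances add, so in OD space the image is a linear mixture and per-pixel
# stain densities are recovered by inverting the stain matrix. A mismatched
# matrix produces physically impossible negative coefficients; their
# prevalence quantifies deconvolution quality.

#' Reference H&E stain OD vectors
#'
#' Unit optical-density vectors for hematoxylin (stains nuclei) and eosin
#' (stains cytoplasm and connective tissue), after Ruifrok & Johnson's
#' empirical calibration; rows are stains, columns are (R, G, B).
#'
#' @return A 2 x 3 matrix with unit-norm rows.
#' @export
he_stain_vectors <- function() {
  v <- rbind(hematoxylin = c(0.650, 0.704, 0.286),
             eosin       = c(0.072, 0.990, 0.105))
  colnames(v) <- c("R", "G", "B")
  v / sqrt(rowSums(v^2))
}

#' Stain model with corrective rotation parameters
#'
#' Bundles the base stain vectors with the two corrective parameters `p1`
#' (stain 1, hematoxylin for H&E) and `p2` (stain 2, eosin). Each parameter
#' rotates its stain vector by that angle (radians) within the plane spanned
#' by the two base vectors; `p1 = p2 = 0` leaves the base matrix unchanged,
#' so the midpoint of a symmetric sweep interval represents "no change".
#'
#' @param vectors 2 x 3 matrix of stain OD vectors (rows; need not be
#'   pre-normalised, but must be non-negative and linearly independent).
#' @param p1,p2 Corrective rotation angles in radians.
#' @param I0 Background (blank slide) intensity per channel, scalar or
#'   length 3, on the image intensity scale.
#' @return An object of class `stain_model`.
#' @export
stain_model <- function(vectors = he_stain_vectors(), p1 = 0, p2 = 0,
                        I0 = 255) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 2L || ncol(vectors) != 3L)
    stop("'vectors' must be a 2 x 3 matrix (stain rows, RGB columns)")
  if (any(vectors < 0)) stop("stain OD vectors must be non-negative")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("stain OD vectors must be non-zero")
  vectors <- vectors / nrm
  if (length(I0) == 1L) I0 <- rep(I0, 3L)
  if (any(I0 <= 0)) stop("'I0' must be positive")
  structure(list(vectors = vectors, p1 = p1, p2 = p2, I0 = I0),
            class = "stain_model")
}

#' Transform intensities to optical density
#'
#' Applies the Beer-Lambert transform `OD = -log10(I / I0)` per channel.
#' Intensities are clamped below at `eps` (default 1 on the 8-bit scale)
#' before the logarithm so zero pixels map to a large finite OD.
#'
#' @param image RGB image, H x W x 3 numeric array on the intensity scale of
#'   `I0`.
#' @param I0 Background intensity, scalar or per-channel length 3; must be
#'   positive.
#' @param eps Lower intensity clamp (same units as `image`).
#' @return H x W x 3 array of optical densities (>= 0 wherever `I <= I0`).
#' @export
rgb_to_od <- function(image, I0 = 255, eps = 1) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("'image' must be an H x W x 3 RGB array")
  if (length(I0) == 1L) I0 <- rep(I0, 3L)
  if (any(!is.finite(I0)) || any(I0 <= 0)) stop("'I0' must be positive")
  od <- image
  for (c in 1:3)
    od[, , c] <- -log10(pmin(pmax(image[, , c], eps), I0[c]) / I0[c])
  od
}

# rotate the two stain vectors within their common plane and complete with
# the normalised cross product
rotated_stain_matrix <- function(model) {
  v1 <- model$vectors[1L, ]; v2 <- model$vectors[2L, ]
  e1 <- v1
  w <- v2 - sum(v2 * e1) * e1
  nw <- sqrt(sum(w^2))
  if (nw < 1e-8)
    stop("stain vectors are (nearly) collinear; deconvolution matrix is ",
         "ill-conditioned")
  e2 <- w / nw
  r1 <- cos(model$p1) * e1 + sin(model$p1) * e2
  a <- sum(v2 * e1); b <- sum(v2 * e2)
  ab <- c(cos(model$p2) * a - sin(model$p2) * b,
          sin(model$p2) * a + cos(model$p2) * b)
  r2 <- ab[1L] * e1 + ab[2L] * e2
  r3 <- c(r1[2L] * r2[3L] - r1[3L] * r2[2L],
          r1[3L] * r2[1L] - r1[1L] * r2[3L],
          r1[1L] * r2[2L] - r1[2L] * r2[1L])
  n3 <- sqrt(sum(r3^2))
  if (n3 < 1e-8)
    stop("rotated stain vectors are collinear; cannot complete the matrix")
  rbind(stain1 = r1, stain2 = r2, residual = r3 / n3)
}

#' Build the deconvolution matrix for a stain model
#'
#' Rotates stain vector 1 by `p1` and stain vector 2 by `p2` within the plane
#' the two base vectors span, completes the 3 x 3 stain matrix with the
#' normalised cross product of the rotated vectors, and returns its inverse.
#' Applying the result to an OD row vector yields (stain 1, stain 2,
#' residual) coefficients. With `p1 = p2 = 0` this is the inverse of the
#' unmodified base matrix (the transpose, when the base rows are
#' orthonormal).
#'
#' @param model A [stain_model()].
#' @return 3 x 3 deconvolution matrix with the rotated stain matrix attached
#'   as attribute `"stain_matrix"`.
#' @export
build_deconv_matrix <- function(model) {
  stopifnot(inherits(model, "stain_model"))
  S <- rotated_stain_matrix(model)
  if (rcond(S) < 1e-8) stop("stain matrix is ill-conditioned")
  M <- solve(S)
  attr(M, "stain_matrix") <- S
  M
}

#' Deconvolve an OD image into per-stain coefficient images
#'
#' Per pixel, coefficients are the OD vector multiplied by the deconvolution
#' matrix; coefficients may be negative when the matrix does not match the
#' image's true mixture. Zero OD maps to zero coefficients and the operation
#' is linear, so `deconvolve(k * od) = k * deconvolve(od)`.
#'
#' @param od H x W x 3 optical-density array (from [rgb_to_od()]).
#' @param matrix 3 x 3 deconvolution matrix (from [build_deconv_matrix()]).
#' @return H x W x 3 array: stain-1, stain-2 and residual coefficient planes.
#' @export
deconvolve <- function(od, matrix) {
  if (length(dim(od)) != 3L || dim(od)[3] != 3L)
    stop("'od' must be an H x W x 3 array")
  if (!identical(dim(matrix), c(3L, 3L)))
    stop("'matrix' must be 3 x 3")
  d <- dim(od)
  flat <- matrix(od, ncol = 3L) %*% matrix
  array(flat, dim = d)
}

#' Statistics of negative deconvolution coefficients
#'
#' Quality measures of one coefficient plane: the percentage of pixels with a
#' negative coefficient, and the mean and population standard deviation of
#' the negative coefficients themselves. When no coefficient is negative all
#' three are 0 by convention.
#'
#' @param coeffs Numeric array/matrix of coefficients (finite).
#' @return Named numeric: `pct` (0-100), `mean` (<= 0), `sd` (>= 0).
#' @examples
#' negative_coefficient_stats(c(1, -1, -3, 2))  # pct 50, mean -2, sd 1
#' @export
negative_coefficient_stats <- function(coeffs) {
  x <- as.numeric(coeffs)
  if (length(x) == 0L) stop("empty coefficient image")
  if (any(!is.finite(x))) stop("coefficients must be finite")
  neg <- x[x < 0]
  if (length(neg) == 0L) return(c(pct = 0, mean = 0, sd = 0))
  m <- mean(neg)
  c(pct = 100 * length(neg) / length(x), mean = m,
    sd = sqrt(mean((neg - m)^2)))
}

# single-dye RGB reconstruction for display: clamp coefficients at 0 (display
# only; statistics always use the raw coefficients)
stain_viewable <- function(coeff_plane, stain_vector, I0) {
  cpos <- pmax(coeff_plane, 0)
  out <- array(0, dim = c(dim(coeff_plane), 3L))
  for (c in 1:3) out[, , c] <- I0[c] * 10^(-cpos * stain_vector[c])
  out
}

#' Colour-deconvolution sweep plugin
#'
#' Wraps the deconvolution pipeline as a [sweep_plugin()] over the corrective
#' parameters `p1` and `p2`: per input image it transforms to OD, builds the
#' corrected deconvolution matrix, deconvolves, and reports six quality
#' measures — `m1`/`m2`/`m3` the percentage, mean and standard deviation of
#' negative coefficients for stain 1, and `m4`/`m5`/`m6` the same for stain 2
#' ([negative_coefficient_stats()]). Its two output channels are the
#' reconstructed single-dye images of each stain (coefficients clamped at
#' zero for display only).
#'
#' @param vectors Base stain vectors (2 x 3), default [he_stain_vectors()].
#' @param I0 Background intensity per channel.
#' @param eps Intensity clamp for the OD transform.
#' @return A [sweep_plugin()] named `"stain_deconvolution"` declaring
#'   measures `m1`..`m6` and 2 output channels.
#' @export
deconvolution_plugin <- function(vectors = he_stain_vectors(), I0 = 255,
                                 eps = 1) {
  if (length(I0) == 1L) I0 <- rep(I0, 3L)
  force(vectors); force(eps)
  run <- function(image, params) {
    model <- stain_model(vectors, p1 = params$p1, p2 = params$p2, I0 = I0)
    M <- build_deconv_matrix(model)
    S <- attr(M, "stain_matrix")
    od <- rgb_to_od(image, I0 = I0, eps = eps)
    co <- deconvolve(od, M)
    s1 <- negative_coefficient_stats(co[, , 1L])
    s2 <- negative_coefficient_stats(co[, , 2L])
    list(measures = list(m1 = s1[["pct"]], m2 = s1[["mean"]],
                         m3 = s1[["sd"]], m4 = s2[["pct"]],
                         m5 = s2[["mean"]], m6 = s2[["sd"]]),
         channels = list(stain_viewable(co[, , 1L], S[1L, ], I0),
                         stain_viewable(co[, , 2L], S[2L, ], I0)))
  }
  sweep_plugin("stain_deconvolution",
               measure_names = c("m1", "m2", "m3", "m4", "m5", "m6"),
               n_channels = 2L, run = run,
               settings = list(vectors = unname(vectors), I0 = I0, eps = eps,
                               correction = "in_plane_rotation"))
}
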