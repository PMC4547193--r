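#' Define a swept input parameter
#'
#' A parameter spec names one real-valued algorithm input and describes how
#' its interval is sampled: `n_samples` evenly spaced values including both
#' endpoints. Sampling an interval symmetric about zero with an odd
#' `n_samples` places a sample exactly at zero, which is convenient when the
#' midpoint represents "no change" (as with corrective stain parameters).
#'
#' @param name Parameter name (non-empty string, unique within a sweep).
#' @param lo,hi Interval endpoints in parameter units, `lo <= hi`. `lo == hi`
#'   is only valid with `n_samples = 1`.
#' @param n_samples Number of evenly spaced samples (integer >= 1).
#' @return An object of class `parameter_spec`.
#' @examples
#' sample_parameter(parameter_spec("p1", -0.5, 0.5, 11))
#' @export
parameter_spec <- function(name, lo, hi, n_samples) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!is.finite(lo) || !is.finite(hi)) stop("'lo' and 'hi' must be finite")
  if (lo > hi) stop("'lo' must be <= 'hi' for parameter '", name, "'")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop("'n_samples' must be an integer >= 1")
  if (lo == hi && n_samples > 1L)
    stop("degenerate interval (lo == hi) requires n_samples = 1 for '",
         name, "'")
  structure(list(name = name, lo = lo, hi = hi, n_samples = n_samples),
            class = "parameter_spec")
}

#' @export
print.parameter_spec <- function(x, ...) {
  cat(sprintf("<parameter_spec> %s in [%g, %g], %d samples\n",
              x$name, x$lo, x$hi, x$n_samples))
  invisible(x)
}

#' Describe one output measure of a sweep
#'
#' @param name Measure name, unique within a sweep.
#' @param input_image_index 1-based index of the input image this measure
#'   describes.
#' @param description Free-text description.
#' @return An object of class `measure_spec`.
#' @export
measure_spec <- function(name, input_image_index, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  input_image_index <- as.integer(input_image_index)
  if (is.na(input_image_index) || input_image_index < 1L)
    stop("'input_image_index' must be a positive integer")
  structure(list(name = name, input_image_index = input_image_index,
                 description = as.character(description)),
            class = "measure_spec")
}

#' Sample a parameter's interval
#'
#' Returns `n_samples` evenly spaced values covering `[lo, hi]` inclusively.
#' Samples are computed as exact convex combinations
#' `lo * (1 - t) + hi * t`, `t = k / (n - 1)`, so the endpoints are
#' reproduced exactly and a symmetric interval yields an exact zero at its
#' midpoint sample.
#'
#' @param spec A [parameter_spec()].
#' @return Numeric vector of length `spec$n_samples`, strictly increasing
#'   when `lo < hi`.
#' @export
sample_parameter <- function(spec) {
  stopifnot(inherits(spec, "parameter_spec"))
  n <- spec$n_samples
  if (n == 1L) return(spec$lo)
  t <- (0:(n - 1L)) / (n - 1L)
  spec$lo * (1 - t) + spec$hi * t
}

#' Expand parameter specs into the full Cartesian grid
#'
#' Enumerates every combination of sampled parameter values. The enumeration
#' order is canonical: the *last* parameter varies fastest, so `record_id`
#' (the row number) is reproducible across runs and implementations.
#'
#' @param specs List of [parameter_spec()] objects with unique names.
#' @return A data frame with one column per parameter (in spec order) and
#'   `prod(n_samples)` rows.
#' @examples
#' specs <- list(parameter_spec("p1", -0.5, 0.5, 11),
#'               parameter_spec("p2", -0.5, 0.5, 11))
#' nrow(expand_param_grid(specs))  # 121
#' @export
expand_param_grid <- function(specs) {
  if (length(specs) < 1L) stop("at least one parameter spec is required")
  if (!all(vapply(specs, inherits, logical(1), "parameter_spec")))
    stop("'specs' must be a list of parameter_spec objects")
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate parameter names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  samples <- lapply(specs, sample_parameter)
  names(samples) <- nms
  # expand.grid varies the first factor fastest; reverse to make the last
  # parameter fastest, then restore column order
  grid <- expand.grid(rev(samples), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(samples)), drop = FALSE]
  names(grid) <- nms
  rownames(grid) <- NULL
  grid
}
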