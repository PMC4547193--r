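#' Define a sweep plugin
#'
#' A plugin is the algorithm under study. Its `run` function is executed once
#' per (parameter combination, input image) pair and must be deterministic
#' given its inputs. It returns the declared measures (named numeric) and the
#' declared number of output channel images; [run_sweep()] verifies both
#' against the declaration for every invocation.
#'
#' @param name Plugin identifier.
#' @param measure_names Character vector of measure names produced per input
#'   image (e.g. `c("m1", ..., "m6")`).
#' @param n_channels Number of output channel images produced per input image.
#' @param run `function(image, params)` where `image` is a 0..255 numeric
#'   array and `params` a named list of parameter values; must return
#'   `list(measures = <named numeric>, channels = <list of images>)`.
#' @param settings Named list of fixed plugin settings, recorded in the
#'   manifest for provenance.
#' @return An object of class `sweep_plugin`.
#' @seealso [deconvolution_plugin()], [nuclei_plugin()]
#' @export
sweep_plugin <- function(name, measure_names, n_channels, run,
                         settings = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(measure_names), length(measure_names) >= 1L,
            !anyDuplicated(measure_names),
            is.function(run))
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L)
    stop("'n_channels' must be a positive integer")
  structure(list(name = name, measure_names = measure_names,
                 n_channels = n_channels, run = run, settings = settings),
            class = "sweep_plugin")
}

#' @export
print.sweep_plugin <- function(x, ...) {
  cat(sprintf("<sweep_plugin> %s: %d measures/image (%s), %d channels/image\n",
              x$name, length(x$measure_names),
              paste(x$measure_names, collapse = ", "), x$n_channels))
  invisible(x)
}

# run a plugin once and validate its output against the declaration
run_plugin_checked <- function(plugin, image, params, context) {
  res <- tryCatch(plugin$run(image, params),
                  error = function(e) stop("plugin '", plugin$name,
                                           "' failed at ", context, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(res) || !all(c("measures", "channels") %in% names(res)))
    stop("plugin '", plugin$name, "' must return list(measures=, channels=)")
  m <- unlist(res$measures)
  if (!identical(sort(names(m)), sort(plugin$measure_names)))
    stop("plugin '", plugin$name, "' returned measures {",
         paste(names(m), collapse = ","), "} at ", context,
         "; declared {", paste(plugin$measure_names, collapse = ","), "}")
  if (length(res$channels) != plugin$n_channels)
    stop("plugin '", plugin$name, "' returned ", length(res$channels),
         " channels at ", context, "; declared ", plugin$n_channels)
  list(measures = m[plugin$measure_names], channels = res$channels)
}
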