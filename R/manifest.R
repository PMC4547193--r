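# Sweep manifests: the on-disk unit of a persisted sweep. A manifest is a
# JSON header (specs, plugin, seed, image references) plus a sibling
# records.csv holding the flat record table, parameters then measures in
# column order. Real values are serialised with 17 significant digits so a
# write/read cycle is bit-faithful.

MANIFEST_VERSION <- 1L

#' Construct a sweep manifest
#'
#' Usually produced by [run_sweep()]; exposed so sweeps can be assembled or
#' manipulated programmatically.
#'
#' @param params List of [parameter_spec()].
#' @param measures List of [measure_spec()], one per (measure, input image).
#' @param plugin_name,plugin_settings Plugin identifier and its fixed
#'   settings (provenance).
#' @param seed Integer seed the sweep was run with.
#' @param input_images Character vector of input-image paths, relative to the
#'   manifest directory.
#' @param records Data frame: `record_id`, then one column per parameter,
#'   then one column per measure.
#' @param image_refs Data frame with columns `record_id`, `input`, `channel`,
#'   `path` (relative paths to output images).
#' @param dir Optional directory the relative paths resolve against.
#' @return An object of class `sweep_manifest`.
#' @export
sweep_manifest <- function(params, measures, plugin_name,
                           plugin_settings = list(), seed = 0L,
                           input_images = character(),
                           records, image_refs =
                             data.frame(record_id = integer(),
                                        input = integer(),
                                        channel = integer(),
                                        path = character()),
                           dir = NULL) {
  stopifnot(is.list(params), is.list(measures), is.data.frame(records),
            is.data.frame(image_refs))
  pn <- vapply(params, `[[`, character(1), "name")
  mn <- vapply(measures, `[[`, character(1), "name")
  if (anyDuplicated(mn)) stop("duplicate measure names")
  expected <- c("record_id", pn, mn)
  if (!identical(names(records), expected))
    stop("records columns must be: ", paste(expected, collapse = ", "))
  m <- structure(list(version = MANIFEST_VERSION,
                      params = params, measures = measures,
                      plugin_name = plugin_name,
                      plugin_settings = plugin_settings,
                      seed = as.integer(seed),
                      input_images = as.character(input_images),
                      records = records, image_refs = image_refs),
                 class = "sweep_manifest")
  attr(m, "dir") <- dir
  m
}

#' @export
print.sweep_manifest <- function(x, ...) {
  cat(sprintf(
    "<sweep_manifest> plugin '%s': %d records, %d parameters, %d measures, %d input images\n",
    x$plugin_name, nrow(x$records), length(x$params), length(x$measures),
    length(x$input_images)))
  invisible(x)
}

#' Names of the parameter / measure columns of a manifest
#' @param manifest A `sweep_manifest`.
#' @return Character vector of column names.
#' @export
param_columns <- function(manifest) {
  vapply(manifest$params, `[[`, character(1), "name")
}

#' @rdname param_columns
#' @export
measure_columns <- function(manifest) {
  vapply(manifest$measures, `[[`, character(1), "name")
}

fmt_real <- function(x) sprintf("%.17g", x)

records_to_csv_lines <- function(records) {
  header <- paste(names(records), collapse = ",")
  if (nrow(records) == 0L) return(header)
  cols <- c(list(sprintf("%d", as.integer(records$record_id))),
            lapply(records[-1L], fmt_real))
  c(header, do.call(paste, c(cols, sep = ",")))
}

#' Write a sweep manifest to disk
#'
#' Writes `manifest.json` and `records.csv` into `dir`. All output-image
#' files referenced by the manifest must already exist under `dir`; a
#' dangling reference aborts the write with the missing path named.
#'
#' @param manifest A [sweep_manifest()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  stopifnot(inherits(manifest, "sweep_manifest"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  refs <- c(manifest$input_images, manifest$image_refs$path)
  missing <- refs[!file.exists(file.path(dir, refs))]
  if (length(missing))
    stop("dangling image reference(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  header <- list(
    format = "sweeplens-manifest",
    version = manifest$version,
    plugin = list(name = manifest$plugin_name,
                  settings = manifest$plugin_settings),
    seed = manifest$seed,
    n_records = nrow(manifest$records),
    parameters = lapply(manifest$params, function(p)
      list(name = p$name, lo = p$lo, hi = p$hi, n_samples = p$n_samples)),
    measures = lapply(manifest$measures, function(m)
      list(name = m$name, input_image_index = m$input_image_index,
           description = m$description)),
    input_images = manifest$input_images,
    image_refs = manifest$image_refs)
  json <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE, dataframe = "columns")
  writeLines(json, file.path(dir, "manifest.json"), useBytes = TRUE)
  writeLines(records_to_csv_lines(manifest$records),
             file.path(dir, "records.csv"), useBytes = TRUE)
  invisible(dir)
}

#' Read a sweep manifest from disk
#'
#' Reconstructs the manifest written by [write_manifest()], verifying the
#' format marker, version, and that the CSV row count matches the declared
#' record count.
#'
#' @param dir Directory containing `manifest.json` and `records.csv`.
#' @return A [sweep_manifest()] with `attr(, "dir")` set to `dir`.
#' @export
read_manifest <- function(dir) {
  jpath <- file.path(dir, "manifest.json")
  cpath <- file.path(dir, "records.csv")
  if (!file.exists(jpath)) stop("no manifest.json in ", dir)
  if (!file.exists(cpath)) stop("no records.csv in ", dir)
  h <- tryCatch(jsonlite::fromJSON(jpath, simplifyDataFrame = TRUE),
                error = function(e) stop("malformed manifest.json in ", dir,
                                         ": ", conditionMessage(e),
                                         call. = FALSE))
  if (!identical(h$format, "sweeplens-manifest"))
    stop("not a sweeplens manifest: ", jpath)
  if (!identical(as.integer(h$version), MANIFEST_VERSION))
    stop("manifest version ", h$version, " not supported (expected ",
         MANIFEST_VERSION, ")")
  params <- lapply(seq_len(nrow(h$parameters)), function(i)
    parameter_spec(h$parameters$name[i], h$parameters$lo[i],
                   h$parameters$hi[i], h$parameters$n_samples[i]))
  measures <- lapply(seq_len(nrow(h$measures)), function(i)
    measure_spec(h$measures$name[i], h$measures$input_image_index[i],
                 h$measures$description[i]))
  expected_cols <- c("record_id", h$parameters$name, h$measures$name)
  got_header <- strsplit(readLines(cpath, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(got_header, expected_cols))
    stop("records.csv columns (", paste(got_header, collapse = ","),
         ") do not match manifest.json specs")
  col_classes <- stats::setNames(
    c("integer", rep("numeric", length(expected_cols) - 1L)), expected_cols)
  records <- tryCatch(
    utils::read.csv(cpath, check.names = FALSE, colClasses = col_classes),
    error = function(e) stop("malformed records.csv in ", dir, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(records) != h$n_records)
    stop("records.csv has ", nrow(records), " rows but manifest.json ",
         "declares ", h$n_records)
  refs <- h$image_refs
  if (is.null(refs) || length(refs) == 0L || NROW(refs) == 0L) {
    refs <- data.frame(record_id = integer(), input = integer(),
                       channel = integer(), path = character())
  } else {
    refs <- data.frame(record_id = as.integer(refs$record_id),
                       input = as.integer(refs$input),
                       channel = as.integer(refs$channel),
                       path = as.character(refs$path))
  }
  settings <- h$plugin$settings
  if (is.null(settings)) settings <- list()
  if (length(settings) == 0L) settings <- list() else settings <- as.list(settings)
  sweep_manifest(params = params, measures = measures,
                 plugin_name = h$plugin$name, plugin_settings = settings,
                 seed = h$seed, input_images = as.character(h$input_images),
                 records = records, image_refs = refs, dir = dir)
}
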