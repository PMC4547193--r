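#' Run a Cartesian parameter sweep
#'
#' Expands the parameter specs into the full grid ([expand_param_grid()]) and
#' executes the plugin once per (combination, input image) pair, collecting
#' one data record per combination: its parameter values, the measures the
#' plugin reports for every input image, and the plugin's output channel
#' images. Output images are written under `out_dir/images/` as
#' `rec<id>_in<i>_ch<k>.png`; the returned manifest (also written to
#' `out_dir` when `write = TRUE`) references them by relative path.
#'
#' Records are emitted in canonical enumeration order (last parameter varies
#' fastest), so `record_id` equals the grid row number and re-running the
#' same configuration and seed reproduces `records.csv` byte for byte.
#' A plugin error on any combination aborts the sweep with the record id,
#' image index and parameter values named.
#'
#' Measure columns are named `<measure>_i<image index>`, e.g. `m1_i1` is
#' measure `m1` on the first input image.
#'
#' @param specs List of [parameter_spec()].
#' @param input_images List of images (0..255 numeric arrays) or file paths.
#' @param plugin A [sweep_plugin()].
#' @param seed Integer seed, recorded in the manifest and set before the run
#'   so any stochastic plugin is reproducible.
#' @param out_dir Output directory for images and manifest.
#' @param write Write `manifest.json` / `records.csv` as well (default TRUE).
#' @return The [sweep_manifest()], invisibly when `write = TRUE`.
#' @examples
#' \donttest{
#' specs <- list(parameter_spec("p1", -0.2, 0.2, 3),
#'               parameter_spec("p2", -0.2, 0.2, 3))
#' img <- generate_two_stain_image(generate_structured_densities(
#'   shape = c(64, 64), seed = 1))$image
#' man <- run_sweep(specs, list(img), deconvolution_plugin(),
#'                  seed = 1, out_dir = tempfile())
#' nrow(man$records)  # 9
#' }
#' @export
run_sweep <- function(specs, input_images, plugin, seed, out_dir,
                      write = TRUE) {
  stopifnot(inherits(plugin, "sweep_plugin"))
  if (length(input_images) < 1L) stop("at least one input image is required")
  grid <- expand_param_grid(specs)
  n_img <- length(input_images)
  images <- lapply(input_images, function(x)
    if (is.character(x)) read_image(x) else x)

  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  input_paths <- sprintf("images/input%d.png", seq_len(n_img))
  for (i in seq_len(n_img))
    write_image_png(images[[i]], file.path(out_dir, input_paths[i]))

  measure_names <- as.vector(vapply(seq_len(n_img), function(i)
    paste0(plugin$measure_names, "_i", i),
    character(length(plugin$measure_names))))
  measures <- unlist(lapply(seq_len(n_img), function(i)
    lapply(plugin$measure_names, function(m)
      measure_spec(paste0(m, "_i", i), i,
                   paste0(m, " on input image ", i)))), recursive = FALSE)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  n_rec <- nrow(grid)
  mvals <- matrix(NA_real_, n_rec, length(measure_names),
                  dimnames = list(NULL, measure_names))
  refs <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    params <- as.list(grid[r, , drop = FALSE])
    rrefs <- data.frame(record_id = integer(), input = integer(),
                        channel = integer(), path = character())
    for (i in seq_len(n_img)) {
      ctx <- sprintf("record %d, image %d, params (%s)", r, i,
                     paste(names(params), unlist(params), sep = "=",
                           collapse = ", "))
      res <- run_plugin_checked(plugin, images[[i]], params, ctx)
      mvals[r, paste0(plugin$measure_names, "_i", i)] <- res$measures
      for (k in seq_along(res$channels)) {
        p <- sprintf("images/rec%d_in%d_ch%d.png", r, i, k)
        write_image_png(res$channels[[k]], file.path(out_dir, p))
        rrefs <- rbind(rrefs, data.frame(record_id = r, input = i,
                                         channel = k, path = p))
      }
    }
    refs[[r]] <- rrefs
  }
  records <- cbind(data.frame(record_id = seq_len(n_rec)), grid,
                   as.data.frame(mvals))
  manifest <- sweep_manifest(
    params = specs, measures = measures, plugin_name = plugin$name,
    plugin_settings = plugin$settings, seed = as.integer(seed),
    input_images = input_paths, records = records,
    image_refs = do.call(rbind, refs), dir = out_dir)
  if (write) {
    write_manifest(manifest, out_dir)
    return(invisible(manifest))
  }
  manifest
}
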