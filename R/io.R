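# On-disk format: per field f, multi-page 16-bit TIFFs labeled_<f>.tif and
# control_<f>.tif (one page per z slice), an integer label mask
# mask_<f>.tif, plus truth.json and config.yaml at the top level.

stack_to_pages <- function(stack) {
  lapply(seq_len(dim(stack)[3]), function(z)
    pmin(pmax(round(stack[, , z]), 0), 65535) / 65535)
}

pages_to_stack <- function(pages) {
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
  arr
}

#' Write a simulated population to disk
#'
#' Serializes a [simulate_population()] result: one multi-page 16-bit TIFF
#' per field for the labeled and the matched unlabeled control stacks, an
#' integer-valued mask TIFF, the ground truth as JSON and the configuration
#' as YAML. Photon counts are clipped to the 16-bit range on write.
#'
#' @param pop a `"fros_population"`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_population <- function(pop, dir) {
  if (!inherits(pop, "fros_population")) stop("`pop` must be a fros_population")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_along(pop$fields)) {
    fld <- pop$fields[[f]]
    tiff::writeTIFF(stack_to_pages(fld$labeled),
                    file.path(dir, sprintf("labeled_%03d.tif", f)),
                    bits.per.sample = 16)
    tiff::writeTIFF(stack_to_pages(fld$control),
                    file.path(dir, sprintf("control_%03d.tif", f)),
                    bits.per.sample = 16)
    tiff::writeTIFF(fld$mask / 65535,
                    file.path(dir, sprintf("mask_%03d.tif", f)),
                    bits.per.sample = 16)
  }
  jsonlite::write_json(pop$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  yaml::write_yaml(unclass(pop$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

read_stack_tiff <- function(path) {
  pages_to_stack(tiff::readTIFF(path, all = TRUE, as.is = TRUE))
}

#' Read a population back from disk
#'
#' Inverse of [write_population()]: reconstructs a `"fros_population"` from
#' a directory of TIFF stacks, `truth.json` and `config.yaml`.
#'
#' @param dir directory written by [write_population()]
#' @return a `"fros_population"`
#' @export
read_population <- function(dir) {
  lab_files <- sort(list.files(dir, "^labeled_\\d+\\.tif$", full.names = TRUE))
  if (length(lab_files) == 0) stop("no labeled_*.tif stacks found in ", dir)
  fields <- lapply(seq_along(lab_files), function(f) {
    mask <- tiff::readTIFF(file.path(dir, sprintf("mask_%03d.tif", f)),
                           as.is = TRUE)
    list(labeled = read_stack_tiff(file.path(dir, sprintf("labeled_%03d.tif", f))),
         control = read_stack_tiff(file.path(dir, sprintf("control_%03d.tif", f))),
         mask = matrix(as.integer(mask), nrow(mask), ncol(mask)),
         cell_ids = sort(setdiff(unique(as.integer(mask)), 0L)))
  })
  truth <- as.data.frame(jsonlite::read_json(file.path(dir, "truth.json"),
                                             simplifyVector = TRUE))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$cell_semiaxes_px <- as.numeric(cfg$cell_semiaxes_px)
  config <- do.call(sim_config, cfg)
  structure(list(fields = fields, truth = truth, config = config),
            class = "fros_population")
}
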