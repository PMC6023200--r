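#' Write a field pair as 16-bit grayscale TIFFs
#'
#' Files follow the acquisition naming convention
#' `<plate>_<well>_s<site>_<channel>.tif` with channels `DAPI` (nuclear
#' stain) and `FITC` (reporter). Intensities are rounded to integers and
#' stored on the 16-bit scale.
#'
#' @param field list with `nuclear` and `reporter` matrices.
#' @param dir output directory (created if missing).
#' @param plate plate barcode string.
#' @param well well id (e.g. "A01").
#' @param site site (field) number within the well.
#' @return invisibly, the two file paths written.
#' @export
write_field <- function(field, dir, plate, well, site) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%s_s%d_%s.tif", plate, well,
                                  as.integer(site), c("DAPI", "FITC")))
  for (i in 1:2) {
    m <- if (i == 1) field$nuclear else field$reporter
    m <- pmin(pmax(round(m), 0), 65535)
    EBImage::writeImage(EBImage::Image(m / 65535), paths[i],
                        type = "tiff", bits.per.sample = 16L)
  }
  invisible(paths)
}

#' Read a field pair written by [write_field()]
#'
#' @inheritParams write_field
#' @param dir directory holding the TIFFs.
#' @return list with `nuclear` and `reporter` matrices on the 16-bit
#'   scale, or `NULL` (with a warning) when either channel file is
#'   missing.
#' @export
read_field <- function(dir, plate, well, site) {
  paths <- file.path(dir, sprintf("%s_%s_s%d_%s.tif", plate, well,
                                  as.integer(site), c("DAPI", "FITC")))
  if (!all(file.exists(paths))) {
    warning("missing channel file(s) for ", plate, " ", well, " site ",
            site, "; field skipped")
    return(NULL)
  }
  rd <- function(p) {
    img <- EBImage::readImage(p)
    round(matrix(as.numeric(img), nrow(img), ncol(img)) * 65535)
  }
  list(nuclear = rd(paths[1]), reporter = rd(paths[2]))
}

#' List the fields available in an image directory
#'
#' Parses file names following the `<plate>_<well>_s<site>_<channel>.tif`
#' convention and returns the set of complete (both-channel) fields.
#'
#' @param dir image directory.
#' @return data frame with `plate`, `well`, `site`.
#' @export
list_fields <- function(dir) {
  files <- list.files(dir, pattern = "\\.tif$")
  m <- regmatches(files,
                  regexec("^(.+)_([A-P][0-9]{2})_s([0-9]+)_(DAPI|FITC)\\.tif$",
                          files))
  m <- m[lengths(m) == 5]
  if (!length(m))
    return(data.frame(plate = character(0), well = character(0),
                      site = integer(0)))
  df <- data.frame(plate = vapply(m, `[`, "", 2),
                   well = vapply(m, `[`, "", 3),
                   site = as.integer(vapply(m, `[`, "", 4)),
                   channel = vapply(m, `[`, "", 5))
  agg <- stats::aggregate(channel ~ plate + well + site, df,
                          function(ch) length(unique(ch)))
  out <- agg[agg$channel == 2, c("plate", "well", "site")]
  out <- out[order(out$plate, out$well, out$site), ]
  rownames(out) <- NULL
  incomplete <- agg[agg$channel < 2, c("plate", "well", "site")]
  rownames(incomplete) <- NULL
  attr(out, "incomplete") <- incomplete
  out
}

#' Assemble a run configuration
#'
#' Bundles every tunable of the pipeline - segmentation parameters,
#' aggregation mode, QC gates, hit threshold and seed - with validation.
#' Round-trips losslessly through YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param segmentation a [segmentation_params()].
#' @param well_aggregation `"mean_of_ratios"` or `"ratio_of_means"`.
#' @param min_cells_per_well validity floor for wells.
#' @param cv_limit,zprime_limit plate QC gates.
#' @param hit_threshold NUC/CYT hit cutoff.
#' @param seed integer seed for simulation-driven runs.
#' @return object of class `run_config`.
#' @export
run_config <- function(segmentation = segmentation_params(),
                       well_aggregation = "mean_of_ratios",
                       min_cells_per_well = 50,
                       cv_limit = 20, zprime_limit = 0.5,
                       hit_threshold = 1.3, seed = 1L) {
  stopifnot(cv_limit > 0, zprime_limit > 0, hit_threshold > 0,
            min_cells_per_well >= 1,
            well_aggregation %in% c("mean_of_ratios", "ratio_of_means"))
  structure(list(segmentation = segmentation,
                 well_aggregation = well_aggregation,
                 min_cells_per_well = as.integer(min_cells_per_well),
                 cv_limit = cv_limit, zprime_limit = zprime_limit,
                 hit_threshold = hit_threshold, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$segmentation <- unclass(x$segmentation)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  seg <- do.call(segmentation_params, x$segmentation)
  run_config(segmentation = seg,
             well_aggregation = x$well_aggregation,
             min_cells_per_well = x$min_cells_per_well,
             cv_limit = x$cv_limit, zprime_limit = x$zprime_limit,
             hit_threshold = x$hit_threshold, seed = x$seed)
}
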