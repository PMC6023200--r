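#' Run the full analysis pipeline on a simulated or imaged plate
#'
#' Chains segmentation, per-cell quantification, well aggregation, plate
#' QC and (when the layout carries compound wells with measurements) hit
#' calling. Input is either a [plate_sim_spec()] - fields are generated
#' on the fly, well by well, so whole plates never sit in memory - or a
#' directory of TIFF fields following the [write_field()] naming
#' convention. Identical configuration and seed give identical outputs.
#'
#' Fields with a missing channel file are skipped with a warning (the
#' well's pooled cell count simply drops). A failed QC plate is flagged
#' in the result; its hit table is still computed but marked unreliable
#' via `qc$pass`.
#'
#' @param input a `plate_sim_spec`, or a directory of TIFF images.
#' @param config a [run_config()].
#' @param layout plate layout; defaults to the simulation spec's layout,
#'   and must be given for directory input.
#' @param keep_cells keep the pooled per-cell table in the result.
#' @param out_dir optional directory: per-well CSV, per-cell CSV, hit
#'   CSV, QC JSON and a JSON run manifest are written there.
#' @return list of class `screen_run`: `wells` (per-well data frame),
#'   `qc` (a `plate_qc`), `hits` (a `hit_table` or `NULL`), `cells`
#'   (optional), `field_log` (per-field counts), `manifest`.
#' @export
run_pipeline <- function(input, config = run_config(), layout = NULL,
                         keep_cells = FALSE, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim_mode <- inherits(input, "plate_sim_spec")
  if (sim_mode) {
    layout <- layout %||% input$layout
    plan <- data.frame(well = names(input$ratio_map))
    sites <- seq_len(input$fields_per_well)
  } else {
    if (is.null(layout)) stop("layout is required for directory input")
    fields <- list_fields(input)
    if (!nrow(fields)) stop("no complete field pairs found in ", input)
    inc <- attr(fields, "incomplete")
    if (!is.null(inc) && nrow(inc))
      for (j in seq_len(nrow(inc)))
        warning("missing channel file for ", inc$plate[j], " ",
                inc$well[j], " site ", inc$site[j], "; field skipped",
                call. = FALSE)
    plan <- data.frame(well = unique(fields$well))
  }

  wells_out <- vector("list", nrow(plan))
  cells_out <- if (keep_cells) vector("list", nrow(plan)) else NULL
  log_rows <- list()
  for (i in seq_len(nrow(plan))) {
    w <- plan$well[i]
    if (sim_mode) {
      flds <- generate_well_fields(input, w)
    } else {
      fw <- fields[fields$well == w, , drop = FALSE]
      flds <- lapply(seq_len(nrow(fw)), function(j)
        read_field(input, fw$plate[j], fw$well[j], fw$site[j]))
      flds <- flds[!vapply(flds, is.null, logical(1))]
    }
    per_field <- lapply(seq_along(flds), function(s) {
      masks <- build_masks(flds[[s]], config$segmentation)
      cells <- measure_cells(flds[[s]], masks)
      log_rows[[length(log_rows) + 1L]] <<-
        data.frame(well = w, site = s, n_cells = nrow(cells),
                   n_discarded = attr(cells, "discarded"))
      cells
    })
    wells_out[[i]] <- aggregate_well(per_field,
                                     min_cells_per_well = config$min_cells_per_well,
                                     method = config$well_aggregation,
                                     well = w)
    if (keep_cells) {
      pooled <- do.call(rbind, per_field)
      if (!is.null(pooled) && nrow(pooled))
        cells_out[[i]] <- cbind(well = w, pooled)
    }
  }
  wells <- do.call(rbind, wells_out)
  rownames(wells) <- NULL
  qc <- qc_plate(wells, layout, cv_limit = config$cv_limit,
                 zprime_limit = config$zprime_limit)

  roles <- layout$role[match(wells$well, layout$well)]
  hits <- NULL
  if (any(roles == "compound"))
    hits <- call_hits(wells, layout, hit_threshold = config$hit_threshold)

  manifest <- list(
    package = "nucshift",
    version = as.character(utils::packageVersion("nucshift")),
    config = unclass(write_config_list(config)),
    input = if (sim_mode) list(mode = "simulation",
                               plate = input$plate, seed = input$seed,
                               fields_per_well = input$fields_per_well,
                               field_template = unclass(input$field_template),
                               ratio_map = as.list(input$ratio_map))
            else list(mode = "images", dir = input))

  result <- structure(list(wells = wells, qc = qc, hits = hits,
                           cells = if (keep_cells) do.call(rbind, cells_out),
                           field_log = do.call(rbind, log_rows),
                           manifest = manifest),
                      class = "screen_run")
  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  result
}

# run_config as a plain list for serialisation
write_config_list <- function(config) {
  x <- unclass(config)
  x$segmentation <- unclass(x$segmentation)
  x
}

#' Write the output tables of a pipeline run
#'
#' Emits `wells.csv`, `field_log.csv`, optionally `cells.csv` and
#' `hits.csv`, plus `qc.json` and `manifest.json`.
#'
#' @param result a `screen_run` from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, `out_dir`.
#' @export
write_run_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "screen_run"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write.csv(result$wells, file.path(out_dir, "wells.csv"),
            row.names = FALSE)
  write.csv(result$field_log, file.path(out_dir, "field_log.csv"),
            row.names = FALSE)
  if (!is.null(result$cells))
    write.csv(result$cells, file.path(out_dir, "cells.csv"),
              row.names = FALSE)
  if (!is.null(result$hits))
    write.csv(result$hits$table, file.path(out_dir, "hits.csv"),
              row.names = FALSE)
  qc <- result$qc
  jsonlite::write_json(
    list(zprime = qc$zprime, cv_max = qc$cv_max, cv_min = qc$cv_min,
         cv_test = qc$cv_test, pass = qc$pass,
         mu_max = qc$summary$mu_max, sd_max = qc$summary$sd_max,
         mu_min = qc$summary$mu_min, sd_min = qc$summary$sd_min,
         n_invalid_wells = qc$n_invalid_wells),
    file.path(out_dir, "qc.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.screen_run <- function(x, ...) {
  cat("Screen run:", nrow(x$wells), "wells,",
      sum(x$field_log$n_cells), "cells segmented\n")
  print(x$qc)
  if (!is.null(x$hits))
    cat("  hits:", sum(x$hits$table$is_hit), "of",
        nrow(x$hits$table), "compound wells at threshold",
        x$hits$threshold, "\n")
  invisible(x)
}
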