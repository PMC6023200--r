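#' Standard 384-well screening layout
#'
#' The single-point screening layout: 16 rows (A-P) by 24 columns, with
#' maximal-activation (TNF-alpha) positive controls in columns 1 and 24,
#' vehicle (DMSO) negative controls in columns 2 and 23, and compounds in
#' columns 3-22 (320 wells).
#'
#' @param library library tag assigned to the compound wells.
#' @param compound_prefix prefix for generated compound ids.
#' @return data frame with columns `well`, `row`, `col`, `role`
#'   (`positive_control`, `negative_control`, `compound`), `compound_id`
#'   (NA for controls) and `library`.
#' @export
plate_layout_384 <- function(library = "LIB1", compound_prefix = "CMPD") {
  grid <- expand.grid(row = 1:16, col = 1:24)
  grid <- grid[order(grid$row, grid$col), ]
  role <- ifelse(grid$col %in% c(1, 24), "positive_control",
          ifelse(grid$col %in% c(2, 23), "negative_control", "compound"))
  layout <- data.frame(well = well_name(grid$row, grid$col),
                       row = grid$row, col = grid$col, role = role,
                       compound_id = NA_character_,
                       library = NA_character_,
                       stringsAsFactors = FALSE)
  is_cmpd <- layout$role == "compound"
  layout$compound_id[is_cmpd] <- sprintf("%s-%04d", compound_prefix,
                                         seq_len(sum(is_cmpd)))
  layout$library[is_cmpd] <- library
  rownames(layout) <- NULL
  layout
}

#' Translocation-ratio map for a control/validation plate
#'
#' Assigns the positive-control translocation ratio to the layout's
#' positive-control wells and the baseline ratio to its negative-control
#' wells; compound wells are left unplated. Optionally restricted to a
#' subset of rows for a scaled-down validation plate.
#'
#' @param layout plate layout (see [plate_layout_384()]).
#' @param positive,negative translocation ratios of the control wells.
#' @param rows optional integer vector of row indices (1-16) to include.
#' @return named numeric vector, well id -> translocation ratio.
#' @export
control_ratio_map <- function(layout, positive = 2.5, negative = 1.0,
                              rows = NULL) {
  keep <- layout$role %in% c("positive_control", "negative_control")
  if (!is.null(rows)) keep <- keep & layout$row %in% rows
  ctl <- layout[keep, ]
  setNames(ifelse(ctl$role == "positive_control", positive, negative),
           ctl$well)
}

#' Specification of a simulated plate
#'
#' Couples a plate layout with a per-well translocation-ratio map, a field
#' template, and the acquisition plan (default nine fields per well, the
#' screen's imaging plan). Wells present in the layout but absent from the
#' ratio map are treated as unplated and not simulated.
#'
#' @param layout plate layout data frame.
#' @param ratio_map named numeric vector, well id -> translocation ratio.
#' @param fields_per_well number of fields (sites) imaged per well.
#' @param field_template a [field_spec()] used for every field; its
#'   `translocation_ratio` and `seed` are overridden per well/site.
#' @param plate plate barcode string.
#' @param seed integer master seed; per-field seeds are derived from it.
#' @return object of class `plate_sim_spec`.
#' @export
plate_sim_spec <- function(layout, ratio_map, fields_per_well = 9,
                           field_template = field_spec(),
                           plate = "SIMPLATE001", seed = 1L) {
  stopifnot(fields_per_well >= 1)
  unknown <- setdiff(names(ratio_map), layout$well)
  if (length(unknown))
    stop("wells in translocation map absent from layout: ",
         paste(unknown, collapse = ", "))
  if (length(ratio_map) == 0) stop("ratio_map must name at least one well")
  if (any(ratio_map <= 0)) stop("translocation ratios must be > 0")
  structure(list(layout = layout, ratio_map = ratio_map,
                 fields_per_well = as.integer(fields_per_well),
                 field_template = field_template,
                 plate = plate, seed = as.integer(seed)),
            class = "plate_sim_spec")
}

#' Generate all fields of one simulated well
#'
#' @param spec a [plate_sim_spec()].
#' @param well well id present in the spec's ratio map.
#' @return list of `sim_field` objects, one per site.
#' @export
generate_well_fields <- function(spec, well) {
  stopifnot(inherits(spec, "plate_sim_spec"))
  if (!well %in% names(spec$ratio_map))
    stop("well ", well, " is not plated in this simulation spec")
  well_index <- match(well, spec$layout$well)
  fs <- spec$field_template
  fs$translocation_ratio <- unname(spec$ratio_map[[well]])
  lapply(seq_len(spec$fields_per_well), function(site) {
    fs$seed <- derive_seed(spec$seed, well_index, site)
    generate_field(fs)
  })
}

#' Generate a simulated plate
#'
#' Generates `fields_per_well` field pairs for every plated well. With
#' `out_dir` set, each field pair is written as 16-bit TIFFs (see
#' [write_field()]) and dropped from memory, so whole plates can be
#' simulated without holding all rasters at once; otherwise all fields are
#' returned in memory (intended for small layouts).
#'
#' @param spec a [plate_sim_spec()].
#' @param out_dir optional directory for TIFF output.
#' @return list with `wells` (named list of per-well field lists; `NULL`
#'   per well when `out_dir` is used), `truth` (combined per-cell ground
#'   truth table with `well` and `site` columns) and `spec`.
#' @export
generate_plate <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "plate_sim_spec"))
  wells <- names(spec$ratio_map)
  truths <- list()
  out <- vector("list", length(wells))
  names(out) <- wells
  for (w in wells) {
    fields <- generate_well_fields(spec, w)
    tr <- lapply(seq_along(fields), function(s) {
      tc <- fields[[s]]$truth$cells
      if (nrow(tc)) cbind(well = w, site = s, tc) else NULL
    })
    truths[[w]] <- do.call(rbind, tr)
    if (is.null(out_dir)) {
      out[[w]] <- fields
    } else {
      for (s in seq_along(fields))
        write_field(fields[[s]]$field, out_dir, spec$plate, w, s)
    }
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  list(wells = out, truth = truth, spec = spec)
}
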