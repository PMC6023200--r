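#' Call hits from single-point compound wells
#'
#' A compound is a hit when its well's raw (un-normalised) translocation
#' value meets or exceeds the threshold; the default 1.3 is the screening
#' cutoff on NUC/CYT. The comparison is inclusive, so a value of exactly
#' 1.3 is a hit. Invalid wells (low cell count) are reported separately
#' and are never called hits.
#'
#' @param wells data frame of well measurements with columns `well`,
#'   `translocation_value`, `valid`.
#' @param layout plate layout carrying `role`, `compound_id`, `library`.
#' @param hit_threshold positive NUC/CYT cutoff (default 1.3).
#' @return object of class `hit_table`: list with `table` (per-compound
#'   data frame: `compound_id`, `library`, `well`, `translocation_value`,
#'   `is_hit`), `invalid_wells`, `threshold`.
#' @export
call_hits <- function(wells, layout, hit_threshold = 1.3) {
  stopifnot(hit_threshold > 0)
  m <- match(wells$well, layout$well)
  if (anyNA(m))
    stop("wells not present in layout: ",
         paste(wells$well[is.na(m)], collapse = ", "))
  role <- layout$role[m]
  cmpd <- wells[role == "compound", , drop = FALSE]
  mc <- match(cmpd$well, layout$well)
  tab <- data.frame(compound_id = layout$compound_id[mc],
                    library = layout$library[mc],
                    well = cmpd$well,
                    translocation_value = cmpd$translocation_value,
                    is_hit = cmpd$valid &
                      cmpd$translocation_value >= hit_threshold)
  invalid <- tab$well[!cmpd$valid]
  tab <- tab[cmpd$valid, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, invalid_wells = invalid,
                 threshold = hit_threshold),
            class = "hit_table")
}

#' Tabulate hit rates per library and overall
#'
#' Summarises a hit table (or raw per-library counts) into per-library and
#' overall hit rates; rates are reported rounded to one decimal in percent
#' with the raw rate retained.
#'
#' @param hits a `hit_table` from [call_hits()], or a data frame with
#'   columns `library`, `n_compounds`, `n_hits` (library-level counts,
#'   e.g. from a published screening campaign).
#' @return data frame with `library`, `n_compounds`, `n_hits`,
#'   `hit_rate_raw`, `hit_rate` (one decimal, percent); the final row
#'   (`library == "Total"`) is the overall summary.
#' @export
tabulate_hit_rates <- function(hits) {
  if (inherits(hits, "hit_table")) {
    tab <- hits$table
    libs <- unique(tab$library)
    counts <- data.frame(
      library = libs,
      n_compounds = vapply(libs, function(l) sum(tab$library == l), integer(1)),
      n_hits = vapply(libs, function(l) sum(tab$is_hit[tab$library == l]),
                      integer(1)))
  } else {
    stopifnot(all(c("library", "n_compounds", "n_hits") %in% names(hits)))
    counts <- hits[, c("library", "n_compounds", "n_hits")]
  }
  counts <- rbind(counts,
                  data.frame(library = "Total",
                             n_compounds = sum(counts$n_compounds),
                             n_hits = sum(counts$n_hits)))
  counts$hit_rate_raw <- ifelse(counts$n_compounds > 0,
                                100 * counts$n_hits / counts$n_compounds,
                                NA_real_)
  counts$hit_rate <- round(counts$hit_rate_raw, 1)
  rownames(counts) <- NULL
  counts
}

#' Rank compounds by translocation value
#'
#' Orders compounds descending by NUC/CYT; exact ties are broken by
#' compound id (lexicographic) so the ranking is deterministic.
#'
#' @param hits a `hit_table` from [call_hits()].
#' @return the hit table's data frame reordered, with a `rank` column.
#' @export
rank_compounds <- function(hits) {
  stopifnot(inherits(hits, "hit_table"))
  tab <- hits$table
  ord <- order(-tab$translocation_value, tab$compound_id)
  out <- tab[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
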