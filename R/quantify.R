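#' Measure per-cell reporter intensities over a mask set
#'
#' For every segmented cell, computes the mean reporter intensity over its
#' nucleus pixels and over its cytoplasm pixels, and their ratio NUC/CYT -
#' the translocation statistic. Cells whose cytoplasm mask was fully
#' consumed by neighbour competition (zero area) or whose cytoplasmic mean
#' is zero are dropped and counted in the `discarded` attribute.
#'
#' @param field list with `nuclear` and `reporter` matrices, or a
#'   `sim_field`.
#' @param masks a [build_masks()] result.
#' @return data frame with columns `label`, `nuc_mean`, `cyt_mean`,
#'   `ratio`, `nucleus_area`, `cytoplasm_area`; attribute `discarded`
#'   holds the number of dropped labels.
#' @export
measure_cells <- function(field, masks) {
  if (inherits(field, "sim_field")) field <- field$field
  rep_chan <- field$reporter
  if (!all(dim(rep_chan) == dim(masks$nuclei_labels)))
    stop("mask dimensions do not match the field")
  n <- max(masks$nuclei_labels)
  if (n == 0L) {
    out <- data.frame(label = integer(0), nuc_mean = numeric(0),
                      cyt_mean = numeric(0), ratio = numeric(0),
                      nucleus_area = integer(0), cytoplasm_area = integer(0))
    attr(out, "discarded") <- 0L
    return(out)
  }
  idx_n <- which(masks$nuclei_labels > 0L)
  lab_n <- masks$nuclei_labels[idx_n]
  nuc_area <- tabulate(lab_n, nbins = n)
  nuc_sum <- rep(0, n)
  s <- rowsum(rep_chan[idx_n], lab_n)
  nuc_sum[as.integer(rownames(s))] <- s[, 1]

  idx_c <- which(masks$cytoplasm_labels > 0L)
  lab_c <- masks$cytoplasm_labels[idx_c]
  cyt_area <- tabulate(lab_c, nbins = n)
  cyt_sum <- rep(0, n)
  if (length(idx_c)) {
    s <- rowsum(rep_chan[idx_c], lab_c)
    cyt_sum[as.integer(rownames(s))] <- s[, 1]
  }

  nuc_mean <- nuc_sum / nuc_area
  cyt_mean <- cyt_sum / cyt_area
  keep <- nuc_area > 0L & cyt_area > 0L & cyt_mean > 0
  out <- data.frame(label = seq_len(n), nuc_mean = nuc_mean,
                    cyt_mean = cyt_mean, ratio = nuc_mean / cyt_mean,
                    nucleus_area = nuc_area,
                    cytoplasm_area = cyt_area)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- as.integer(n - sum(keep))
  out
}

#' Aggregate per-cell measurements into a well translocation value
#'
#' Pools the per-cell tables of all fields of one well and summarises them
#' into a single translocation value. The default pools the per-cell
#' NUC/CYT ratios and averages them (`mean_of_ratios`); the alternative
#' ratios the well-level mean intensities (`ratio_of_means`). Wells with
#' fewer than `min_cells_per_well` pooled cells are flagged invalid and
#' carry no value.
#'
#' @param cells a single per-cell data frame or a list of them (one per
#'   field), as returned by [measure_cells()].
#' @param min_cells_per_well minimum pooled cell count for a valid well.
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @param well optional well id carried through to the result.
#' @return one-row data frame with `well`, `translocation_value`,
#'   `n_cells`, `valid`.
#' @export
aggregate_well <- function(cells, min_cells_per_well = 50,
                           method = c("mean_of_ratios", "ratio_of_means"),
                           well = NA_character_) {
  method <- match.arg(method)
  if (is.data.frame(cells)) cells <- list(cells)
  pooled <- do.call(rbind, cells)
  n <- if (is.null(pooled)) 0L else nrow(pooled)
  valid <- n >= min_cells_per_well
  value <- NA_real_
  if (valid) {
    value <- if (method == "mean_of_ratios") mean(pooled$ratio)
             else mean(pooled$nuc_mean) / mean(pooled$cyt_mean)
  }
  data.frame(well = well, translocation_value = value,
             n_cells = as.integer(n), valid = valid)
}
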