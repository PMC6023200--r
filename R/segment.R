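#' Segmentation parameters for the mask pipeline
#'
#' Parameters of the five-step mask pipeline. The intensity band keeps dim
#' but real nuclei while excluding saturated debris and dead cells; the
#' shrink step tightens the nuclear mask; the extend step builds a guard
#' ring so nuclear fluorescence does not bleed into the cytoplasm
#' measurement; and the cell radius - required to be more than three times
#' the extend radius - bounds the whole-cell mask grown from each nucleus.
#'
#' @param threshold_low,threshold_high inclusive intensity band applied to
#'   the nuclear channel.
#' @param shrink_radius disk radius (pixels) by which labelled nuclei are
#'   eroded.
#' @param extend_radius disk radius by which nuclei are dilated to form the
#'   extended-nuclei (guard) mask.
#' @param cell_radius disk radius by which nuclei are dilated to form the
#'   whole-cell mask; must exceed `3 * extend_radius`.
#' @param min_area,max_area inclusive area bounds (pixels^2) for nuclei.
#' @param exclude_border drop nuclei touching the image border.
#' @param auto_threshold if `TRUE`, replace `threshold_low` with an Otsu
#'   threshold computed on the nuclear channel (the high bound stays
#'   fixed). Off by default for reproducibility.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_low = 1000, threshold_high = 60000,
                                shrink_radius = 2, extend_radius = 2,
                                cell_radius = 8, min_area = 20,
                                max_area = 500, exclude_border = TRUE,
                                auto_threshold = FALSE) {
  p <- list(threshold_low = threshold_low, threshold_high = threshold_high,
            shrink_radius = shrink_radius, extend_radius = extend_radius,
            cell_radius = cell_radius, min_area = min_area,
            max_area = max_area, exclude_border = isTRUE(exclude_border),
            auto_threshold = isTRUE(auto_threshold))
  if (p$threshold_low >= p$threshold_high)
    stop("threshold_low must be < threshold_high")
  if (p$shrink_radius < 0 || p$extend_radius < 0)
    stop("radii must be >= 0")
  if (p$cell_radius <= 3 * p$extend_radius)
    stop("cell_radius must exceed 3 * extend_radius")
  if (!(p$min_area > 0 && p$min_area < p$max_area))
    stop("need 0 < min_area < max_area")
  class(p) <- "segmentation_params"
  p
}

#' Band-threshold the nuclear channel
#'
#' Marks a pixel foreground iff `threshold_low <= intensity <=
#' threshold_high` (both bounds inclusive). The band keeps dim nuclei that
#' still stand out from background while rejecting very bright objects
#' (dead cells, mitotic figures, debris).
#'
#' @param nuclear_channel intensity matrix.
#' @param threshold_low,threshold_high inclusive band.
#' @return integer 0/1 matrix.
#' @export
threshold_nuclei <- function(nuclear_channel, threshold_low, threshold_high) {
  if (threshold_low >= threshold_high)
    stop("threshold_low must be < threshold_high")
  m <- (nuclear_channel >= threshold_low) & (nuclear_channel <= threshold_high)
  storage.mode(m) <- "integer"
  m
}

#' Fill holes in a binary mask
#'
#' Background components not 4-connected to the image border are converted
#' to foreground, so uneven staining inside a nucleus does not punch holes
#' in its mask. Foreground never shrinks.
#'
#' @param mask integer/logical 0-1 matrix.
#' @return integer 0/1 matrix.
#' @export
fill_holes <- function(mask) {
  m <- mask
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("fill_holes expects a binary mask")
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  # flood the border-connected background (4-connected); what remains 0 is
  # a hole
  flood <- EBImage::floodFill(pad, c(1L, 1L), col = 2L)
  flood <- flood[2:(h + 1L), 2:(w + 1L)]
  out <- m
  out[flood != 2L] <- 1L
  out
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so
# labels that touch diagonally are merged with a union-find pass
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1])))  # up-right
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# bounding box of a label's pixels, padded and clamped to the raster
label_bbox <- function(idx, h, w, pad) {
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  list(r0 = max(1L, min(rows) - pad), r1 = min(h, max(rows) + pad),
       c0 = max(1L, min(cols) - pad), c1 = min(w, max(cols) + pad),
       rows = rows, cols = cols)
}

#' Label connected nuclei and shrink each by a disk
#'
#' Connected foreground components (8-connected) are labelled, then each
#' object is independently eroded by a disk of `shrink_radius`. Objects
#' erased entirely by the erosion are dropped and surviving labels are
#' renumbered consecutively. Touching nuclei stay merged as one object; no
#' watershed split is attempted.
#'
#' @param filled_mask binary matrix (typically from [fill_holes()]).
#' @param shrink_radius non-negative disk radius in pixels.
#' @return integer label matrix (0 = background).
#' @export
label_and_shrink <- function(filled_mask, shrink_radius) {
  stopifnot(shrink_radius >= 0)
  lab <- label_components(filled_mask)
  if (shrink_radius == 0 || max(lab) == 0L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  r <- as.integer(round(shrink_radius))
  kern <- disk_kernel(r)
  out <- matrix(0L, h, w)
  next_label <- 0L
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    bb <- label_bbox(idx, h, w, pad = r)
    crop <- (lab[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE] == k)
    storage.mode(crop) <- "integer"
    # pad so pixels at the raster border erode against outside background
    ch <- nrow(crop); cw <- ncol(crop)
    padc <- matrix(0L, ch + 2L * r, cw + 2L * r)
    padc[(r + 1):(r + ch), (r + 1):(r + cw)] <- crop
    er <- EBImage::erode(padc, kern)
    er <- matrix(as.integer(er), nrow(padc), ncol(padc))[(r + 1):(r + ch),
                                                         (r + 1):(r + cw),
                                                         drop = FALSE]
    if (!any(er > 0L)) next
    next_label <- next_label + 1L
    sub <- out[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE]
    sub[er > 0L] <- next_label
    out[bb$r0:bb$r1, bb$c0:bb$c1] <- sub
  }
  out
}

#' Filter labelled objects by area and border contact
#'
#' Removes objects whose area falls outside the inclusive `[min_area,
#' max_area]` band and, optionally, objects touching the outermost
#' row/column of the raster. Survivors are renumbered consecutively from 1
#' in order of their original labels.
#'
#' @param labels integer label matrix.
#' @param min_area,max_area inclusive area bounds in pixels^2.
#' @param exclude_border drop objects with any border pixel.
#' @return integer label matrix.
#' @export
filter_objects <- function(labels, min_area, max_area, exclude_border = TRUE) {
  if (!(min_area > 0 && min_area < max_area))
    stop("need 0 < min_area < max_area")
  n <- max(labels)
  if (n == 0L) return(labels)
  area <- tabulate(labels[labels > 0L], nbins = n)
  keep <- area >= min_area & area <= max_area
  if (exclude_border) {
    h <- nrow(labels); w <- ncol(labels)
    border <- unique(c(labels[1, ], labels[h, ], labels[, 1], labels[, w]))
    keep[border[border > 0L]] <- FALSE
  }
  relab <- integer(n)
  relab[keep] <- seq_len(sum(keep))
  out <- labels
  out[labels > 0L] <- relab[labels[labels > 0L]]
  out
}

#' Build the full mask set for a field
#'
#' Runs the five-step pipeline on the nuclear channel: band threshold,
#' hole filling, labelling with per-object shrink, area/border filtering,
#' then derives the extended-nuclei mask (nuclei dilated by
#' `extend_radius`), the whole-cell mask (nuclei dilated by `cell_radius`)
#' and the cytoplasm mask (whole cell minus extended nuclei). Where the
#' dilations of distinct cells collide, each contested pixel is assigned
#' to the cell whose nucleus centroid is nearest (Euclidean; lower label
#' wins exact ties), and nucleus pixels always retain their own label, so
#' for every cell nucleus <= extended <= whole cell.
#'
#' @param field list with `nuclear` and `reporter` matrices (a
#'   `FieldImagePair`), or a `sim_field` object.
#' @param params a [segmentation_params()].
#' @return object of class `mask_set`: list with `filled_mask`,
#'   `nuclei_labels`, `extended_nuclei_labels`, `whole_cell_labels`,
#'   `cytoplasm_labels`.
#' @export
build_masks <- function(field, params = segmentation_params()) {
  if (inherits(field, "sim_field")) field <- field$field
  stopifnot(inherits(params, "segmentation_params"))
  nuc <- field$nuclear
  lo <- params$threshold_low
  if (params$auto_threshold)
    lo <- EBImage::otsu(EBImage::Image(nuc / 65535), range = c(0, 1)) * 65535
  thr <- threshold_nuclei(nuc, lo, params$threshold_high)
  filled <- fill_holes(thr)
  nuclei <- label_and_shrink(filled, params$shrink_radius)
  nuclei <- filter_objects(nuclei, params$min_area, params$max_area,
                           params$exclude_border)
  n <- max(nuclei)
  h <- nrow(nuclei); w <- ncol(nuclei)
  empty <- matrix(0L, h, w)
  if (n == 0L)
    return(structure(list(filled_mask = filled, nuclei_labels = nuclei,
                          extended_nuclei_labels = empty,
                          whole_cell_labels = empty,
                          cytoplasm_labels = empty),
                     class = "mask_set"))

  r_cell <- as.integer(round(params$cell_radius))
  r_ext <- as.integer(round(params$extend_radius))

  whole <- empty
  best <- matrix(Inf, h, w)
  crops <- vector("list", n)   # per-label distance crops, reused for extend
  for (k in seq_len(n)) {
    idx <- which(nuclei == k)
    bb <- label_bbox(idx, h, w, pad = r_cell)
    crop_mask <- (nuclei[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE] == k)
    inv <- 1L - crop_mask
    storage.mode(inv) <- "integer"
    d <- EBImage::distmap(inv)        # distance to nearest pixel of cell k
    d <- matrix(as.numeric(d), nrow(inv), ncol(inv))
    cy <- mean(bb$rows); cx <- mean(bb$cols)
    crops[[k]] <- list(bb = bb, d = d)
    cand <- which(d <= r_cell)
    if (!length(cand)) next
    rows <- ((cand - 1L) %% nrow(d)) + bb$r0
    cols <- ((cand - 1L) %/% nrow(d)) + bb$c0
    gidx <- rows + (cols - 1L) * h
    cd <- (rows - cy)^2 + (cols - cx)^2
    take <- cd < best[gidx]
    gi <- gidx[take]
    whole[gi] <- k
    best[gi] <- cd[take]
  }
  # nucleus pixels always keep their own label
  own <- which(nuclei > 0L)
  whole[own] <- nuclei[own]

  # guard ring: any pixel within extend_radius of any nucleus is excluded
  # from cytoplasm; it is labelled with its whole-cell owner so per-cell
  # nesting (nucleus <= extended <= whole cell) is preserved
  ext <- empty
  for (k in seq_len(n)) {
    bb <- crops[[k]]$bb; d <- crops[[k]]$d
    cand <- which(d <= r_ext)
    if (!length(cand)) next
    rows <- ((cand - 1L) %% nrow(d)) + bb$r0
    cols <- ((cand - 1L) %/% nrow(d)) + bb$c0
    gidx <- rows + (cols - 1L) * h
    ext[gidx] <- whole[gidx]
  }

  cyt <- whole
  cyt[ext > 0L] <- 0L

  structure(list(filled_mask = filled, nuclei_labels = nuclei,
                 extended_nuclei_labels = ext, whole_cell_labels = whole,
                 cytoplasm_labels = cyt),
            class = "mask_set")
}
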