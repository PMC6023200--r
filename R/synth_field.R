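#' Specification of a synthetic two-channel field
#'
#' Describes one simulated microscopy field: an adherent monolayer of cells
#' with elliptical nuclei in the nuclear-stain channel and a reporter channel
#' whose intensity is split between nucleus and cytoplasm according to a
#' translocation ratio. The defaults emulate a 20X field of a confluent
#' endothelial monolayer in a 384-well screen: roughly 60 cells per
#' 256 x 256 field, 6-pixel nuclei with a 6-pixel cytoplasmic annulus,
#' 16-bit intensity scale with background 500, nuclear-stain peak 10000 and
#' occasional saturated debris.
#'
#' @param width,height field dimensions in pixels.
#' @param n_cells number of cells to place.
#' @param nucleus_radius_mean,nucleus_radius_sd mean/SD of the nuclear
#'   semi-axes in pixels (each axis drawn independently, truncated at 2).
#' @param cytoplasm_extent width in pixels of the cytoplasmic annulus
#'   surrounding each nucleus.
#' @param translocation_ratio target ratio of mean nuclear to mean
#'   cytoplasmic reporter intensity; 1 means no translocation.
#' @param background_level background intensity added to both channels.
#' @param noise_sd standard deviation of additive Gaussian read-out noise
#'   (intensity units; applied to both channels).
#' @param nuclear_peak nuclear-stain intensity of a nucleus (jittered by a
#'   few percent per cell).
#' @param reporter_cyt_mean cytoplasmic reporter intensity; the nuclear
#'   reporter intensity is `translocation_ratio * reporter_cyt_mean`.
#' @param debris_rate expected number of small saturated debris blobs per
#'   field (Poisson), rendered into the nuclear channel at sensor maximum.
#' @param clumping degree of cell aggregation in `[0, 1]`: 0 places cells
#'   with a minimum-separation constraint, 1 allows dense piling around
#'   cluster seeds.
#' @param margin minimum distance of cell centres from the field border,
#'   in pixels.
#' @param min_separation minimum centre-to-centre distance in pixels;
#'   `NULL` (default) uses `2 * nucleus_radius_mean * (1 - clumping)`.
#' @param seed integer seed; a fixed seed gives bit-identical fields.
#' @return an object of class `field_spec` (a validated list).
#' @export
field_spec <- function(width = 256, height = 256, n_cells = 60,
                       nucleus_radius_mean = 6, nucleus_radius_sd = 1,
                       cytoplasm_extent = 6, translocation_ratio = 1,
                       background_level = 500, noise_sd = 100,
                       nuclear_peak = 10000, reporter_cyt_mean = 2000,
                       debris_rate = 0.5, clumping = 0, margin = 2,
                       min_separation = NULL, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_cells = as.integer(n_cells),
               nucleus_radius_mean = nucleus_radius_mean,
               nucleus_radius_sd = nucleus_radius_sd,
               cytoplasm_extent = cytoplasm_extent,
               translocation_ratio = translocation_ratio,
               background_level = background_level, noise_sd = noise_sd,
               nuclear_peak = nuclear_peak,
               reporter_cyt_mean = reporter_cyt_mean,
               debris_rate = debris_rate, clumping = clumping,
               margin = margin, min_separation = min_separation,
               seed = as.integer(seed))
  if (spec$width <= 0 || spec$height <= 0)
    stop("field dimensions must be positive")
  if (spec$n_cells < 0) stop("n_cells must be >= 0")
  if (spec$translocation_ratio <= 0) stop("translocation_ratio must be > 0")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$nucleus_radius_mean <= 0 || spec$nucleus_radius_sd < 0)
    stop("nucleus radius parameters must be positive")
  if (spec$clumping < 0 || spec$clumping > 1)
    stop("clumping must be in [0, 1]")
  class(spec) <- "field_spec"
  spec
}

# sample cell centres; uniform placement with a minimum-separation
# constraint that relaxes as clumping grows, plus Gaussian cluster
# attraction for clumping > 0
place_centers <- function(spec) {
  n <- spec$n_cells
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  min_sep <- spec$min_separation %||%
    (2 * spec$nucleus_radius_mean * (1 - spec$clumping))
  mg <- max(2, spec$margin)
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  tries <- 0L; max_tries <- 200L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("placement failure: could not place ", n, " cells in a ",
           spec$width, "x", spec$height, " field without total overlap")
    if (placed > 0 && spec$clumping > 0 && runif(1) < spec$clumping) {
      anchor <- sample.int(placed, 1)
      x <- rnorm(1, xs[anchor], 2 * spec$nucleus_radius_mean)
      y <- rnorm(1, ys[anchor], 2 * spec$nucleus_radius_mean)
    } else {
      x <- runif(1, mg, spec$width - mg + 1)
      y <- runif(1, mg, spec$height - mg + 1)
    }
    if (x < mg || x > spec$width - mg + 1 ||
        y < mg || y > spec$height - mg + 1) next
    if (min_sep > 0 && placed > 0) {
      d2 <- (xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
  }
  cbind(x = xs, y = ys)
}

# paint ellipse pixels (centre cx,cy, semi-axes a,b) of value `label` into
# an integer ownership raster; returns the raster
paint_ellipse <- function(owner, cx, cy, a, b, label) {
  h <- nrow(owner); w <- ncol(owner)
  r0 <- max(1L, floor(cy - b)); r1 <- min(h, ceiling(cy + b))
  c0 <- max(1L, floor(cx - a)); c1 <- min(w, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) return(owner)
  rows <- r0:r1; cols <- c0:c1
  inside <- outer(((rows - cy) / b)^2, ((cols - cx) / a)^2, "+") <= 1
  sub <- owner[rows, cols, drop = FALSE]
  sub[inside] <- label
  owner[rows, cols] <- sub
  owner
}

#' Generate one synthetic two-channel field with ground truth
#'
#' Renders a field according to a [field_spec()]. Cytoplasmic annuli are
#' painted first and nuclei on top (nuclei of crowded cells may cover a
#' neighbour's cytoplasm, as in a real monolayer). The reporter channel is
#' piecewise constant before noise - cytoplasm at `reporter_cyt_mean`,
#' nucleus at `translocation_ratio * reporter_cyt_mean` - so that the
#' nuclear/cytoplasmic mean ratio over the true masks equals
#' `translocation_ratio` exactly in the noiseless case. Debris is rendered
#' as small blobs at the sensor maximum (65535) in the nuclear channel.
#'
#' @param spec a [field_spec()].
#' @return a list of class `sim_field` with elements
#'   * `field`: list with `nuclear` and `reporter` intensity matrices
#'     (rows = y, columns = x; doubles on the 16-bit scale, clipped to
#'     `[0, 65535]`),
#'   * `truth`: list with `cells` (data frame: cell, x, y, nucleus_area,
#'     cytoplasm_area, nuc_mean_true, cyt_mean_true, ratio_true),
#'     `debris` (data frame: x, y, radius), and the ground-truth ownership
#'     rasters `nucleus_labels` and `cytoplasm_labels`.
#' @export
generate_field <- function(spec) {
  if (!inherits(spec, "field_spec")) spec <- do.call(field_spec, spec)
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    centers <- place_centers(spec)
    n <- nrow(centers)
    a <- pmax(2, rnorm(n, spec$nucleus_radius_mean, spec$nucleus_radius_sd))
    b <- pmax(2, rnorm(n, spec$nucleus_radius_mean, spec$nucleus_radius_sd))
    peak_jitter <- exp(rnorm(n, 0, 0.05))

    nuc_owner <- matrix(0L, h, w)
    cyt_owner <- matrix(0L, h, w)
    ext <- spec$cytoplasm_extent
    for (i in seq_len(n))
      cyt_owner <- paint_ellipse(cyt_owner, centers[i, "x"], centers[i, "y"],
                                 a[i] + ext, b[i] + ext, i)
    for (i in seq_len(n))
      nuc_owner <- paint_ellipse(nuc_owner, centers[i, "x"], centers[i, "y"],
                                 a[i], b[i], i)
    cyt_owner[nuc_owner > 0L] <- 0L

    nuclear <- matrix(spec$background_level, h, w)
    reporter <- matrix(spec$background_level, h, w)
    idx_c <- which(cyt_owner > 0L)
    idx_n <- which(nuc_owner > 0L)
    reporter[idx_c] <- spec$reporter_cyt_mean
    reporter[idx_n] <- spec$reporter_cyt_mean * spec$translocation_ratio
    nuclear[idx_n] <- spec$nuclear_peak * peak_jitter[nuc_owner[idx_n]]

    n_debris <- rpois(1, spec$debris_rate)
    debris <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0))
    if (n_debris > 0) {
      debris <- data.frame(x = runif(n_debris, 2, w - 1),
                           y = runif(n_debris, 2, h - 1),
                           radius = runif(n_debris, 1.5, 3.5))
      deb_owner <- matrix(0L, h, w)
      for (i in seq_len(n_debris))
        deb_owner <- paint_ellipse(deb_owner, debris$x[i], debris$y[i],
                                   debris$radius[i], debris$radius[i], i)
      nuclear[deb_owner > 0L] <- 65535
    }

    # per-cell truths measured over the ownership masks, before noise
    nuc_area <- tabulate(nuc_owner[idx_n], nbins = max(n, 1L))
    cyt_area <- tabulate(cyt_owner[idx_c], nbins = max(n, 1L))
    nuc_mean <- cyt_mean <- rep(NA_real_, n)
    if (n > 0) {
      s <- rowsum(reporter[idx_n], nuc_owner[idx_n])
      nuc_mean[as.integer(rownames(s))] <- s[, 1] / nuc_area[as.integer(rownames(s))]
      if (length(idx_c)) {
        s <- rowsum(reporter[idx_c], cyt_owner[idx_c])
        cyt_mean[as.integer(rownames(s))] <- s[, 1] / cyt_area[as.integer(rownames(s))]
      }
    }
    cells <- data.frame(cell = seq_len(n),
                        x = centers[, "x"], y = centers[, "y"],
                        nucleus_area = if (n) nuc_area else integer(0),
                        cytoplasm_area = if (n) cyt_area else integer(0),
                        nuc_mean_true = nuc_mean, cyt_mean_true = cyt_mean,
                        ratio_true = nuc_mean / cyt_mean)

    if (spec$noise_sd > 0) {
      nuclear <- nuclear + rnorm(h * w, 0, spec$noise_sd)
      reporter <- reporter + rnorm(h * w, 0, spec$noise_sd)
    }
    nuclear <- pmin(pmax(nuclear, 0), 65535)
    reporter <- pmin(pmax(reporter, 0), 65535)
    dim(nuclear) <- dim(reporter) <- c(h, w)

    structure(list(field = list(nuclear = nuclear, reporter = reporter),
                   truth = list(cells = cells, debris = debris,
                                nucleus_labels = nuc_owner,
                                cytoplasm_labels = cyt_owner),
                   spec = spec),
              class = "sim_field")
  })
}

#' Generate a synthetic dose-response series
#'
#' Draws responses from a four-parameter logistic curve
#' `bottom + (top - bottom) / (1 + (ec50 / dose)^hill)` plus Gaussian noise;
#' the standard fixture for exercising [fit_4pl()].
#'
#' @param ec50 curve midpoint (same concentration units as `doses`).
#' @param hill Hill slope.
#' @param top,bottom upper/lower asymptotes (response units).
#' @param doses strictly positive concentrations.
#' @param noise_sd SD of additive Gaussian noise on the response.
#' @param replicates number of replicate responses per dose.
#' @param seed integer seed.
#' @return data frame with columns `dose`, `response`, `replicate`.
#' @export
generate_dose_series <- function(ec50, hill = 1, top = 100, bottom = 0,
                                 doses = dose_series_3fold(),
                                 noise_sd = 0, replicates = 1, seed = 1L) {
  if (length(doses) == 0) stop("dose list must not be empty")
  if (any(doses <= 0)) stop("doses must be strictly positive")
  if (ec50 <= 0) stop("ec50 must be > 0")
  with_seed(seed, {
    d <- rep(doses, times = replicates)
    rep_idx <- rep(seq_len(replicates), each = length(doses))
    y <- four_pl(d, bottom, top, ec50, hill)
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    data.frame(dose = d, response = y, replicate = rep_idx)
  })
}

#' Ten-point three-fold serial dilution
#'
#' The standard dose ladder of the confirmation assays: `n` three-fold
#' dilutions descending from `top_dose`.
#'
#' @param top_dose highest concentration (default 100, e.g. micromolar).
#' @param n number of points (default 10).
#' @param fold dilution factor (default 3).
#' @return numeric vector of doses, descending.
#' @export
dose_series_3fold <- function(top_dose = 100, n = 10, fold = 3) {
  top_dose / fold^(seq_len(n) - 1)
}

#' Ground-truth masks of a simulated field as a mask set
#'
#' Packages the generator's per-cell ownership rasters in the same
#' structure returned by [build_masks()], so [measure_cells()] can
#' quantify over the true masks. In the noiseless case this recovers the
#' generating translocation ratio exactly.
#'
#' @param sim a `sim_field` from [generate_field()].
#' @return object of class `mask_set` (extended-nuclei mask equal to the
#'   true nucleus mask; whole cell = nucleus plus cytoplasm annulus).
#' @export
truth_masks <- function(sim) {
  stopifnot(inherits(sim, "sim_field"))
  nuc <- sim$truth$nucleus_labels
  cyt <- sim$truth$cytoplasm_labels
  whole <- nuc
  whole[cyt > 0L] <- cyt[cyt > 0L]
  filled <- (nuc > 0L); storage.mode(filled) <- "integer"
  structure(list(filled_mask = filled, nuclei_labels = nuc,
                 extended_nuclei_labels = nuc, whole_cell_labels = whole,
                 cytoplasm_labels = cyt),
            class = "mask_set")
}
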