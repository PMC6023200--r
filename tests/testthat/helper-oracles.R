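# Brute-force oracles used to validate the morphology and measurement
# code paths. Deliberately naive (nested loops, O(n * kernel)) and
# independent of the package implementation; only run on small rasters.

# dilation/erosion of a binary matrix by a disk of radius r, pixels
# outside the raster counting as background
brute_dilate <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  for (i in 1:h) for (j in 1:w) {
    hit <- FALSE
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 > r^2) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && m[ii, jj] > 0) hit <- TRUE
    }
    if (hit) out[i, j] <- 1L
  }
  out
}

brute_erode <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  for (i in 1:h) for (j in 1:w) {
    ok <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 > r^2) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > h || jj < 1 || jj > w || m[ii, jj] == 0) ok <- FALSE
    }
    if (ok) out[i, j] <- 1L
  }
  out
}

# hole filling by breadth-first flood from the border over 4-connected
# background; anything unreached becomes foreground
brute_fill_holes <- function(m) {
  h <- nrow(m); w <- ncol(m)
  reached <- matrix(FALSE, h, w)
  queue <- list()
  for (i in 1:h) for (j in 1:w)
    if ((i == 1 || i == h || j == 1 || j == w) && m[i, j] == 0)
      queue[[length(queue) + 1]] <- c(i, j)
  for (q in queue) reached[q[1], q[2]] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue[[1]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- p[1] + d[1]; jj <- p[2] + d[2]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
          m[ii, jj] == 0 && !reached[ii, jj]) {
        reached[ii, jj] <- TRUE
        queue[[length(queue) + 1]] <- c(ii, jj)
      }
    }
  }
  out <- m
  out[!reached & m == 0] <- 1L
  out
}

# per-label mean intensity by naive per-pixel accumulation
brute_label_means <- function(intensity, labels) {
  n <- max(labels)
  sums <- rep(0, n); counts <- rep(0L, n)
  for (i in seq_len(nrow(labels))) for (j in seq_len(ncol(labels))) {
    k <- labels[i, j]
    if (k > 0) { sums[k] <- sums[k] + intensity[i, j]; counts[k] <- counts[k] + 1L }
  }
  ifelse(counts > 0, sums / counts, NA_real_)
}

# Kruskal-Wallis H with tie correction, straight from the rank formula
brute_kw_H <- function(groups) {
  values <- unlist(groups)
  N <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# a random binary blob mask for property tests
random_mask <- function(h, w, p = 0.35, seed = 1) {
  set.seed(seed)
  matrix(as.integer(runif(h * w) < p), h, w)
}

# a small noiseless field with well-separated interior cells: wide margin
# and enforced separation so no nucleus touches the border or a neighbour
isolated_field <- function(n_cells = 6, ratio = 2, seed = 11, noise_sd = 0,
                           width = 160, height = 160) {
  generate_field(field_spec(width = width, height = height,
                            n_cells = n_cells, translocation_ratio = ratio,
                            nucleus_radius_sd = 0.5,
                            noise_sd = noise_sd, debris_rate = 0,
                            margin = 24, min_separation = 34,
                            seed = seed))
}
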