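test_that("band threshold is inclusive on both ends and rejects bad bands", {
  img <- matrix(c(500, 1000, 30000, 60000, 60001, 65535), 2, 3)
  m <- threshold_nuclei(img, 1000, 60000)
  expect_equal(as.vector(m), c(0L, 1L, 1L, 1L, 0L, 0L))
  expect_true(all(threshold_nuclei(img, 0, 65535) == 1L))
  expect_true(all(threshold_nuclei(matrix(500, 4, 4), 1000, 60000) == 0L))
  expect_error(threshold_nuclei(img, 10, 10), "threshold_low")
})

test_that("threshold band separates nuclei from saturated debris", {
  f <- generate_field(field_spec(n_cells = 5, noise_sd = 0, debris_rate = 6,
                                 width = 128, height = 128, seed = 14))
  m <- threshold_nuclei(f$field$nuclear, 1000, 60000)
  # every nucleus pixel not covered by debris is kept
  nuc_px <- f$truth$nucleus_labels > 0 & f$field$nuclear < 60000
  expect_true(all(m[nuc_px] == 1L))
  # debris pixels are saturated and excluded
  expect_true(all(m[f$field$nuclear == 65535] == 0L))
})

test_that("hole filling matches a border flood-fill oracle and never shrinks", {
  # annulus becomes a solid disk; a solid disk is unchanged
  a <- matrix(0L, 15, 15)
  for (i in 1:15) for (j in 1:15) {
    d <- sqrt((i - 8)^2 + (j - 8)^2)
    if (d <= 6) a[i, j] <- 1L
  }
  expect_identical(fill_holes(a), a)
  ann <- a
  for (i in 1:15) for (j in 1:15)
    if (sqrt((i - 8)^2 + (j - 8)^2) <= 3) ann[i, j] <- 0L
  expect_identical(fill_holes(ann), a)

  for (s in 1:8) {
    m <- random_mask(24, 24, p = 0.45, seed = s)
    filled <- fill_holes(m)
    expect_identical(filled, brute_fill_holes(m))
    expect_true(all(filled >= m))
  }
})

test_that("label_and_shrink matches per-object erosion oracle", {
  # disk of radius 5 shrunk by 2 stays one label of roughly radius 3
  disk <- matrix(0L, 21, 21)
  for (i in 1:21) for (j in 1:21)
    if ((i - 11)^2 + (j - 11)^2 <= 25) disk[i, j] <- 1L
  lab <- label_and_shrink(disk, 2)
  expect_equal(max(lab), 1)
  expect_identical(unname(lab > 0) * 1L, unname(brute_erode(disk, 2)))

  # shrink 0 is plain labelling; diagonal touch merges (8-connected)
  m <- matrix(0L, 6, 6); m[2, 2] <- 1L; m[3, 3] <- 1L; m[5, 5] <- 1L
  lab <- label_and_shrink(m, 0)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])

  # objects fully erased by the erosion are dropped, survivors renumbered
  m <- matrix(0L, 20, 20)
  m[3:4, 3:4] <- 1L                     # too small to survive r=2
  for (i in 8:18) for (j in 8:18)
    if ((i - 13)^2 + (j - 13)^2 <= 16) m[i, j] <- 1L
  lab <- label_and_shrink(m, 2)
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L))
  expect_true(all(lab[3:4, 3:4] == 0L))

  # random masks against the oracle, object by object
  for (s in 1:4) {
    m <- random_mask(30, 30, p = 0.4, seed = s + 50)
    lab0 <- label_and_shrink(m, 0)
    got <- label_and_shrink(m, 1)
    expected <- matrix(0L, 30, 30)
    nxt <- 0L
    for (k in seq_len(max(lab0))) {
      er <- brute_erode((lab0 == k) * 1L, 1)
      if (any(er > 0)) { nxt <- nxt + 1L; expected[er > 0] <- nxt }
    }
    expect_identical(got, expected)
  }
})

test_that("object filtering applies inclusive area bounds and border rule", {
  lab <- matrix(0L, 10, 10)
  lab[2:3, 2:3] <- 1L      # area 4
  lab[6:8, 6:8] <- 2L      # area 9
  lab[1, 10] <- 3L         # corner pixel
  out <- filter_objects(lab, min_area = 4, max_area = 8,
                        exclude_border = TRUE)
  expect_equal(sort(unique(as.vector(out))), c(0L, 1L))
  expect_true(all(out[2:3, 2:3] == 1L))   # area exactly min_area retained
  expect_equal(out[1, 10], 0L)            # border object removed
  expect_equal(out[7, 7], 0L)             # above max_area removed

  # brute-force area census agreement on random label fields
  for (s in 1:5) {
    m <- random_mask(32, 32, p = 0.35, seed = s + 100)
    lab <- label_and_shrink(m, 0)
    out <- filter_objects(lab, 3, 40, exclude_border = TRUE)
    survivors_in <- sort(unique(lab[out > 0]))
    area <- tabulate(lab[lab > 0], nbins = max(lab))
    border <- unique(c(lab[1, ], lab[32, ], lab[, 1], lab[, 32]))
    expected <- which(area >= 3 & area <= 40 &
                        !(seq_len(max(lab)) %in% border))
    expect_equal(survivors_in, expected)
    # renumbering is consecutive from 1
    if (length(expected))
      expect_equal(sort(unique(as.vector(out[out > 0]))),
                   seq_along(expected))
  }
  expect_error(filter_objects(lab, 0, 10), "min_area")
})

test_that("mask-set geometry is correct for an isolated cell", {
  f <- generate_field(field_spec(width = 96, height = 96, n_cells = 1,
                                 noise_sd = 0, debris_rate = 0,
                                 translocation_ratio = 2, seed = 8))
  p <- segmentation_params()
  m <- build_masks(f, p)
  expect_equal(max(m$nuclei_labels), 1)
  # cytoplasm is an annulus disjoint from the extended nucleus
  expect_true(all(m$cytoplasm_labels[m$extended_nuclei_labels > 0] == 0L))
  expect_gt(sum(m$cytoplasm_labels == 1), 0)
  # ring width: cell_radius - extend_radius from the nucleus boundary
  d_ext <- max(EBImage::distmap(1L - (m$nuclei_labels > 0) * 1L) *
                 (m$extended_nuclei_labels > 0))
  d_cell <- max(EBImage::distmap(1L - (m$nuclei_labels > 0) * 1L) *
                  (m$whole_cell_labels > 0))
  expect_lte(d_ext, p$extend_radius)
  expect_lte(d_cell, p$cell_radius)
  expect_gt(d_cell, p$cell_radius - 1.5)
})

test_that("mask-set invariants hold across random generated fields", {
  set.seed(101)
  for (s in 1:30) {
    f <- generate_field(field_spec(width = 96, height = 96,
                                   n_cells = sample(3:10, 1),
                                   clumping = runif(1, 0, 0.5),
                                   noise_sd = 80, debris_rate = 0.5,
                                   translocation_ratio = runif(1, 1, 3),
                                   seed = s))
    m <- build_masks(f)
    n <- max(m$nuclei_labels)
    labs <- function(x) setdiff(unique(as.vector(x)), 0L)
    expect_true(all(labs(m$extended_nuclei_labels) %in% seq_len(n)))
    expect_true(all(labs(m$whole_cell_labels) %in% seq_len(n)))
    expect_true(all(labs(m$cytoplasm_labels) %in% seq_len(n)))
    # nucleus pixels keep their label in extended and whole-cell masks
    nz <- m$nuclei_labels > 0
    expect_true(all(m$extended_nuclei_labels[nz] == m$nuclei_labels[nz]))
    expect_true(all(m$whole_cell_labels[nz] == m$nuclei_labels[nz]))
    # cytoplasm and extended nuclei are disjoint
    expect_true(all(m$cytoplasm_labels[m$extended_nuclei_labels > 0] == 0L))
    # cytoplasm + extended partition the whole-cell mask
    covered <- (m$cytoplasm_labels > 0) | (m$extended_nuclei_labels > 0)
    expect_true(all(covered[m$whole_cell_labels > 0]))
  }
})

test_that("segmentation recovers the true cell count on isolated noiseless fields", {
  for (s in c(2, 13, 77)) {
    f <- isolated_field(n_cells = 8, seed = s)
    m <- build_masks(f)
    expect_equal(max(m$nuclei_labels), nrow(f$truth$cells))
  }
})

test_that("parameter validation enforces the mask-pipeline constraints", {
  expect_error(segmentation_params(threshold_low = 100, threshold_high = 50))
  expect_error(segmentation_params(extend_radius = 3, cell_radius = 9),
               "3 \\* extend_radius")
  expect_error(segmentation_params(min_area = 10, max_area = 5))
  expect_silent(segmentation_params(extend_radius = 2, cell_radius = 7))
})
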