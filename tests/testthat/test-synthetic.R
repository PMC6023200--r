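test_that("empty and degenerate field specs behave as declared", {
  f <- generate_field(field_spec(n_cells = 0, noise_sd = 0, debris_rate = 0,
                                 background_level = 500, seed = 1))
  expect_equal(nrow(f$truth$cells), 0)
  expect_true(all(f$field$nuclear == 500))
  expect_true(all(f$field$reporter == 500))

  expect_error(field_spec(width = 0), "positive")
  expect_error(field_spec(translocation_ratio = 0), "translocation_ratio")
  expect_error(field_spec(noise_sd = -1), "noise_sd")
  expect_error(generate_field(field_spec(width = 40, height = 40,
                                         n_cells = 500, clumping = 0)),
               "placement failure")
})

test_that("noiseless construction hits the target ratio exactly over true masks", {
  f <- generate_field(field_spec(n_cells = 1, noise_sd = 0, debris_rate = 0,
                                 translocation_ratio = 2.0, seed = 5))
  expect_equal(nrow(f$truth$cells), 1)
  expect_equal(f$truth$cells$ratio_true, 2.0, tolerance = 1e-12)

  cm <- measure_cells(f, truth_masks(f))
  expect_equal(cm$ratio, 2.0, tolerance = 1e-12)
})

test_that("fixed seed reproduces fields bit-identically", {
  fs <- field_spec(n_cells = 25, noise_sd = 80, debris_rate = 1, seed = 42)
  f1 <- generate_field(fs)
  f2 <- generate_field(fs)
  expect_identical(f1$field, f2$field)
  expect_identical(f1$truth$cells, f2$truth$cells)
  f3 <- generate_field(field_spec(n_cells = 25, noise_sd = 80,
                                  debris_rate = 1, seed = 43))
  expect_false(identical(f1$field$nuclear, f3$field$nuclear))
})

test_that("raising the translocation ratio raises the measured field NUC/CYT", {
  ratios <- c(1, 1.5, 2.5, 4)
  measured <- vapply(ratios, function(r) {
    f <- generate_field(field_spec(n_cells = 40, translocation_ratio = r,
                                   noise_sd = 100, seed = 9))
    mean(measure_cells(f, build_masks(f))$ratio)
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("clumped placement produces tighter neighbour spacing", {
  nn_dist <- function(clump) {
    f <- generate_field(field_spec(n_cells = 50, clumping = clump,
                                   noise_sd = 0, debris_rate = 0,
                                   seed = 21))
    xy <- as.matrix(f$truth$cells[, c("x", "y")])
    d <- as.matrix(dist(xy)); diag(d) <- Inf
    median(apply(d, 1, min))
  }
  expect_gt(nn_dist(0), nn_dist(0.9))
})

test_that("debris is rendered saturated in the nuclear channel only", {
  f <- generate_field(field_spec(n_cells = 0, noise_sd = 0, debris_rate = 8,
                                 seed = 3))
  expect_gt(nrow(f$truth$debris), 0)
  expect_true(any(f$field$nuclear == 65535))
  expect_true(all(f$field$reporter < 65535))
})

test_that("plate simulation honours layout roles, counts and determinism", {
  layout <- plate_layout_384()
  rmap <- control_ratio_map(layout, positive = 2.5, negative = 1.0,
                            rows = 1)
  expect_named(rmap)
  expect_setequal(names(rmap), c("A01", "A02", "A23", "A24"))
  expect_equal(unname(rmap[c("A01", "A24")]), c(2.5, 2.5))
  expect_equal(unname(rmap[c("A02", "A23")]), c(1, 1))

  spec <- plate_sim_spec(layout, rmap, fields_per_well = 9,
                         field_template = field_spec(width = 64, height = 64,
                                                     n_cells = 4,
                                                     noise_sd = 0,
                                                     debris_rate = 0),
                         seed = 2)
  plate <- generate_plate(spec)
  expect_equal(sum(lengths(plate$wells)), 36)  # 4 wells x 9 fields

  # per-well ratios propagate to the rendered truth
  tr <- plate$truth
  expect_true(all(abs(tr$ratio_true[tr$well == "A01"] - 2.5) < 1e-9))
  expect_true(all(abs(tr$ratio_true[tr$well == "A02"] - 1.0) < 1e-9))

  # determinism of the whole plate
  plate2 <- generate_plate(spec)
  expect_identical(plate$truth, plate2$truth)
  expect_identical(plate$wells[["A01"]][[3]]$field,
                   plate2$wells[["A01"]][[3]]$field)

  expect_error(plate_sim_spec(layout, c(Z99 = 1.5)), "absent from layout")
})

test_that("dose-series generator follows the 4PL and the dilution ladder", {
  doses <- dose_series_3fold(100, 10, 3)
  expect_equal(length(doses), 10)
  expect_equal(doses[1], 100)
  expect_equal(doses[10], 100 / 3^9, tolerance = 1e-12)
  expect_equal(doses[10], 0.00508, tolerance = 1e-3)

  ds <- generate_dose_series(ec50 = 1, hill = 1, top = 100, bottom = 0,
                             doses = 1, noise_sd = 0)
  expect_equal(ds$response, 50)  # half-maximal at the midpoint

  ds <- generate_dose_series(ec50 = 1, hill = 2, top = 80, bottom = 10,
                             doses = c(1e-6, 1e6), noise_sd = 0)
  expect_equal(ds$response, c(10, 80), tolerance = 1e-6)

  expect_error(generate_dose_series(ec50 = 1, doses = numeric(0)), "empty")
  expect_error(generate_dose_series(ec50 = 0, doses = 1), "ec50")
})
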