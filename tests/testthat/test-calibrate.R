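make_cube <- function(values, w = seq(400, 1000, length.out = dim(values)[3])) {
  hypercube(values, w)
}

test_that("reflectance calibration follows the white/dark normalization", {
  dims <- c(3, 4, 5)
  rw <- array(0.9, dims); rd <- array(0.1, dims)
  w <- seq(400, 1000, length.out = 5)

  # raw equal to white -> reflectance 1 everywhere
  fr <- calibration_frames(make_cube(rw), make_cube(rw), make_cube(rd))
  expect_equal(as.vector(unclass(calibrate_reflectance(fr))),
               rep(1, prod(dims)))

  # raw equal to dark -> reflectance 0 everywhere
  fr <- calibration_frames(make_cube(rd), make_cube(rw), make_cube(rd))
  expect_equal(as.vector(unclass(calibrate_reflectance(fr))),
               rep(0, prod(dims)))

  # single-element hand evaluation: (0.5 - 0.1) / (0.9 - 0.1) = 0.5
  one <- function(v) hypercube(array(v, c(1, 1, 1)), 700)
  fr <- calibration_frames(one(0.5), one(0.9), one(0.1))
  expect_equal(as.numeric(unclass(calibrate_reflectance(fr))), 0.5)
})

test_that("calibration rejects zero denominators, naming the first index", {
  v <- array(1, c(2, 2, 2))
  rw <- v; rw[2, 1, 2] <- 0
  rd <- array(0, c(2, 2, 2))
  rd[2, 1, 2] <- 0  # white == dark at (2, 1) band 2
  fr <- calibration_frames(make_cube(v, c(500, 600)),
                           make_cube(rw, c(500, 600)),
                           make_cube(rd, c(500, 600)))
  expect_error(calibrate_reflectance(fr), "\\(2, 1\\), band 2")
})

test_that("calibration is monotone in the raw signal", {
  w <- c(500, 600)
  base <- array(runif(2 * 2 * 2, 0.2, 0.4), c(2, 2, 2))
  rw <- array(1, c(2, 2, 2)); rd <- array(0, c(2, 2, 2))
  r1 <- calibrate_reflectance(calibration_frames(
    make_cube(base, w), make_cube(rw, w), make_cube(rd, w)))
  r2 <- calibrate_reflectance(calibration_frames(
    make_cube(base + 0.1, w), make_cube(rw, w), make_cube(rd, w)))
  expect_true(all(unclass(r2) > unclass(r1)))
})

test_that("white/dark single frames broadcast across scan rows", {
  w <- c(500, 600, 700)
  raw <- array(runif(4 * 3 * 3, 0.3, 0.6), c(4, 3, 3))
  white_frame <- matrix(1, 3, 3)   # cols x bands
  dark_frame <- matrix(0.1, 3, 3)
  fr <- calibration_frames(make_cube(raw, w), white_frame, dark_frame)
  R <- calibrate_reflectance(fr)
  expect_equal(unclass(R), (raw - 0.1) / 0.9, ignore_attr = TRUE)
})

test_that("synthetic scenes calibrate back to the encoded reflectance", {
  sc <- generate_cube_scene(small_config(seed = 2), scene_dim = 24, seed = 2)
  R <- calibrate_reflectance(sc$frames)
  fg <- which(sc$truth_mask)
  err <- vapply(seq_along(sc$reflectance), function(b) {
    max(abs(unclass(R)[, , b][fg] - sc$reflectance[b]))
  }, numeric(1))
  expect_lt(max(err), 1e-12)
  bg <- which(!sc$truth_mask)
  expect_lt(max(abs(unclass(R)[, , 1][bg] - 0.02)), 1e-12)
})

test_that("threshold segmentation recovers the scene foreground", {
  sc <- generate_cube_scene(small_config(seed = 4), scene_dim = 32, seed = 4)
  R <- calibrate_reflectance(sc$frames)
  mask <- segment_foreground(R, threshold = 0.1)
  jac <- sum(mask & sc$truth_mask) / sum(mask | sc$truth_mask)
  expect_gte(jac, 0.95)

  all_mask <- segment_foreground(R, threshold = min(unclass(R)) - 1)
  expect_true(all(all_mask))
  expect_error(segment_foreground(R, threshold = max(unclass(R)) + 1),
               "empty foreground")
})

test_that("segmentation keeps only the largest connected component", {
  v <- array(0, c(5, 5, 1))
  v[1:2, 1:2, 1] <- 1          # 4-pixel blob
  v[5, 5, 1] <- 1              # isolated pixel
  mask <- segment_foreground(hypercube(v, 700), threshold = 0.5)
  expect_equal(sum(mask), 4)
  expect_false(mask[5, 5])
})

test_that("ROI mean spectrum is the arithmetic per-band mean", {
  w <- c(500, 600)
  v <- array(0, c(2, 2, 2))
  v[1, 1, ] <- c(1, 2); v[2, 2, ] <- c(3, 6)
  cube <- hypercube(v, w)

  m1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(unname(extract_mean_spectrum(cube, m1)), c(1, 2))

  m2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_equal(unname(extract_mean_spectrum(cube, m2)), c(2, 4))

  uniform <- hypercube(array(0.7, c(3, 3, 2)), w)
  expect_equal(unname(extract_mean_spectrum(uniform, matrix(TRUE, 3, 3))),
               c(0.7, 0.7))
  expect_error(extract_mean_spectrum(cube, matrix(FALSE, 2, 2)), "no pixels")
})
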