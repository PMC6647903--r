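test_that("grayscale is the unweighted channel mean", {
  px <- array(0, c(2, 2, 3))
  px[1, 1, ] <- c(1, 1, 1)
  px[1, 2, ] <- c(0.2, 0.4, 0.6)
  px[2, 1, ] <- c(0.5, 0.5, 0.5)
  g <- to_grayscale(spot_image(px))
  expect_equal(g[1, 1], 1)
  expect_equal(g[1, 2], 0.4)
  expect_equal(g[2, 1], 0.5)
})

test_that("Gaussian smoothing preserves constants and mass, and the impulse response is the kernel", {
  const <- matrix(0.37, 40, 40)
  expect_equal(gaussian_smooth(const, 15), const)

  imp <- matrix(0, 101, 101)
  imp[51, 51] <- 1
  sm <- gaussian_smooth(imp, 15)
  k1 <- drscore:::gaussian_kernel_1d(15, 5)
  expect_equal(sm[51, 51], k1[16]^2, tolerance = 1e-12)
  # 2-D kernel weight at offset (2, 3)
  expect_equal(sm[53, 54], k1[18] * k1[19], tolerance = 1e-12)

  # interior mean preserved on an image without border effects
  flat <- matrix(0.2, 80, 80)
  flat[40, 40] <- 0.9
  expect_equal(mean(gaussian_smooth(flat, 15)), mean(flat), tolerance = 1e-6)
})

test_that("intensity transform hits its analytic anchors and is strictly decreasing", {
  two_e <- 2 * exp(1)
  expect_equal(transform_intensity(matrix(0, 1, 1))[1], 1)
  expect_equal(transform_intensity(matrix(1 - exp(-two_e), 1, 1))[1], 0,
               tolerance = 1e-12)
  expect_equal(transform_intensity(matrix(0.5, 1, 1))[1],
               (log(0.5) + two_e) / two_e, tolerance = 1e-12)
  # values at and beyond the clamp boundary collapse to 0
  expect_equal(transform_intensity(matrix(1, 1, 1))[1], 0, tolerance = 1e-12)

  grid <- seq(0, 1 - exp(-two_e), length.out = 200)
  it <- transform_intensity(matrix(grid, 1))
  expect_true(all(diff(as.numeric(it)) < 0))
  expect_true(all(it >= 0 & it <= 1))
})

test_that("Otsu separates a bimodal image, is permutation invariant, and flags constants", {
  x <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10)
  m <- otsu_threshold(x)
  thr <- attr(m, "threshold")
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.9)
  expect_identical(as.vector(m), as.vector(x > 0.5))

  set.seed(5)
  y <- matrix(runif(400), 20)
  perm <- matrix(sample(y), 20)
  expect_equal(attr(otsu_threshold(y), "threshold"),
               attr(otsu_threshold(perm), "threshold"))

  expect_warning(mc <- otsu_threshold(matrix(0.5, 8, 8)), "constant")
  expect_false(any(mc))
})

test_that("small-object removal uses strict 'smaller than' with 8-connectivity", {
  m <- matrix(FALSE, 200, 200)
  m[1:10, 1:10] <- TRUE                      # 100 px blob
  expect_false(any(remove_small_objects(m, 12500)))

  m2 <- matrix(FALSE, 200, 200)
  m2[1:125, 1:100] <- TRUE                   # exactly 12,500 px
  expect_equal(sum(remove_small_objects(m2, 12500)), 12500)

  m3 <- matrix(FALSE, 300, 300)
  m3[1:100, 1:200] <- TRUE
  m3[151:250, 1:200] <- TRUE                 # two 20,000 px blobs
  expect_equal(sum(remove_small_objects(m3, 12500)), 40000)

  # a diagonal chain is one component under 8-connectivity
  d <- matrix(FALSE, 10, 10)
  diag(d) <- TRUE
  expect_equal(sum(remove_small_objects(d, 10)), 10)
  expect_false(any(remove_small_objects(d, 11)))
})

test_that("full foreground pipeline recovers the synthetic tissue disc", {
  img <- generate_spot_image(latent_score = 0, image_size = 256, seed = 21)
  fg <- compute_foreground(img)
  truth <- attr(img, "truth")$disc_mask
  jac <- sum(fg$mask & truth) / sum(fg$mask | truth)
  expect_gte(jac, 0.8)
  expect_lte(fg$area_pixels, 256 * 256)
  expect_equal(fg$area_pixels, sum(fg$mask))
  expect_equal(fg$area_mm2, fg$area_pixels * (0.22 / 1000)^2)

  white <- spot_image(array(1, c(64, 64, 3)))
  expect_warning(fg_w <- compute_foreground(white), "constant")
  expect_equal(fg_w$area_pixels, 0)
})

test_that("segmentation is deterministic", {
  img <- generate_spot_image(latent_score = 1, image_size = 128, seed = 4)
  expect_identical(compute_foreground(img)$mask, compute_foreground(img)$mask)
})

test_that("area criterion is strict and scales with pixel size", {
  m <- matrix(TRUE, 100, 100)
  # construct exactly 0.02 mm^2: 10,000 px at sqrt(0.02)/100*1000 um/px
  fm <- foreground_mask(m, pixel_size_um = sqrt(0.02) / 100 * 1000)
  expect_equal(fm$area_mm2, 0.02)
  expect_false(passes_area_criterion(fm, 0.02))

  big <- foreground_mask(matrix(TRUE, 1000, 500), pixel_size_um = 0.22)
  expect_equal(big$area_mm2, 5e5 * (0.22 / 1000)^2)  # 0.0242 mm^2
  expect_true(passes_area_criterion(big, 0.02))

  empty <- foreground_mask(matrix(FALSE, 10, 10))
  expect_false(passes_area_criterion(empty, 0.02))
})
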