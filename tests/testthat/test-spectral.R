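# the published detector calibration for the confocal HyD detectors
hyd_coeffs <- function() linearity_coefficients(0.9838, 1.1044, 0.001, 7000)

test_that("linearity correction matches independent evaluation of the curve", {
  co <- hyd_coeffs()
  expect_identical(linearity_transform(0, co), 0)
  # independent evaluation of a*x + b*(exp(c*x) - 1)
  ref <- 0.9838 * 7000 + 1.1044 * (exp(0.001 * 7000) - 1)
  expect_equal(linearity_transform(7000, co), ref, tolerance = 1e-9)
  expect_equal(linearity_transform(7000, co), 8096.617, tolerance = 1e-4)
})

test_that("saturated voxels are discarded, not corrected", {
  co <- hyd_coeffs()
  expect_true(is.na(linearity_transform(7001, co)))
  img <- channel_image(array(c(100, 7001, 3000, 50), c(2, 2, 1, 1)))
  out <- apply_linearity_correction(img, co)
  expect_equal(sum(is.na(out$voxels)), 1L)
  expect_true(isTRUE(attr(out, "linearity_corrected")))
})

test_that("the correction fixes 0 and increases strictly below the cutoff", {
  co <- hyd_coeffs()
  x <- seq(0, 7000, length.out = 500)
  y <- linearity_transform(x, co)
  expect_equal(y[1], 0)
  expect_true(all(diff(y) > 0))
  expect_error(linearity_coefficients(-2, 1, 0.1, 100), "monotonically")
})

test_that("an identity detector fits to a ~ 1 with a negligible exponential", {
  powers <- seq(0.2, 3, by = 0.2)
  set.seed(21)
  slopes <- runif(40, 500, 3000)
  measured <- outer(slopes, powers)          # perfectly linear detector
  co <- fit_linearity(measured, powers, linear_range = seq(0.2, 1, 0.2))
  expect_equal(co$a, 1, tolerance = 0.01)
  x <- seq(0, max(measured), length.out = 50)
  expect_lt(max(abs(co$b * (exp(co$c * x) - 1))), 0.01 * max(measured))
})

test_that("generating coefficients are recovered from a synthetic detector", {
  a <- 0.9838; b <- 1.1044; cc <- 0.001
  fwd <- function(x) a * x + b * exp(cc * x) - b   # measured -> true
  xg <- seq(0, 9000, by = 1)
  inv <- stats::approxfun(fwd(xg), xg)             # true -> measured
  powers <- seq(0.2, 3, by = 0.2)
  set.seed(22)
  slopes <- runif(60, 300, 2300)
  true_int <- outer(slopes, powers)
  measured <- matrix(inv(true_int), nrow(true_int))
  co <- fit_linearity(measured, powers, linear_range = seq(0.2, 1, 0.2))
  expect_equal(co$a, a, tolerance = 0.02)
  expect_equal(co$c, cc, tolerance = 0.05)
  # b trades off against c in the exponential term, so the binding check
  # is the correction curve itself: within 2% of the generator everywhere
  x <- seq(100, 6000, length.out = 200)
  got <- co$a * x + co$b * expm1(co$c * x)
  expect_lt(max(abs(got - fwd(x)) / fwd(x)), 0.02)
})

test_that("degenerate calibration series fail with a diagnosis", {
  powers <- seq(0.2, 3, by = 0.2)
  flat <- matrix(500, 10, length(powers))
  expect_error(fit_linearity(flat, powers, seq(0.2, 1, 0.2)), "degenerate")
  decreasing <- outer(runif(10, 500, 1000), rev(powers))
  expect_error(fit_linearity(decreasing, powers, seq(0.2, 1, 0.2)),
               "monotone")
  expect_error(fit_linearity(flat, powers, c(0.2, 0.4)), "at least 3")
})

ref_layout <- function() list(
  list(laser = "488", channels = 1:2, fluorophores = c("A", "B")))

test_that("mixing-matrix columns recover known emission ratios", {
  # fluorophore emitting into a single channel -> unit basis column
  set.seed(23)
  mkref <- function(col, bright = 1000) {
    vox <- array(rnorm(8 * 8 * 4 * 2, 10, 0.5), c(8, 8, 4, 2))
    fg <- sample(8 * 8 * 4, 40)
    for (ch in 1:2) {
      plane <- vox[, , , ch]
      plane[fg] <- bright * col[ch] * (1 + rnorm(40, 0, 0.01)) + 10
      vox[, , , ch] <- plane
    }
    channel_image(vox)
  }
  ref <- build_mixing_matrix(list(A = mkref(c(1, 0)), B = mkref(c(0.3, 0.7))),
                             ref_layout())
  M <- ref$groups[[1]]$M
  expect_equal(unname(M[, "A"]), c(1, 0), tolerance = 0.02)
  expect_equal(unname(M[, "B"]), c(0.3, 0.7), tolerance = 0.02)
  expect_warning(
    build_mixing_matrix(list(A = mkref(c(0.5, 0.5)), B = mkref(c(0.5, 0.5))),
                        ref_layout()),
    "rank-deficient")
})

test_that("a known 3x3 ratio matrix is recovered within 0.02 from noisy refs", {
  set.seed(24)
  truth <- cbind(c(0.7, 0.2, 0.1), c(0.1, 0.6, 0.3), c(0.25, 0.25, 0.5))
  mkref3 <- function(col) {
    vox <- array(rnorm(8 * 8 * 4 * 3, 5, 0.2), c(8, 8, 4, 3))
    fg <- sample(8 * 8 * 4, 50)
    for (ch in 1:3) {
      plane <- vox[, , , ch]
      plane[fg] <- 2000 * col[ch] * (1 + rnorm(50, 0, 0.01)) + 5
      vox[, , , ch] <- plane
    }
    channel_image(vox)
  }
  layout3 <- list(list(laser = "405", channels = 1:3,
                       fluorophores = c("F1", "F2", "F3")))
  refs <- list(F1 = mkref3(truth[, 1]), F2 = mkref3(truth[, 2]),
               F3 = mkref3(truth[, 3]))
  M <- build_mixing_matrix(refs, layout3)$groups[[1]]$M
  expect_lt(max(abs(unname(M) - truth)), 0.02)
})

test_that("unmixing solves the 2x2 system exactly", {
  M <- cbind(c(0.8, 0.2), c(0.3, 0.7))
  ref <- spectral_reference(list(list(laser = "488", channels = 1:2,
                                      fluorophores = c("A", "B"), M = M)))
  img <- channel_image(array(c(1.1, 0.9), c(1, 1, 1, 2)))
  attr(img, "linearity_corrected") <- TRUE
  u <- unmix(img, ref)
  expect_equal(as.numeric(u$voxels), c(1, 1), tolerance = 1e-9)
  # a pure-fluorophore voxel returns k on its own channel only
  img2 <- channel_image(array(5 * M[, 2], c(1, 1, 1, 2)))
  attr(img2, "linearity_corrected") <- TRUE
  u2 <- unmix(img2, ref)
  expect_equal(as.numeric(u2$voxels), c(0, 5), tolerance = 1e-6)
})

test_that("unmix . mix is the identity on noiseless abundances", {
  set.seed(25)
  M1 <- cbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3), c(0.1, 0.2, 0.7))
  M2 <- cbind(c(0.8, 0.2), c(0.4, 0.6))
  ref <- spectral_reference(list(
    list(laser = "405", channels = 1:3, fluorophores = c("F1", "F2", "F3"),
         M = M1),
    list(laser = "488", channels = 4:5, fluorophores = c("F4", "F5"),
         M = M2)))
  truth <- channel_image(array(rexp(6 * 6 * 3 * 5, 1 / 100),
                               c(6, 6, 3, 5)))
  mixed <- mix(truth, ref)
  attr(mixed, "linearity_corrected") <- TRUE
  back <- unmix(mixed, ref)
  expect_equal(back$voxels, truth$voxels, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("saturated voxels propagate to every fluorophore of their group", {
  M <- cbind(c(0.8, 0.2), c(0.3, 0.7))
  ref <- spectral_reference(list(list(laser = "488", channels = 1:2,
                                      fluorophores = c("A", "B"), M = M)))
  vox <- array(1, c(2, 1, 1, 2)); vox[1, 1, 1, 2] <- NA
  img <- channel_image(vox)
  attr(img, "linearity_corrected") <- TRUE
  u <- unmix(img, ref)
  expect_true(all(is.na(u$voxels[1, 1, 1, ])))
  expect_true(all(!is.na(u$voxels[2, 1, 1, ])))
})

test_that("a singular mixing matrix is rejected with advice", {
  M <- cbind(c(0.5, 0.5), c(0.5, 0.5))
  ref <- spectral_reference(list(list(laser = "488", channels = 1:2,
                                      fluorophores = c("A", "B"), M = M)))
  img <- channel_image(array(1, c(1, 1, 1, 2)))
  attr(img, "linearity_corrected") <- TRUE
  expect_error(unmix(img, ref), "reference")
})

test_that("unmixing an uncorrected image warns about channel ratios", {
  ref <- spectral_reference(list(list(laser = "488", channels = 1:2,
                                      fluorophores = c("A", "B"),
                                      M = cbind(c(0.8, 0.2), c(0.3, 0.7)))))
  img <- channel_image(array(1, c(1, 1, 1, 2)))
  expect_warning(unmix(img, ref), "linearity")
})

test_that("channel images round-trip through TIFF with NA voxels intact", {
  set.seed(26)
  vox <- array(rexp(6 * 5 * 3 * 2, 1 / 500), c(6, 5, 3, 2))
  vox[2, 3, 1, 2] <- NA
  img <- channel_image(vox, voxel_size = c(0.5, 0.5, 2),
                       channels = c("red", "green"))
  p <- withr::local_tempfile(fileext = ".tif")
  write_channel_image(img, p)
  back <- read_channel_image(p)
  expect_equal(back$voxels, img$voxels, tolerance = 1e-6)
  expect_equal(back$voxel_size, img$voxel_size)
  expect_equal(back$channels, img$channels)
})

test_that("spectral references round-trip through YAML", {
  M <- cbind(c(0.8, 0.2), c(0.3, 0.7))
  ref <- spectral_reference(list(list(laser = "488", channels = 1:2,
                                      fluorophores = c("A", "B"), M = M)))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_spectral_reference(ref, p)
  back <- read_spectral_reference(p)
  expect_equal(unname(as.matrix(back$groups[[1]]$M)), unname(M),
               tolerance = 1e-12)
  expect_equal(back$groups[[1]]$channels, 1:2)
})
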