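# Morphometry: binarization, orientation, crossings, density/ICD, diameters.

bars_image <- function(angle_deg = 0, spacing = 30, diam = 5, fov = 300,
                       pixel = 1, psf = 0, seed = 1) {
  net <- generate_network("Temp", spacing, diam, seed = seed, fov_um = fov,
                          angle_deg = angle_deg)
  render_histology(net, pixel_um = pixel, psf_fwhm_um = psf)
}

test_that("binarize recovers a two-level image exactly and flags inversion", {
  img <- matrix(0, 50, 50)
  img[20:30, ] <- 100
  ef <- enface_image(img, 1)
  bin <- binarize(ef, smooth_sigma_px = 0)
  expect_equal(bin$pixels, matrix(as.numeric(img > 0), 50, 50))
  inv <- enface_image(100 - img + 1, 1)
  expect_warning(binarize(inv, smooth_sigma_px = 0), "inverted")
  expect_error(binarize(enface_image(matrix(1, 5, 5), 1)), "constant")
})

test_that("binarized histology render overlaps the truth mask (Dice >= 0.9)", {
  net <- generate_network("ST", 35, 6, waviness = 0.1, seed = 9, fov_um = 400)
  truth <- render_histology(net, pixel_um = 1, psf_fwhm_um = 0)
  blurred <- render_histology(net, pixel_um = 1, psf_fwhm_um = 2)
  bin <- binarize(blurred, smooth_sigma_px = 1)
  inter <- sum(bin$pixels * (truth$pixels > 0.5))
  dice <- 2 * inter / (sum(bin$pixels) + sum(truth$pixels > 0.5))
  expect_gte(dice, 0.9)
})

test_that("dominant orientation finds bar angles and is rotation equivariant", {
  a30 <- dominant_orientation(bars_image(30))
  expect_lt(min(abs(as.numeric(a30) - 30), 180 - abs(as.numeric(a30) - 30)), 2)
  # constructing the same bars rotated by phi shifts the estimate by phi
  for (phi in c(25, 60, 115)) {
    ai <- as.numeric(dominant_orientation(bars_image(10)))
    aj <- as.numeric(dominant_orientation(bars_image((10 + phi) %% 180)))
    d <- abs((aj - ai) %% 180 - phi %% 180)
    expect_lt(min(d, 180 - d), 2)
  }
  # isotropic input is rejected with guidance
  set.seed(1)
  noise <- enface_image(matrix(runif(400), 20, 20), 1)
  expect_error(dominant_orientation(noise, smooth_sigma_px = 0), "isotropic")
})

test_that("orientation recovers the generator angle on wavy phantoms", {
  errs <- vapply(1:10, function(s) {
    net <- generate_network("IT", 35, 5, waviness = 0.2, seed = s,
                            fov_um = 400)
    img <- render_histology(net, pixel_um = 1, psf_fwhm_um = 2)
    a <- as.numeric(dominant_orientation(img))
    d <- abs(a - net$dominant_angle) %% 180
    min(d, 180 - d)
  }, numeric(1))
  expect_true(all(errs < 5))
})

test_that("crossing counts match geometry on constructed bars", {
  net <- generate_network("Temp", 30, 5, n_capillaries = 6, seed = 1,
                          fov_um = 200)
  img <- render_histology(net, pixel_um = 1, psf_fwhm_um = 0)
  # perpendicular line crosses all 6; parallel line crosses at most 1
  perp <- count_crossings(img, 90)
  expect_equal(perp$n_crossings, 6)
  par <- count_crossings(img, 0)
  expect_lte(par$n_crossings, 1)
})

test_that("crossing counts agree with the segment-intersection oracle", {
  for (s in 1:20) {
    spacing <- stats::runif(1, 28, 45)
    ang <- stats::runif(1, 0, 180)
    net <- generate_network("Temp", spacing, 5, waviness = 0.1, seed = s,
                            fov_um = 400, angle_deg = ang)
    img <- render_histology(net, pixel_um = 1, psf_fwhm_um = 0)
    line <- count_crossings(img, ang + 90, length_um = 300)
    oracle <- crossings_oracle(net, c(200, 200), ang + 90, 300)
    expect_lte(abs(line$n_crossings - oracle), 1)
  }
})

test_that("crossing count is invariant to intensity scale and line offset", {
  net <- generate_network("Temp", 35, 5, seed = 2, fov_um = 400)
  img <- render_histology(net, pixel_um = 1, psf_fwhm_um = 2)
  bin1 <- binarize(img, 1)
  img5 <- img; img5$pixels <- img$pixels * 5
  bin5 <- binarize(img5, 1)
  expect_equal(bin1$pixels, bin5$pixels)
  # translating the line along the vessel direction does not change counts
  base <- count_crossings(bin1, 90, length_um = 300)$n_crossings
  for (off in c(-40, -20, 10, 30, 50)) {
    moved <- count_crossings(bin1, 90, center = c(200 + off, 200),
                             length_um = 300)$n_crossings
    expect_equal(moved, base)
  }
})

test_that("density and ICD are exact inverses scaled by 100", {
  line <- structure(list(center = c(0, 0), angle_deg = 90, length_um = 200,
                         crossings_um = seq(10, 190, length.out = 6),
                         n_crossings = 6L), class = "sampling_line")
  res <- density_and_icd(line)
  expect_equal(res$density_per_100um, 3)
  expect_equal(res$icd_um, 200 / 6)
  expect_equal(res$density_per_100um * res$icd_um, 100)
  empty <- line; empty$n_crossings <- 0L; empty$crossings_um <- numeric(0)
  res0 <- density_and_icd(empty)
  expect_equal(res0$density_per_100um, 0)
  expect_false(res0$icd_defined)
  expect_true(is.na(res0$icd_um))
})

test_that("diameters are exact on sharp bars and match the blur oracle", {
  net <- generate_network("Temp", 40, 5, n_capillaries = 4, seed = 1,
                          fov_um = 200)
  sharp <- render_histology(net, pixel_um = 0.5, psf_fwhm_um = 0)
  d0 <- suppressWarnings(capillary_diameter(sharp))
  expect_true(all(abs(d0 - 5) <= 0.5))
  # blurred bars: measured FWHM matches the 1-D convolution oracle and
  # exceeds the true width
  for (psf in c(4, 8.6)) {
    blur <- render_histology(net, pixel_um = 0.5, psf_fwhm_um = psf)
    d <- suppressWarnings(capillary_diameter(blur))
    oracle <- fwhm_convolution_oracle(5, psf)
    expect_equal(mean(d), oracle, tolerance = 0.05)
    expect_gt(mean(d), 5)
  }
})

test_that("PSF blur biases measured diameter upward monotonically", {
  net <- generate_network("Temp", 40, 5, n_capillaries = 4, seed = 3,
                          fov_um = 200)
  ds <- vapply(c(0.5, 3, 6, 9), function(psf) {
    mean(suppressWarnings(
      capillary_diameter(render_histology(net, 0.5, psf))))
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
  expect_true(all(ds >= 5))
})

test_that("binary-mode diameter equals the run length through the point", {
  net <- generate_network("Temp", 40, 6, n_capillaries = 3, seed = 2,
                          fov_um = 150)
  img <- render_histology(net, pixel_um = 0.5, psf_fwhm_um = 0)
  d <- suppressWarnings(capillary_diameter(img, mode = "binary"))
  expect_true(all(abs(d - 6) <= 0.75))
})
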