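# Boundary segmentation and RNFL thickness.

# noiseless synthetic volume: vitreous dark, tissue bright from z_ilm,
# thin bright band at z_rpe (pixel indices)
step_volume <- function(ny = 6, nz = 200, nx = 30, z_ilm = 40, z_rpe = 160,
                        dz = 2) {
  arr <- array(0.05, c(ny, nz, nx))
  arr[, z_ilm:nz, ] <- 1
  arr[, z_rpe:(z_rpe + 3), ] <- 2
  structure(arr, spacing = c(slow = 4, depth = dz, fast = 4))
}

test_that("noiseless step-profile boundaries are recovered exactly", {
  arr <- step_volume()
  seg <- segment_boundaries(arr, spacing = c(slow = 4, depth = 2, fast = 4),
                            smooth_sigma_px = 0, rpe_smooth_sigma_px = 0)
  # ILM reported at the voxel boundary just above the first bright voxel
  expect_true(all(seg$ilm == (40 - 1) * 2))
  # RPE at the center of the brightest band rows (first band row wins ties)
  expect_true(all(abs(seg$rpe - (160 - 0.5) * 2) <= 2 * 2))
})

test_that("segmentation is depth-shift equivariant and scale invariant", {
  arr <- step_volume()
  seg0 <- segment_boundaries(arr, spacing = c(slow = 4, depth = 2, fast = 4))
  shifted <- array(0.05, dim(arr))
  shifted[, 11:200, ] <- arr[, 1:190, ]
  seg1 <- segment_boundaries(shifted, spacing = c(slow = 4, depth = 2, fast = 4))
  expect_equal(seg1$ilm, seg0$ilm + 10 * 2)
  expect_equal(seg1$rpe, seg0$rpe + 10 * 2)
  seg2 <- segment_boundaries(arr * 37, spacing = c(slow = 4, depth = 2, fast = 4))
  expect_equal(seg2$ilm, seg0$ilm)
  expect_equal(seg2$rpe, seg0$rpe)
})

test_that("an edgeless volume is rejected per B-scan", {
  flat <- array(1, c(4, 60, 10))
  expect_error(segment_boundaries(flat + 0,
                                  spacing = c(slow = 4, depth = 3, fast = 4)),
               "no edge")
})

test_that("the RNFL/GCL boundary derives from the RPE by anterior offset", {
  ilm <- matrix(50, 4, 6)
  rpe <- matrix(300, 4, 6)
  lm0 <- derive_rnfl_gcl(ilm, rpe, 0)
  expect_equal(lm0$rnfl_gcl, rpe)
  lm1 <- derive_rnfl_gcl(ilm, rpe, 250)
  expect_true(all(lm1$rnfl_gcl == 50))
  expect_warning(derive_rnfl_gcl(ilm, rpe, 270), "clipped")
  # layer ordering invariant is asserted on construction
  expect_error(layer_model(rpe, ilm, rpe), "ordering")
})

test_that("offset fitted against phantom truth recovers the boundary", {
  geom <- small_geom(n = 48, fov = 260)
  net <- generate_network("Sup", 40, 6, seed = 11, fov_um = 260)
  layers <- retina_layers(geom)
  rnd <- render_oct_volume(net, layers, geom, speckle_params(seed = 11))
  seg <- segment_boundaries(rnd$volume)
  off <- fit_rnfl_offset(seg$rpe, layers$rnfl_gcl)
  lmod <- derive_rnfl_gcl(seg$ilm, seg$rpe, off)
  err_px <- mean(abs(lmod$rnfl_gcl - layers$rnfl_gcl)) / geom$dz_um
  expect_lt(err_px, 2)
})

test_that("RNFL thickness averages the selected B-scans", {
  ilm <- matrix(10 * 2, 20, 8)
  rnfl_gcl <- matrix(30 * 2, 20, 8)
  rpe <- matrix(100 * 2, 20, 8)
  lmod <- layer_model(ilm, rnfl_gcl, rpe)
  th <- rnfl_thickness(lmod)
  expect_equal(th$mean_um, 40)
  expect_equal(th$n_bscans, 10)
  # linearly varying thickness 20 -> 60 um, all B-scans: mean is 40
  grad <- matrix(rep(seq(20, 60, length.out = 20), 8), 20, 8)
  lm2 <- layer_model(ilm, ilm + grad, rpe)
  expect_equal(rnfl_thickness(lm2, bscan_indices = 1:20)$mean_um, 40)
  expect_error(rnfl_thickness(lmod, bscan_indices = integer(0)), "empty")
  expect_error(rnfl_thickness(lmod, bscan_indices = 99), "range")
})
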