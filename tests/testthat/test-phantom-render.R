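# Rendering: histology rasters and repeat-frame speckle volumes.

test_that("a single capillary rasterizes to a bar of its true width", {
  net <- generate_network("Temp", 30, 5, n_capillaries = 1, seed = 1,
                          fov_um = 100)
  img <- render_histology(net, pixel_um = 0.5, psf_fwhm_um = 0)
  # width of the bar at mid-image, in pixels (true width 10 px at 0.5 um)
  widths <- colSums(img$pixels > 0.5)
  widths <- widths[widths > 0]
  expect_true(all(abs(widths - 10) <= 1))
})

test_that("raster foreground area matches the analytic tube area", {
  net <- generate_network("Temp", 35, 5, n_capillaries = 18, seed = 1)
  img <- render_histology(net, pixel_um = 0.5, psf_fwhm_um = 0)
  area <- sum(img$pixels) * 0.5^2
  len <- sum(vapply(net$capillaries, function(p)
    sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)), numeric(1)))
  expect_equal(area, len * 5, tolerance = 0.03)
})

test_that("renders are deterministic", {
  net <- generate_network("ST", 32, 5, waviness = 0.1, seed = 4)
  a <- render_histology(net, 1, 1)
  b <- render_histology(net, 1, 1)
  expect_identical(a$pixels, b$pixels)
  geom <- small_geom(n = 40, fov = 200)
  r1 <- render_oct_volume(generate_network("Sup", 40, 6, seed = 2, fov_um = 200),
                          retina_layers(geom), geom, speckle_params(seed = 9))
  r2 <- render_oct_volume(generate_network("Sup", 40, 6, seed = 2, fov_um = 200),
                          retina_layers(geom), geom, speckle_params(seed = 9))
  expect_identical(r1$volume$intensity, r2$volume$intensity)
})

test_that("zero flow decorrelation means repeats identical up to noise", {
  geom <- small_geom(n = 40, fov = 200)
  net <- generate_network("Sup", 40, 6, seed = 2, fov_um = 200)
  layers <- retina_layers(geom)
  # noise_floor 0, w 0: per-voxel variance across repeats exactly 0
  rnd <- render_oct_volume(net, layers, geom,
                           speckle_params(flow_decorrelation = 0,
                                          noise_floor = 0, seed = 5))
  svv <- speckle_variance(rnd$volume)
  expect_true(all(svv$sv == 0))
  # with noise, differences stay at the noise-floor scale
  rnd2 <- render_oct_volume(net, layers, geom,
                            speckle_params(flow_decorrelation = 0,
                                           noise_floor = 0.05, seed = 5))
  d <- rnd2$volume$intensity[1, , , ] - rnd2$volume$intensity[2, , , ]
  expect_lt(stats::sd(d), 3 * 0.05)
})

test_that("capillary voxels decorrelate much faster than static tissue", {
  geom <- small_geom(n = 48, fov = 260)
  net <- generate_network("Sup", 40, 6, seed = 3, fov_um = 260)
  layers <- retina_layers(geom)
  ratios <- vapply(1:10, function(s) {
    rnd <- render_oct_volume(net, layers, geom, speckle_params(seed = s))
    svv <- speckle_variance(rnd$volume)
    mean(svv$sv[rnd$truth$flow_mask]) / mean(svv$sv[!rnd$truth$flow_mask])
  }, numeric(1))
  expect_gt(mean(ratios), 5)
})

test_that("fraction-weighted flow volume matches the analytic tube volume", {
  geom <- scan_geometry(fov_um = 300, n_fast = 300, n_slow = 300,
                        n_depth = 120, depth_range_um = 240)
  net <- generate_network("ST", 40, 8, seed = 4, fov_um = 300,
                          z_range_um = c(60, 120))
  layers <- retina_layers(geom, ilm_um = 40, rpe_um = 200, rpe_band_um = 15)
  rnd <- render_oct_volume(net, layers, geom, speckle_params(seed = 4))
  vox <- geom$pixel_um^2 * geom$dz_um
  len <- sum(vapply(rnd$truth$network$capillaries, function(p)
    sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)), numeric(1)))
  expect_equal(sum(rnd$truth$flow_frac) * vox, len * pi * 4^2,
               tolerance = 0.03)
})

test_that("across-repeat variance in capillaries rises with flow decorrelation", {
  geom <- small_geom(n = 40, fov = 200)
  net <- generate_network("Sup", 40, 6, seed = 3, fov_um = 200)
  layers <- retina_layers(geom)
  for (s in 1:5) {
    v <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(w) {
      rnd <- render_oct_volume(net, layers, geom,
                               speckle_params(flow_decorrelation = w,
                                              noise_floor = 0, seed = s))
      mean(speckle_variance(rnd$volume)$sv[rnd$truth$flow_mask])
    }, numeric(1))
    expect_true(all(diff(v) > 0))
  }
})

test_that("geometry mismatches are rejected", {
  geom <- small_geom(n = 40, fov = 200)
  net_big <- generate_network("Sup", 40, 6, seed = 1, fov_um = 500)
  expect_error(render_oct_volume(net_big, retina_layers(geom), geom),
               "exceeds")
  shallow <- scan_geometry(fov_um = 200, n_fast = 40, n_slow = 40,
                           n_depth = 40, depth_range_um = 120)
  expect_error(retina_layers(shallow), "depth range")
})
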