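# Speckle variance, thresholding, streak removal, en-face projection, crop.

make_volume <- function(arr, spacing = c(slow = 4, depth = 3, fast = 4)) {
  oct_volume(arr, spacing = spacing)
}

test_that("speckle variance is the population variance across repeats", {
  # identical repeats -> all zero
  a <- array(5, c(3, 2, 4, 2))
  expect_true(all(speckle_variance(make_volume(a))$sv == 0))
  # (1, 2, 3) across repeats -> population variance 2/3
  a[, 1, 1, 1] <- c(1, 2, 3)
  expect_equal(speckle_variance(make_volume(a))$sv[1, 1, 1], 2 / 3)
  expect_error(speckle_variance(make_volume(array(1, c(1, 2, 2, 2)))),
               "repeats")
})

test_that("speckle variance invariances hold", {
  set.seed(42)
  a <- array(rexp(3 * 4 * 5 * 6), c(3, 4, 5, 6))
  sv <- speckle_variance(make_volume(a))$sv
  # permutation of repeats
  expect_equal(speckle_variance(make_volume(a[c(3, 1, 2), , , ]))$sv, sv)
  # additive shift leaves sv unchanged; scaling by a scales sv by a^2
  expect_equal(speckle_variance(make_volume(a + 7))$sv, sv, tolerance = 1e-12)
  expect_equal(speckle_variance(make_volume(2.5 * a))$sv, 2.5^2 * sv)
})

test_that("percentile thresholding zeroes only sub-threshold values", {
  img <- enface_image(matrix(c(1, 2, 3, 4, 5, 6), 2, 3), pixel_um = 2)
  # percentile 0 on an all-positive image is the identity
  expect_equal(threshold_sv(img, 0)$pixels, img$pixels)
  # constant positive image: ties at the threshold are kept
  cimg <- enface_image(matrix(5, 4, 4), pixel_um = 2)
  expect_equal(threshold_sv(cimg, 50)$pixels, cimg$pixels)
  out <- threshold_sv(img, 50)
  thr <- stats::quantile(1:6, 0.5)
  expect_true(all(out$pixels[img$pixels < thr] == 0))
  expect_true(all(out$pixels[img$pixels >= thr] == img$pixels[img$pixels >= thr]))
  expect_error(threshold_sv(img, 100), "100")
})

test_that("thresholding a phantom keeps static false positives low", {
  geom <- small_geom(n = 64, fov = 350)
  net <- generate_network("Sup", 40, 6, seed = 6, fov_um = 350)
  rnd <- render_oct_volume(net, retina_layers(geom), geom,
                           speckle_params(seed = 6))
  svv <- speckle_variance(rnd$volume)
  lmod <- layer_model(rnd$truth$layers$ilm, rnd$truth$layers$rnfl_gcl,
                      rnd$truth$layers$rpe)
  ef <- threshold_sv(enface_project(svv, lmod), 75)
  # static tissue = lateral positions with no capillary in the slab;
  # exclude a one-pixel guard ring around true vessels (PSF halo)
  fm <- apply(rnd$truth$flow_mask, c(1, 3), any)
  guard <- fm
  for (dy in -2:2) for (dx in -2:2)
    guard <- guard | rpcsvoct:::shift_dim(rpcsvoct:::shift_dim(fm, 1L, dy), 2L, dx)
  fp <- mean(ef$pixels[!guard] > 0)
  expect_lt(fp, 0.05)
})

test_that("streak rows are corrected toward their neighbours", {
  img <- matrix(1, 40, 40)
  img[20, ] <- 12
  out <- remove_streaks(enface_image(img, 4))
  expect_equal(unname(attr(out, "streak_rows")), 20)
  expect_equal(mean(out$pixels[20, ]), 1, tolerance = 0.01)
  # all-zero image is untouched
  z <- remove_streaks(enface_image(matrix(0, 10, 10), 1))
  expect_true(all(z$pixels == 0))
})

test_that("streak filtering preserves vessel recall within 2 points", {
  r_clean <- pipeline_once(8, region = "Sup", n = 128, fov = 560, crop = 560)
  r_strk <- pipeline_once(8, region = "Sup", n = 128, fov = 560, crop = 560,
                          bulk_motion_prob = 0.05)
  recall <- function(r) {
    fm <- apply(r$truth$flow_mask, c(1, 3), any)
    mean(r$enface$pixels[fm] > 0)
  }
  expect_lt(abs(recall(r_strk) - recall(r_clean)), 0.02 + 1e-9)
})

test_that("en-face projection reduces the slab as documented", {
  sv <- array(0, c(4, 10, 5))
  sv[, , ] <- 3   # constant
  svv <- structure(list(sv = sv, spacing = c(slow = 4, depth = 10, fast = 4)),
                   class = "sv_volume")
  lm_flat <- layer_model(matrix(20, 4, 5), matrix(60, 4, 5), matrix(90, 4, 5))
  ef <- enface_project(svv, lm_flat)
  expect_true(all(ef$pixels == 3))
  # single-plane slab extracts that plane exactly
  sv2 <- sv
  sv2[, 5, ] <- matrix(seq_len(20), 4, 5)
  svv2 <- structure(list(sv = sv2, spacing = c(slow = 4, depth = 10, fast = 4)),
                    class = "sv_volume")
  lm_one <- layer_model(matrix(40, 4, 5), matrix(50, 4, 5), matrix(90, 4, 5))
  ef2 <- enface_project(svv2, lm_one, slab = c("ILM", "RNFL/GCL"))
  expect_equal(ef2$pixels, matrix(seq_len(20), 4, 5))
  # crossed boundaries error and report positions
  lm_bad <- layer_model(matrix(50, 4, 5), matrix(50, 4, 5), matrix(90, 4, 5))
  expect_error(enface_project(svv, lm_bad), "empty slab")
})

test_that("max reducer picks the slab maximum", {
  sv <- array(1, c(3, 8, 3))
  sv[2, 4, 2] <- 9
  svv <- structure(list(sv = sv, spacing = c(slow = 4, depth = 10, fast = 4)),
                   class = "sv_volume")
  lm <- layer_model(matrix(10, 3, 3), matrix(70, 3, 3), matrix(80, 3, 3))
  ef <- enface_project(svv, lm, reducer = "max")
  expect_equal(ef$pixels[2, 2], 9)
  expect_equal(ef$pixels[1, 1], 1)
})

test_that("centered crop follows the floor convention and is idempotent", {
  img <- enface_image(matrix(runif(300 * 300), 300, 300), pixel_um = 10 / 3)
  # 1000 um FOV at 3.33 um/px, crop 636.5 -> 190 px (floor convention)
  out <- crop_enface(img, 636.5)
  expect_equal(dim(out$pixels), c(190, 190))
  expect_equal(out$pixel_um, img$pixel_um)
  # crop to the full FOV is the identity
  expect_equal(crop_enface(img, 1000)$pixels, img$pixels)
  # idempotent
  expect_equal(crop_enface(out, 636.5)$pixels, out$pixels)
  expect_error(crop_enface(out, 2000), "exceeds")
})

test_that("en-face sv inside the capillary mask exceeds outside", {
  geom <- small_geom(n = 48, fov = 260)
  net <- generate_network("ST", 40, 6, seed = 1, fov_um = 260)
  layers <- retina_layers(geom)
  for (s in 1:5) {
    for (w in c(0.3, 0.6, 0.9)) {
      rnd <- render_oct_volume(net, layers, geom,
                               speckle_params(flow_decorrelation = w, seed = s))
      svv <- speckle_variance(rnd$volume)
      lmod <- layer_model(layers$ilm, layers$rnfl_gcl, layers$rpe)
      ef <- enface_project(svv, lmod)
      fm <- apply(rnd$truth$flow_mask, c(1, 3), any)
      expect_gt(mean(ef$pixels[fm]), mean(ef$pixels[!fm]))
    }
  }
})
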