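# Shared fixtures and independent oracles.
# Fixtures are generated in code at test time; oracles are deliberately
# naive (loops, quadrature, brute-force geometry) and independent of the
# implementation paths they check.

# small scan geometry for fast volume renders
small_geom <- function(n = 72, fov = 400, nz = 96, zrange = 288) {
  scan_geometry(fov_um = fov, n_fast = n, n_slow = n, n_depth = nz,
                depth_range_um = zrange)
}

# the full desk-scale pipeline for one region, criterion-style
pipeline_once <- function(seed, region = "Temp", spacing = 35,
                          waviness = 0, n = 160, fov = 700,
                          bulk_motion_prob = 0, crop = 636.5,
                          offset_um = 120) {
  geom <- scan_geometry(fov_um = fov, n_fast = n, n_slow = n)
  net <- generate_network(region, spacing, 5, seed = seed, fov_um = fov,
                          waviness = waviness)
  rnd <- render_oct_volume(net, retina_layers(geom), geom,
                           speckle_params(seed = seed,
                                          bulk_motion_prob = bulk_motion_prob))
  svv <- speckle_variance(rnd$volume)
  seg <- segment_boundaries(rnd$volume)
  lmod <- derive_rnfl_gcl(seg$ilm, seg$rpe, offset_um,
                          min_slab_um = geom$dz_um)
  ef <- crop_enface(threshold_sv(remove_streaks(enface_project(svv, lmod)),
                                 75), crop)
  list(measure = measure_enface(ef, region, "svOCT"), truth = rnd$truth,
       enface = ef, layers = rnd$truth$layers, seg = seg, geom = geom)
}

# brute-force per-voxel two-pass variance over the repeat axis
variance_loop_oracle <- function(intensity) {
  d <- dim(intensity)
  out <- array(0, d[-1])
  for (y in seq_len(d[2])) for (z in seq_len(d[3])) for (x in seq_len(d[4])) {
    v <- intensity[, y, z, x]
    m <- mean(v)
    s <- 0
    for (t in seq_len(d[1])) s <- s + (v[t] - m)^2
    out[y, z, x] <- s / d[1]
  }
  out
}

# do two 2-D segments intersect?
segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(FALSE)
  s <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
  s >= 0 && s <= 1 && u >= 0 && u <= 1
}

# number of capillaries whose centerline crosses the sampling segment
crossings_oracle <- function(network, center, angle_deg, length_um) {
  th <- angle_deg * pi / 180
  u <- c(cos(th), sin(th))
  a <- center - u * length_um / 2
  b <- center + u * length_um / 2
  hits <- 0
  for (p in network$capillaries) {
    crossed <- FALSE
    for (i in seq_len(nrow(p) - 1)) {
      if (segments_intersect(p[i, 1:2], p[i + 1, 1:2], a, b)) {
        crossed <- TRUE
        break
      }
    }
    if (crossed) hits <- hits + 1
  }
  hits
}

# FWHM of a rectangular profile of width d convolved with a Gaussian of
# FWHM F, by dense numerical convolution
fwhm_convolution_oracle <- function(width_um, psf_fwhm_um, dx = 0.01) {
  x <- seq(-40, 40, by = dx)
  bar <- as.numeric(abs(x) <= width_um / 2)
  if (psf_fwhm_um > 0) {
    s <- psf_fwhm_um / (2 * sqrt(2 * log(2)))
    k <- stats::dnorm(x, sd = s)
    k <- k / sum(k)
    prof <- stats::convolve(bar, rev(k), type = "open")
    prof <- prof[(length(x) + 1) / 2 + seq_along(x) - 1]
  } else prof <- bar
  half <- max(prof) / 2
  diff(range(x[prof >= half]))
}

# retinal arc length by numerical quadrature of the mapped point speed
# |dP/dtheta| = L * dtheta'/dtheta, with dtheta'/dtheta = cos(theta) /
# (n cos(theta')) from differentiating Snell's law
arc_quadrature_oracle <- function(half_angle_deg, eye_length_mm, n_media) {
  f <- function(th) {
    thp <- asin(sin(th) / n_media)
    cos(th) / (n_media * cos(thp))
  }
  th_max <- half_angle_deg * pi / 180
  2 * eye_length_mm * stats::integrate(f, 0, th_max, rel.tol = 1e-10)$value
}

# Gaussian-beam focus into a medium by complex-q (ABCD) propagation:
# collimated waist w_p at a refracting element of power n/f' (posterior
# focal length f' measured inside the medium of index n), then free
# propagation in the medium to the waist (minimal spot).
abcd_waist_oracle <- function(w_pupil_mm, lambda0_nm, f_post_mm, n_medium) {
  lambda_mm <- lambda0_nm * 1e-6
  f_air <- f_post_mm / n_medium   # air-equivalent thin-lens focal length
  q0 <- 1i * pi * w_pupil_mm^2 / lambda_mm          # at the lens (waist)
  q1 <- 1 / (1 / q0 - 1 / f_air)                    # after thin lens
  wz <- function(z) {
    qz <- q1 + z / n_medium   # reduced distance; q carries vacuum lambda
    sqrt(-lambda_mm / (pi * Im(1 / qz)))
  }
  opt <- stats::optimize(wz, c(0.2 * f_post_mm, 2 * f_post_mm))
  opt$objective * 1000   # um
}
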