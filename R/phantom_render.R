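# Rendering of ground-truth networks: histology-style en-face images and
# repeat-frame OCT speckle volumes with a layered retina.

#' Ground-truth retinal layer maps
#'
#' Smooth depth maps for the three boundaries the pipeline uses: the ILM
#' (anterior retinal surface), the RNFL/GCL boundary, and the RPE/BM complex
#' (bright posterior band). Optional linear tilts let tests exercise sloped
#' layers. Depths are micrometres below the top of the imaged depth range.
#'
#' @param geometry a [scan_geometry()] (lateral grid and FOV).
#' @param ilm_um ILM depth at the FOV center.
#' @param rnfl_thickness_um RNFL thickness (RNFL/GCL = ILM + thickness).
#' @param rpe_um RPE/BM depth at the FOV center.
#' @param slope_x,slope_y boundary tilt in um depth per um lateral (applied
#'   to all three boundaries jointly).
#' @param reflectivity named list of mean backscatter levels per layer:
#'   `vitreous`, `rnfl`, `inner` (GCL..RPE), `rpe`, `below`.
#' @param rpe_band_um thickness of the bright RPE band.
#' @return Object of class `retina_layers`: depth matrices `ilm`,
#'   `rnfl_gcl`, `rpe` of size `[n_slow, n_fast]` (micrometres) plus the
#'   reflectivity model.
#' @export
retina_layers <- function(geometry, ilm_um = 50, rnfl_thickness_um = 90,
                          rpe_um = 250, slope_x = 0, slope_y = 0,
                          reflectivity = list(vitreous = 0.02, rnfl = 1,
                                              inner = 0.25, rpe = 1.6,
                                              below = 0.08),
                          rpe_band_um = 20) {
  nx <- geometry$n_fast; ny <- geometry$n_slow
  xs <- (seq_len(nx) - 0.5) * geometry$pixel_um - geometry$fov_um / 2
  ys <- (seq_len(ny) - 0.5) * geometry$pixel_slow_um - geometry$fov_um / 2
  tilt <- outer(ys, xs, function(y, x) slope_x * x + slope_y * y)
  ilm <- ilm_um + tilt
  rnfl_gcl <- ilm + rnfl_thickness_um
  rpe <- rpe_um + tilt
  if (any(ilm >= rnfl_gcl) || any(rnfl_gcl >= rpe))
    stop("layer ordering violated: need ilm < rnfl_gcl < rpe everywhere")
  if (any(ilm < 0) || any(rpe + rpe_band_um > geometry$depth_range_um))
    stop("layer depths exceed the imaged depth range")
  structure(list(ilm = ilm, rnfl_gcl = rnfl_gcl, rpe = rpe,
                 reflectivity = reflectivity, rpe_band_um = rpe_band_um,
                 rnfl_thickness_um = rnfl_thickness_um),
            class = "retina_layers")
}

#' Speckle model parameters
#'
#' Parameters of the repeat-frame speckle synthesis. Static tissue carries a
#' single complex scattering-field realization (Rayleigh amplitude) reused
#' across repeats; voxels inside flowing capillaries mix in an independent
#' field draw per repeat with weight `flow_decorrelation` (repeat-to-repeat
#' field correlation `1 - flow_decorrelation`), so across-repeat intensity
#' variance grows with flow decorrelation while static tissue varies only
#' by the additive noise floor.
#'
#' @param n_repeats repeat B-scans per slow-axis location (>= 2).
#' @param static_scale mean speckle intensity scale of tissue.
#' @param flow_decorrelation mixing weight in `[0, 1]`; 1 = fully
#'   independent speckle per repeat inside flowing capillaries.
#' @param noise_floor additive Gaussian noise SD.
#' @param bulk_motion_prob probability that a slow-axis location suffers a
#'   bulk-motion lateral shift in one repeat (streak artifact).
#' @param bulk_motion_px shift magnitude in fast-axis pixels.
#' @param seed RNG seed; identical seeds give bit-identical volumes.
#' @return Object of class `speckle_params`.
#' @export
speckle_params <- function(n_repeats = 3, static_scale = 1,
                           flow_decorrelation = 0.85, noise_floor = 0.05,
                           bulk_motion_prob = 0, bulk_motion_px = 8,
                           seed = 1) {
  if (n_repeats < 2) stop("'n_repeats' must be >= 2")
  if (flow_decorrelation < 0 || flow_decorrelation > 1)
    stop("'flow_decorrelation' must be in [0, 1]")
  if (noise_floor < 0) stop("'noise_floor' must be >= 0")
  structure(list(n_repeats = as.integer(n_repeats),
                 static_scale = static_scale,
                 flow_decorrelation = flow_decorrelation,
                 noise_floor = noise_floor,
                 bulk_motion_prob = bulk_motion_prob,
                 bulk_motion_px = as.integer(bulk_motion_px),
                 seed = seed),
            class = "speckle_params")
}

# 2-D distance map from pixel centers to the network centerlines, together
# with the index of the nearest capillary. Grid: rows = y (slow), cols = x
# (fast); pixel centers at (i - 0.5) * pixel_um.
network_distance_2d <- function(network, nx, ny, pixel_um) {
  dist <- matrix(Inf, ny, nx)
  idx <- matrix(0L, ny, nx)
  for (ci in seq_along(network$capillaries)) {
    p <- network$capillaries[[ci]]
    r <- network$diameters_um[ci] / 2
    margin <- r + 2 * pixel_um
    for (si in seq_len(nrow(p) - 1)) {
      ax <- p[si, 1]; ay <- p[si, 2]; bx <- p[si + 1, 1]; by <- p[si + 1, 2]
      c0 <- max(1L, floor((min(ax, bx) - margin) / pixel_um + 0.5))
      c1 <- min(nx, ceiling((max(ax, bx) + margin) / pixel_um + 0.5))
      r0 <- max(1L, floor((min(ay, by) - margin) / pixel_um + 0.5))
      r1 <- min(ny, ceiling((max(ay, by) + margin) / pixel_um + 0.5))
      if (c0 > c1 || r0 > r1) next
      cols <- c0:c1; rows <- r0:r1
      px <- rep((cols - 0.5) * pixel_um, each = length(rows))
      py <- rep((rows - 0.5) * pixel_um, times = length(cols))
      d <- point_segment_distance(px, py, ax, ay, bx, by)
      d <- matrix(d, length(rows), length(cols))
      sub_d <- dist[rows, cols, drop = FALSE]
      upd <- d < sub_d
      if (any(upd)) {
        sub_i <- idx[rows, cols, drop = FALSE]
        sub_d[upd] <- d[upd]
        sub_i[upd] <- ci
        dist[rows, cols] <- sub_d
        idx[rows, cols] <- sub_i
      }
    }
  }
  list(dist = dist, idx = idx)
}

#' Render a histology-style en-face image of a network
#'
#' Rasterizes the capillary tubes at their true diameters on a fine pixel
#' grid (foreground 1, background 0) and blurs with a Gaussian PSF of the
#' given FWHM. Histology (confocal) rendering uses a sub-micron PSF; passing
#' the OCT lateral FWHM (~8.6 um) instead produces an idealized svOCT-
#' resolution rendering of the same truth, which is how the in-silico
#' svOCT-vs-histology diameter comparison is built.
#'
#' @param network a [generate_network()] result.
#' @param pixel_um pixel pitch of the rendering, micrometres.
#' @param psf_fwhm_um Gaussian PSF FWHM, micrometres (0 = no blur).
#' @return An [enface_image()] with binary (psf 0) or blurred float pixels.
#' @export
render_histology <- function(network, pixel_um = 0.5, psf_fwhm_um = 0.5) {
  stopifnot_positive(pixel_um)
  if (psf_fwhm_um < 0) stop("'psf_fwhm_um' must be >= 0")
  n <- round(network$fov_um / pixel_um)
  dmap <- network_distance_2d(network, n, n, pixel_um)
  r <- network$diameters_um[pmax(dmap$idx, 1L)] / 2
  # anti-aliased coverage: linear ramp over one pixel across the tube
  # edge, so the summed foreground equals the analytic tube area
  # independent of how the tube aligns with the pixel grid
  img <- matrix(pmin(pmax((r + 0.5 * pixel_um - dmap$dist) / pixel_um, 0), 1),
                n, n)
  img[dmap$idx == 0L] <- 0
  if (psf_fwhm_um > 0) img <- blur_image_fwhm(img, psf_fwhm_um / pixel_um)
  enface_image(img, pixel_um = pixel_um,
               slab = sprintf("truth render (PSF %g um)", psf_fwhm_um))
}

#' Render a repeat-frame svOCT speckle volume of a phantom retina
#'
#' Builds an OCT intensity volume indexed `[repeat, slow, depth, fast]` over
#' a layered retina with the given capillary network embedded in the RNFL.
#' Speckle is synthesized coherently: every voxel holds a circular complex
#' Gaussian scattering field (Rayleigh amplitude, fully developed speckle),
#' static tissue reuses one field realization across repeats (plus the
#' additive noise floor), and voxels inside flowing capillaries mix in a
#' fresh field each repeat with weight `flow_decorrelation`. The *field* is
#' blurred laterally with the beam FWHM and axially with the coherence
#' length from `geometry$optics` before detection, so the speckle grain
#' size follows the PSF at any sampling density. Optional
#' bulk-motion events laterally shift one repeat of a whole B-scan,
#' producing the bright streak rows the en-face streak filter removes.
#'
#' @param network a [generate_network()] result (FOV must not exceed the
#'   geometry FOV).
#' @param layers a [retina_layers()] truth object on the same grid.
#' @param geometry a [scan_geometry()].
#' @param speckle a [speckle_params()].
#' @return A list with `volume` (an `oct_volume`) and `truth` (voxel-level
#'   flow mask `[slow, depth, fast]`, the layer maps, network, and
#'   parameters).
#' @export
render_oct_volume <- function(network, layers, geometry,
                              speckle = speckle_params()) {
  nx <- geometry$n_fast; ny <- geometry$n_slow; nz <- geometry$n_depth
  nr <- speckle$n_repeats
  if (network$fov_um > geometry$fov_um + 1e-9)
    stop(sprintf("network FOV (%g um) exceeds scan FOV (%g um)",
                 network$fov_um, geometry$fov_um))
  if (!isTRUE(all.equal(dim(layers$ilm), c(ny, nx))))
    stop(sprintf("layer maps are %s but the scan grid is %d x %d",
                 paste(dim(layers$ilm), collapse = " x "), ny, nx))
  if (max(layers$rpe) + layers$rpe_band_um > geometry$depth_range_um)
    stop("depth range does not cover the RPE band")

  z_um <- (seq_len(nz) - 0.5) * geometry$dz_um

  # mean reflectivity template [y, z, x] from the layer model
  refl <- layers$reflectivity
  mu <- array(refl$below, c(ny, nz, nx))
  Z <- array(rep(z_um, each = ny), c(ny, nz, nx))
  expand_map <- function(m) {
    a <- array(0, c(ny, nz, nx))
    for (k in seq_len(nz)) a[, k, ] <- m
    a
  }
  ILM <- expand_map(layers$ilm)
  RNFLG <- expand_map(layers$rnfl_gcl)
  RPE <- expand_map(layers$rpe)
  mu[Z < ILM] <- refl$vitreous
  mu[Z >= ILM & Z < RNFLG] <- refl$rnfl
  mu[Z >= RNFLG & Z < RPE] <- refl$inner
  mu[Z >= RPE & Z < RPE + layers$rpe_band_um] <- refl$rpe
  mu <- mu * speckle$static_scale

  # voxel-level flow fraction from the 3-D tube geometry: at each lateral
  # pixel within the tube radius the tube spans depths zc +/- sqrt(r^2 -
  # d^2); each depth voxel receives the fraction of its extent covered by
  # that span (partial volume), so capillaries thinner than a depth voxel
  # still decorrelate in proportion to their overlap
  dz <- geometry$dz_um
  offset <- (geometry$fov_um - network$fov_um) / 2
  net_shift <- shift_network(network, offset)
  dmap <- network_distance_2d(net_shift, nx, ny, geometry$pixel_um)
  flow_frac <- array(0, c(ny, nz, nx))
  zc <- vapply(net_shift$capillaries, function(p) p[1, 3], numeric(1))
  for (ci in seq_along(net_shift$capillaries)) {
    if (!net_shift$flow[ci]) next
    r <- net_shift$diameters_um[ci] / 2
    sel <- which(dmap$idx == ci & dmap$dist < r, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    hz <- sqrt(pmax(r^2 - dmap$dist[sel]^2, 0))
    for (j in seq_len(nrow(sel))) {
      zlo <- zc[ci] - hz[j]; zhi <- zc[ci] + hz[j]
      zk <- which(z_um + dz / 2 > zlo & z_um - dz / 2 < zhi)
      if (!length(zk)) next
      ov <- (pmin(z_um[zk] + dz / 2, zhi) - pmax(z_um[zk] - dz / 2, zlo)) / dz
      flow_frac[sel[j, 1], zk, sel[j, 2]] <-
        pmax(flow_frac[sel[j, 1], zk, sel[j, 2]], ov)
    }
  }
  flow_mask <- flow_frac > 0

  # Coherent speckle synthesis. Each voxel carries a circular complex
  # Gaussian scattering field with variance equal to the local reflectivity
  # mu, so the detected amplitude is Rayleigh and the intensity |E|^2 is
  # fully developed speckle (contrast 1). Static tissue reuses one field
  # realization across repeats; inside flowing capillaries the repeat-t
  # field is sqrt(1-w) E_static + sqrt(w) E_t with fresh draws E_t, giving
  # repeat-to-repeat field correlation (1-w). The PSF acts on the *field*
  # (amplitude), not the intensity, so speckle grain follows the PSF and
  # the decorrelation contrast does not wash out at fine sampling; the
  # blurred field is renormalized so mean intensity stays at mu.
  nvox <- ny * nz * nx
  w <- speckle$flow_decorrelation
  fm <- which(flow_frac > 0)
  fw <- as.vector(flow_frac)[fm] * w   # effective decorrelation per voxel
  vol <- array(0, c(nr, ny, nz, nx))
  s_lat_x <- fwhm_to_sigma(geometry$optics$lateral_fwhm_um) / geometry$pixel_um
  s_lat_y <- fwhm_to_sigma(geometry$optics$lateral_fwhm_um) /
    geometry$pixel_slow_um
  s_ax <- fwhm_to_sigma(geometry$optics$coherence_length_um) / geometry$dz_um
  # field-variance gain of the blur, for renormalization
  gain <- prod(vapply(c(s_lat_y, s_ax, s_lat_x),
                      function(s) sum(gauss_kernel(s)^2), numeric(1)))
  with_seed(speckle$seed, {
    sdev <- sqrt(mu / 2)
    es_re <- sdev * stats::rnorm(nvox)
    es_im <- sdev * stats::rnorm(nvox)
    hit <- stats::runif(ny) < speckle$bulk_motion_prob
    which_rep <- sample.int(nr, ny, replace = TRUE)
    for (t in seq_len(nr)) {
      ef_re <- sdev * stats::rnorm(nvox)
      ef_im <- sdev * stats::rnorm(nvox)
      re <- es_re; im <- es_im
      re[fm] <- sqrt(1 - fw) * es_re[fm] + sqrt(fw) * ef_re[fm]
      im[fm] <- sqrt(1 - fw) * es_im[fm] + sqrt(fw) * ef_im[fm]
      re <- array(re, c(ny, nz, nx)); im <- array(im, c(ny, nz, nx))
      # bulk motion: the hit B-scan of one randomly chosen repeat is
      # shifted laterally by bulk_motion_px (replicate boundary)
      for (yy in which(hit & which_rep == t)) {
        re[yy, , ] <- shift_dim(re[yy, , ], 2L, speckle$bulk_motion_px)
        im[yy, , ] <- shift_dim(im[yy, , ], 2L, speckle$bulk_motion_px)
      }
      for (dd in c(1L, 2L, 3L)) {
        s <- c(s_lat_y, s_ax, s_lat_x)[dd]
        re <- blur_dim(re, dd, s)
        im <- blur_dim(im, dd, s)
      }
      rep_t <- (re * re + im * im) / gain
      if (speckle$noise_floor > 0)
        rep_t <- pmax(rep_t + stats::rnorm(nvox, sd = speckle$noise_floor), 0)
      vol[t, , , ] <- rep_t
    }
  })

  volume <- oct_volume(vol, spacing = c(slow = geometry$pixel_slow_um,
                                        depth = geometry$dz_um,
                                        fast = geometry$pixel_um),
                       geometry = geometry)
  truth <- list(flow_mask = flow_mask, flow_frac = flow_frac,
                layers = layers, network = net_shift, speckle = speckle,
                z_um = z_um)
  list(volume = volume, truth = truth)
}

# Translate a network laterally (used to center a small-FOV network in a
# larger scan FOV).
shift_network <- function(network, offset_um) {
  if (offset_um == 0) return(network)
  net <- network
  net$capillaries <- lapply(network$capillaries, function(p) {
    p[, 1] <- p[, 1] + offset_um
    p[, 2] <- p[, 2] + offset_um
    p
  })
  net$fov_um <- network$fov_um + 2 * offset_um
  net
}

#' OCT intensity volume container
#'
#' Repeat-resolved intensity volume indexed `[repeat, slow, depth, fast]`
#' with physical pixel spacing in micrometres.
#'
#' @param intensity 4-D non-negative array `[repeat, slow, depth, fast]`.
#' @param spacing named numeric vector `c(slow=, depth=, fast=)`, um/px.
#' @param geometry optional [scan_geometry()] kept as metadata.
#' @return Object of class `oct_volume`.
#' @export
oct_volume <- function(intensity, spacing, geometry = NULL) {
  if (length(dim(intensity)) != 4)
    stop("'intensity' must be a 4-D array [repeat, slow, depth, fast]")
  if (dim(intensity)[1] < 2) stop("need at least 2 repeats")
  if (any(intensity < 0)) stop("'intensity' must be non-negative")
  structure(list(intensity = intensity, spacing = spacing,
                 n_repeats = dim(intensity)[1], geometry = geometry),
            class = "oct_volume")
}

#' @exportS3Method base::print
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("oct_volume: %d repeats x %d slow x %d depth x %d fast\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing (um/px): slow %.3g, depth %.3g, fast %.3g\n",
              x$spacing[["slow"]], x$spacing[["depth"]], x$spacing[["fast"]]))
  invisible(x)
}
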