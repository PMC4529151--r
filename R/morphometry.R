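# Capillary morphometry on en-face images: binarization, dominant
# orientation, crossing counts along a perpendicular sampling line,
# density / inter-capillary distance, and per-vessel diameters.
#
# The manual protocol these estimators reproduce: draw a straight line
# through the image center perpendicular to the capillaries' orientation,
# count the capillaries crossing it, express the count per 100 um
# (density) and the line length per crossing (ICD), and measure each
# vessel's width across its widest perpendicular profile.

#' Binarize an en-face capillary image
#'
#' Gaussian-smooths by 1 px and applies Otsu's threshold computed on the
#' nonzero pixels (zeros are the thresholded-out background and would bias
#' the histogram). With `method = "otsu-log"` the histogram is taken on
#' the log scale, which balances the classes when the foreground is
#' heavy-tailed (speckle-variance angiograms span decades; a linear
#' histogram then puts the threshold inside the vessel class and drops
#' dim vessel stretches). Deterministic. A foreground fraction above one
#' half triggers a contrast-convention warning.
#'
#' @param enface an [enface_image()].
#' @param smooth_sigma_px pre-smoothing SD in pixels.
#' @param method `"otsu"` (linear histogram) or `"otsu-log"`.
#' @return An [enface_image()] with 0/1 pixels; the threshold used is
#'   attached as attribute `"threshold"`.
#' @export
binarize <- function(enface, smooth_sigma_px = 1,
                     method = c("otsu", "otsu-log")) {
  method <- match.arg(method)
  if (!inherits(enface, "enface_image"))
    stop("'enface' must be an enface_image")
  px <- enface$pixels
  if (length(px) == 0 || diff(range(px)) == 0)
    stop("cannot binarize an empty or constant image")
  if (smooth_sigma_px > 0)
    px <- blur_dim(blur_dim(px, 1L, smooth_sigma_px), 2L, smooth_sigma_px)
  vals <- px[px > 0]
  if (length(vals) < 2 ||
      (diff(range(vals)) == 0 && !any(px == 0)))
    stop("cannot binarize: nonzero pixels are constant")
  # exactly two levels (0 / c): the zero level is background
  thr <- if (diff(range(vals)) == 0) {
    vals[1] / 2
  } else if (method == "otsu-log") {
    exp(otsu_threshold(log(vals)))
  } else otsu_threshold(vals)
  bin <- matrix(as.numeric(px > thr), nrow(px), ncol(px))
  if (mean(bin) > 0.5)
    warning(sprintf(
      "foreground fraction %.2f > 0.5: image contrast may be inverted",
      mean(bin)))
  out <- enface_image(bin, pixel_um = enface$pixel_um,
                      slab = paste(enface$slab, "(binary)"))
  attr(out, "threshold") <- thr
  out
}

# Otsu's threshold (maximum between-class variance) on a 256-bin histogram.
otsu_threshold <- function(vals, n_bins = 256L) {
  rng <- range(vals)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(vals, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Dominant orientation of a vessel image
#'
#' Length-weighted mean orientation in `[0, 180)` degrees of the
#' foreground structures, from the image structure tensor (summed outer
#' product of the smoothed intensity gradient): the dominant *vessel*
#' direction is perpendicular to the dominant gradient direction. Angles
#' are measured from the +x (fast) axis toward +y (slow).
#'
#' @param enface an [enface_image()] (binary or grayscale).
#' @param smooth_sigma_px gradient pre-smoothing SD in pixels.
#' @param min_coherence minimum structure-tensor coherence (0..1); below
#'   this the image is effectively isotropic and an error suggests passing
#'   an explicit angle.
#' @return Angle in degrees in `[0, 180)`, with the coherence attached as
#'   attribute `"coherence"`.
#' @export
dominant_orientation <- function(enface, smooth_sigma_px = 2,
                                 min_coherence = 0.2) {
  px <- enface$pixels
  if (all(px == 0)) stop("foreground is empty")
  if (smooth_sigma_px > 0)
    px <- blur_dim(blur_dim(px, 1L, smooth_sigma_px), 2L, smooth_sigma_px)
  gx <- (shift_dim(px, 2L, -1L) - shift_dim(px, 2L, 1L)) / 2
  gy <- (shift_dim(px, 1L, -1L) - shift_dim(px, 1L, 1L)) / 2
  jxx <- sum(gx * gx); jyy <- sum(gy * gy); jxy <- sum(gx * gy)
  coh <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / max(jxx + jyy, 1e-12)
  if (coh < min_coherence)
    stop(sprintf(
      "image is nearly isotropic (coherence %.3f < %g); supply the sampling-line angle manually",
      coh, min_coherence))
  grad_angle <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  ang <- (grad_angle + 90) %% 180
  attr(ang, "coherence") <- coh
  ang
}

#' Count capillary crossings along a sampling line
#'
#' Samples the (binary) image by bilinear interpolation at quarter-pixel
#' steps along a straight line and counts maximal foreground runs at least
#' one pixel long; each run is one capillary crossing. The line runs
#' through `center` at `angle_deg` and is clipped to the image bounds.
#'
#' @param binary a binarized [enface_image()] (values in `[0, 1]`).
#' @param angle_deg line angle, degrees from +x; typically the dominant
#'   vessel orientation + 90.
#' @param center line center `(x, y)` in micrometres; `NULL` = image
#'   center.
#' @param length_um line length; `NULL` = maximal within the image.
#' @param step_px sampling step in pixels.
#' @return Object of class `sampling_line`: `center`, `angle_deg`,
#'   `length_um`, and `crossings_um`, the sorted crossing positions along
#'   the line (micrometres from its start).
#' @export
count_crossings <- function(binary, angle_deg, center = NULL,
                            length_um = NULL, step_px = 0.25) {
  px <- binary$pixels
  pu <- binary$pixel_um
  ny <- nrow(px); nx <- ncol(px)
  if (is.null(center)) center <- c(nx, ny) / 2 * pu
  theta <- angle_deg * pi / 180
  u <- c(cos(theta), sin(theta))
  # clip half-lengths to the image bounds (um); pixel centers span
  # [0.5, n - 0.5] px
  lim <- function(dir) {
    ts <- c()
    for (k in 1:2) {
      if (abs(u[k]) > 1e-12) {
        bounds_um <- c(0.5, c(nx, ny)[k] - 0.5) * pu
        ts <- c(ts, (bounds_um - center[k]) / (dir * u[k]))
      }
    }
    max(0, min(ts[ts >= 0]))
  }
  t_neg <- lim(-1); t_pos <- lim(1)
  if (!is.null(length_um)) {
    t_neg <- min(t_neg, length_um / 2)
    t_pos <- min(t_pos, length_um / 2)
  }
  len <- t_neg + t_pos
  if (len <= 0) stop("sampling line has zero length inside the image")
  step_um <- step_px * pu
  ts <- seq(-t_neg, t_pos, by = step_um)
  sx <- (center[1] + ts * u[1]) / pu + 0.5
  sy <- (center[2] + ts * u[2]) / pu + 0.5
  vals <- bilinear_sample(px, sx, sy)
  fg <- vals >= 0.5
  runs <- rle(fg)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & (runs$lengths * step_um >= pu)
  cross <- (ts[starts[keep]] + ts[ends[keep]]) / 2 + t_neg
  structure(list(center = center, angle_deg = angle_deg %% 360,
                 length_um = len, crossings_um = sort(cross),
                 n_crossings = sum(keep)),
            class = "sampling_line")
}

#' @exportS3Method base::print
print.sampling_line <- function(x, ...) {
  cat(sprintf("sampling_line: %.1f um at %.1f deg, %d crossings\n",
              x$length_um, x$angle_deg, x$n_crossings))
  invisible(x)
}

#' Capillary density and inter-capillary distance from a sampling line
#'
#' Density is the number of crossings per 100 um of line
#' (`100 * n / length`); the inter-capillary distance (ICD) is the line
#' length divided by the number of crossings, so `density * ICD = 100`
#' identically. Zero crossings give density 0 and an undefined (NA,
#' flagged) ICD.
#'
#' @param line a [count_crossings()] result.
#' @param region_label,technique optional annotations carried through to
#'   the result.
#' @return Object of class `morphometry_result` (without diameters).
#' @export
density_and_icd <- function(line, region_label = NA_character_,
                            technique = NA_character_) {
  n <- line$n_crossings
  density <- 100 * n / line$length_um
  icd <- if (n >= 1) line$length_um / n else NA_real_
  structure(list(n_crossings = n, length_um = line$length_um,
                 density_per_100um = density, icd_um = icd,
                 icd_defined = n >= 1, diameters_um = numeric(0),
                 region_label = region_label, technique = technique,
                 line = line),
            class = "morphometry_result")
}

#' @exportS3Method base::print
print.morphometry_result <- function(x, ...) {
  cat(sprintf("morphometry_result%s%s\n",
              if (!is.na(x$region_label)) paste0(" [", x$region_label, "]") else "",
              if (!is.na(x$technique)) paste0(" (", x$technique, ")") else ""))
  cat(sprintf("  %d crossings over %.1f um -> density %.2f /100um, ICD %s um\n",
              x$n_crossings, x$length_um, x$density_per_100um,
              if (x$icd_defined) sprintf("%.1f", x$icd_um) else "undefined"))
  if (length(x$diameters_um))
    cat(sprintf("  diameter: %.2f um (mean of %d vessels)\n",
                mean(x$diameters_um), length(x$diameters_um)))
  invisible(x)
}

#' Per-vessel capillary diameters
#'
#' Identifies vessel segments as connected foreground components, takes
#' each segment's widest point (maximum of the distance transform), and
#' measures the full width at half maximum of the grayscale intensity
#' profile sampled perpendicular to the local vessel orientation through
#' that point (`mode = "fwhm"`), or the foreground run length through the
#' point on the binary mask (`mode = "binary"`). Profiles that are not
#' unimodal around the center are skipped and counted in the
#' `"n_skipped"` attribute.
#'
#' @param enface grayscale [enface_image()] used for the FWHM profile.
#' @param binary binarized [enface_image()]; computed with [binarize()]
#'   defaults when `NULL`.
#' @param mode `"fwhm"` (grayscale) or `"binary"` (run length).
#' @param min_component_px minimum component size considered a vessel.
#' @param profile_halfwidth_um half-length of the sampled profile.
#' @return Numeric vector of per-vessel diameters (micrometres) with
#'   attribute `"n_skipped"`.
#' @export
capillary_diameter <- function(enface, binary = NULL,
                               mode = c("fwhm", "binary"),
                               min_component_px = 30,
                               profile_halfwidth_um = 20) {
  mode <- match.arg(mode)
  if (is.null(binary)) binary <- binarize(enface)
  bw <- binary$pixels
  pu <- binary$pixel_um
  lab <- EBImage::bwlabel(t(bw))            # EBImage uses [x, y]
  lab <- t(EBImage::imageData(lab))
  dmap <- t(EBImage::imageData(EBImage::distmap(t(bw))))
  n_lab <- max(lab)
  if (n_lab < 1) stop("no vessel segments found")
  diam <- numeric(0); skipped <- 0L
  for (li in seq_len(n_lab)) {
    sel <- which(lab == li)
    if (length(sel) < min_component_px) next
    # widest point: among near-maximal distance-transform pixels, prefer
    # the most central one (the distance map degenerates at image borders)
    cand <- sel[dmap[sel] >= max(dmap[sel]) - 0.5]
    ij_all <- arrayInd(cand, dim(bw))
    ctr <- dim(bw) / 2
    at <- cand[which.min((ij_all[, 1] - ctr[1])^2 + (ij_all[, 2] - ctr[2])^2)]
    ij <- arrayInd(at, dim(bw))
    d <- measure_profile_diameter(
      if (mode == "fwhm") enface$pixels else bw,
      bw, ij[1], ij[2], pu, profile_halfwidth_um, mode,
      half_width_px = dmap[at])
    if (is.na(d)) skipped <- skipped + 1L else diam <- c(diam, d)
  }
  if (skipped > 0)
    warning(sprintf("%d vessel profile(s) skipped (not unimodal)", skipped))
  attr(diam, "n_skipped") <- skipped
  diam
}

# Diameter from the perpendicular profile through (row, col).
# half_width_px: local mask half-width (distance-transform value), used to
# size the orientation window so it always reaches past the vessel edges.
measure_profile_diameter <- function(gray, bw, row, col, pixel_um,
                                     halfwidth_um, mode,
                                     half_width_px = 3) {
  # local vessel orientation from the structure tensor in a window wide
  # enough to contain both vessel edges
  w <- max(8L, ceiling(2.5 * half_width_px))
  r0 <- max(1, row - w); r1 <- min(nrow(bw), row + w)
  c0 <- max(1, col - w); c1 <- min(ncol(bw), col + w)
  win <- bw[r0:r1, c0:c1, drop = FALSE]
  ang <- tryCatch(
    dominant_orientation(enface_image(win, pixel_um), smooth_sigma_px = 1,
                         min_coherence = 0),
    error = function(e) NA_real_)
  if (is.na(ang)) return(NA_real_)
  perp <- (ang + 90) * pi / 180
  step <- 0.25
  ts <- seq(-halfwidth_um / pixel_um, halfwidth_um / pixel_um, by = step)
  sx <- col + ts * cos(perp)
  sy <- row + ts * sin(perp)
  prof <- bilinear_sample(gray, sx, sy)
  if (mode == "binary") {
    fg <- prof >= 0.5
    # run containing the center
    ctr <- which.min(abs(ts))
    if (!fg[ctr]) return(NA_real_)
    l <- ctr; while (l > 1 && fg[l - 1]) l <- l - 1
    r <- ctr; while (r < length(fg) && fg[r + 1]) r <- r + 1
    return((r - l + 1) * step * pixel_um)
  }
  # FWHM around the central peak, baseline 0
  ctr <- which.min(abs(ts))
  lo <- max(1, ctr - 8L); hi <- min(length(prof), ctr + 8L)
  pk_idx <- lo - 1L + which.max(prof[lo:hi])
  peak <- prof[pk_idx]
  if (peak <= 0) return(NA_real_)
  half <- peak / 2
  # walk outward from the peak to the half-maximum crossings, with linear
  # interpolation at the crossing
  left <- NA_real_; right <- NA_real_
  i <- pk_idx
  while (i > 1) {
    if (prof[i - 1] <= half) {
      f <- (prof[i] - half) / (prof[i] - prof[i - 1])
      left <- ts[i] - f * step
      break
    }
    i <- i - 1
  }
  i <- pk_idx
  while (i < length(prof)) {
    if (prof[i + 1] <= half) {
      f <- (prof[i] - half) / (prof[i] - prof[i + 1])
      right <- ts[i] + f * step
      break
    }
    i <- i + 1
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  # unimodality check: no dip below half between the crossings
  seg <- prof[ts >= left & ts <= right]
  if (any(seg < half - 1e-9)) return(NA_real_)
  (right - left) * pixel_um
}

#' Smooth an en-face image along a given orientation
#'
#' One-dimensional Gaussian smoothing along the vessel direction (a
#' matched filter for line-like structures): averaging along the vessel
#' suppresses the speckle-induced beading of svOCT capillaries without
#' widening them perpendicular to their course.
#'
#' @param enface an [enface_image()].
#' @param angle_deg direction to smooth along, degrees from +x.
#' @param sigma_um Gaussian SD along the direction, micrometres.
#' @return The smoothed [enface_image()].
#' @export
smooth_along <- function(enface, angle_deg, sigma_um = 30) {
  img <- enface$pixels
  sigma_px <- sigma_um / enface$pixel_um
  th <- angle_deg * pi / 180
  u <- c(cos(th), sin(th))
  r <- ceiling(3 * sigma_px)
  w <- stats::dnorm(-r:r, sd = sigma_px)
  w <- w / sum(w)
  ny <- nrow(img); nx <- ncol(img)
  xs <- rep(seq_len(nx), each = ny)
  ys <- rep(seq_len(ny), times = nx)
  out <- 0
  for (k in -r:r)
    out <- out + w[k + r + 1] * bilinear_sample(img, xs + k * u[1],
                                                ys + k * u[2])
  enface$pixels <- matrix(out, ny, nx)
  enface
}

#' Close vessel gaps along the dominant orientation
#'
#' Morphological closing with a line structuring element oriented along
#' the vessels. svOCT capillaries appear beaded (speckle-modulated
#' varicosities), and a reader counting crossings connects the beads by
#' eye; closing along the vessel direction is the algorithmic equivalent.
#' Closing along the vessels does not merge adjacent parallel capillaries,
#' which are separated perpendicular to the closing direction.
#'
#' @param binary a binarized [enface_image()].
#' @param angle_deg vessel orientation in degrees.
#' @param close_um length of the line element in micrometres.
#' @return The closed binary [enface_image()].
#' @export
close_vessel_mask <- function(binary, angle_deg, close_um = 70) {
  len <- max(3L, round(close_um / binary$pixel_um))
  if (len %% 2L == 0L) len <- len + 1L
  off <- line_offsets(len, angle_deg)
  dil <- morph_line(binary$pixels, off, pmax)
  binary$pixels <- morph_line(dil, off, pmin)
  binary
}

# unique integer (dx, dy) offsets of a rasterized line of the given length
# through the origin at the given angle (any angle in [0, 180))
line_offsets <- function(len, angle_deg) {
  h <- (len - 1) / 2
  th <- angle_deg * pi / 180
  t_seq <- seq(-h, h, by = 0.5)
  unique(cbind(dx = round(t_seq * cos(th)), dy = round(t_seq * sin(th))))
}

# grayscale dilation (op = pmax) / erosion (op = pmin) of a matrix by a
# set of offsets, replicate boundary
morph_line <- function(img, off, op) {
  out <- NULL
  for (i in seq_len(nrow(off))) {
    sh <- shift_dim(shift_dim(img, 1L, off[i, "dy"]), 2L, off[i, "dx"])
    out <- if (is.null(out)) sh else op(out, sh)
  }
  out
}

#' Full morphometry of one en-face image
#'
#' Runs the whole measurement protocol: estimate the dominant capillary
#' orientation from the smoothed grayscale image, smooth the
#' grayscale image along that orientation ([smooth_along()], suppressing
#' speckle beading), re-binarize, optionally close residual gaps, place
#' the sampling line through the image center perpendicular to the
#' vessels, count crossings, compute density and ICD, and measure
#' per-vessel diameters (on the original grayscale image, at widest
#' points of the mask).
#'
#' @param enface grayscale [enface_image()].
#' @param region_label,technique annotations for the result row.
#' @param angle_deg optional explicit dominant-orientation override.
#' @param smooth_sigma_px isotropic pre-smoothing for the orientation
#'   estimate ([binarize()]).
#' @param match_sigma_um matched-filter SD along the vessels
#'   ([smooth_along()]; 0 disables).
#' @param close_um gap-closing length along the vessels
#'   ([close_vessel_mask()]; 0 disables).
#' @param diameter_mode passed to [capillary_diameter()].
#' @param line_offsets_um sampling-line placements: offsets of the line
#'   center along the vessel direction; the crossing counts are averaged
#'   (so `n_crossings` in the result may be fractional), mirroring the
#'   manual protocol of averaging several counts.
#' @param binarize_method [binarize()] method; the log-scale Otsu default
#'   suits heavy-tailed speckle-variance angiograms.
#' @return A `morphometry_result` with diameters filled in.
#' @export
measure_enface <- function(enface, region_label = NA_character_,
                           technique = NA_character_, angle_deg = NULL,
                           smooth_sigma_px = 2, match_sigma_um = 30,
                           close_um = 30, diameter_mode = "fwhm",
                           line_offsets_um = c(-30, -15, 0, 15, 30),
                           binarize_method = "otsu-log") {
  ang <- angle_deg %||%
    dominant_orientation(enface, smooth_sigma_px = smooth_sigma_px)
  ang <- as.numeric(ang)
  # a matched-filtered mask of a dense network can legitimately exceed
  # one-half foreground; the inversion warning is not informative here
  bin <- withCallingHandlers({
    if (match_sigma_um > 0) {
      binarize(smooth_along(enface, ang, match_sigma_um),
               smooth_sigma_px = 0, method = binarize_method)
    } else {
      binarize(enface, smooth_sigma_px = smooth_sigma_px,
               method = binarize_method)
    }
  }, warning = function(w) {
    if (grepl("foreground fraction", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  if (close_um > 0) bin <- close_vessel_mask(bin, ang, close_um)
  # cap the line length at the image width so an oblique line does not
  # reach the image corners, where the radial network is clipped
  max_len <- min(dim(bin$pixels)) * bin$pixel_um
  # the counting protocol averages several line placements: shift the
  # sampling line along the vessel direction and average the counts, so a
  # local gap in one cross-section does not drop a whole capillary
  ctr <- rev(dim(bin$pixels)) / 2 * bin$pixel_um   # (x, y)
  u <- c(cos(ang * pi / 180), sin(ang * pi / 180))
  lines <- lapply(line_offsets_um, function(o)
    count_crossings(bin, angle_deg = ang + 90,
                    center = ctr + o * u, length_um = max_len))
  line <- lines[[ceiling(length(lines) / 2)]]
  n_eff <- mean(vapply(lines, function(l) l$n_crossings, numeric(1)))
  res <- density_and_icd(line, region_label = region_label,
                         technique = technique)
  res$n_crossings <- n_eff
  res$density_per_100um <- 100 * n_eff / line$length_um
  res$icd_um <- if (n_eff > 0) line$length_um / n_eff else NA_real_
  res$icd_defined <- n_eff > 0
  res$diameters_um <- tryCatch(
    suppressWarnings(capillary_diameter(enface, bin, mode = diameter_mode)),
    error = function(e) numeric(0))
  res$dominant_angle <- ang
  res
}
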