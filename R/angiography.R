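# Speckle-variance flow contrast: per-voxel variance across repeat B-scans,
# percentile thresholding, streak-artifact attenuation, and en-face slab
# projection between segmented layer boundaries.

#' En-face image container
#'
#' A 2-D non-negative float image indexed `[slow, fast]` with its pixel
#' pitch and a free-text descriptor of the depth slab it summarizes.
#'
#' @param pixels numeric matrix `[slow, fast]`, values >= 0.
#' @param pixel_um lateral pixel pitch, micrometres.
#' @param slab slab descriptor (layer names or "truth render ...").
#' @return Object of class `enface_image`.
#' @export
enface_image <- function(pixels, pixel_um, slab = "") {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  if (any(pixels < 0)) stop("'pixels' must be non-negative")
  stopifnot_positive(pixel_um)
  structure(list(pixels = pixels, pixel_um = pixel_um, slab = slab),
            class = "enface_image")
}

#' @exportS3Method base::print
print.enface_image <- function(x, ...) {
  cat(sprintf("enface_image: %d x %d px at %.3g um/px (%.4g x %.4g um)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_um,
              nrow(x$pixels) * x$pixel_um, ncol(x$pixels) * x$pixel_um))
  if (nzchar(x$slab)) cat(sprintf("  slab: %s\n", x$slab))
  invisible(x)
}

#' @export
plot.enface_image <- function(x, ...) {
  img <- x$pixels
  graphics::image(t(img)[, nrow(img):1], asp = nrow(img) / ncol(img),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE, ...)
  invisible(x)
}

#' Speckle variance across repeat B-scans
#'
#' Per-voxel population variance of intensity across the repeat axis,
#' \eqn{sv = (1/N) \sum_t (I_t - \bar I)^2}. Flowing blood decorrelates the
#' speckle pattern between repeats, so sv is high inside perfused vessels
#' and low in static tissue. Population (1/N) normalization is used; all sv
#' invariants (permutation, additive shift, quadratic scaling) are
#' normalization-independent.
#'
#' @param volume an [oct_volume()] with `n_repeats >= 2`.
#' @return Object of class `sv_volume`: list with `sv` (3-D array
#'   `[slow, depth, fast]`) and `spacing`.
#' @export
speckle_variance <- function(volume) {
  if (!inherits(volume, "oct_volume")) stop("'volume' must be an oct_volume")
  nr <- volume$n_repeats
  if (nr < 2) stop("speckle variance needs at least 2 repeats")
  d <- dim(volume$intensity)
  m <- matrix(volume$intensity, nrow = nr)
  mu <- colMeans(m)
  sv <- numeric(length(mu))
  for (t in seq_len(nr)) sv <- sv + (m[t, ] - mu)^2
  sv <- sv / nr
  structure(list(sv = array(sv, d[-1]), spacing = volume$spacing),
            class = "sv_volume")
}

#' @exportS3Method base::print
print.sv_volume <- function(x, ...) {
  d <- dim(x$sv)
  cat(sprintf("sv_volume: %d slow x %d depth x %d fast\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Threshold out low speckle-variance values
#'
#' Sets values strictly below the given percentile of the *nonzero* values
#' to zero, leaving everything else (including ties at the threshold)
#' unchanged. This reproduces, deterministically, the interactive
#' brightness/contrast suppression of low sv values.
#'
#' @param x an `sv_volume` or [enface_image()].
#' @param percentile percentile in `[0, 100)` of the nonzero values.
#' @return Same type as `x`.
#' @export
threshold_sv <- function(x, percentile = 75) {
  if (percentile < 0 || percentile >= 100)
    stop("'percentile' must be in [0, 100)")
  apply_vals <- function(v) {
    nz <- v[v > 0]
    if (length(nz) == 0) return(v)
    thr <- stats::quantile(nz, percentile / 100, names = FALSE, type = 7)
    v[v < thr] <- 0
    v
  }
  if (inherits(x, "sv_volume")) {
    x$sv <- array(apply_vals(as.vector(x$sv)), dim(x$sv))
  } else if (inherits(x, "enface_image")) {
    x$pixels <- matrix(apply_vals(as.vector(x$pixels)),
                       nrow(x$pixels), ncol(x$pixels))
  } else stop("'x' must be an sv_volume or enface_image")
  x
}

#' Attenuate bulk-motion streak rows in an en-face image
#'
#' Bulk motion at a single B-scan location decorrelates the whole frame and
#' produces a bright row across the en-face angiogram. Rows (slow-axis
#' lines) whose median exceeds the global row-median by more than
#' `k` robust SDs (MAD) *and* twice the 90th-percentile row median are
#' flagged as streaks; the flagged band (plus `neighbor_rows` rows on each
#' side, reached by the slow-axis PSF) is reconstructed by linear
#' interpolation between the nearest clean rows, which suppresses the
#' streak while restoring the vessels crossing the band. All other rows
#' are untouched, preserving vessel-scale structure. The amplitude floor
#' keeps capillaries that happen to run along the fast axis (and hence
#' also brighten whole rows, but only by the slab-diluted vessel signal)
#' from being mistaken for streaks. Apply this to the raw (unthresholded)
#' en-face projection: after percentile thresholding most row medians are
#' zero and streak statistics are no longer meaningful.
#'
#' @param enface an [enface_image()].
#' @param k flag threshold in MAD units (default 3).
#' @param neighbor_rows how many rows on each side of a flagged row are
#'   also rescaled (the slow-axis PSF spreads a streak into neighbours).
#' @return An [enface_image()] with flagged rows attenuated; attributes
#'   `"streak_rows"` (flagged) and `"corrected_rows"` (flagged plus
#'   neighbours actually rescaled) list the indices.
#' @export
remove_streaks <- function(enface, k = 3, neighbor_rows = 2) {
  if (!inherits(enface, "enface_image"))
    stop("'enface' must be an enface_image")
  px <- enface$pixels
  m <- apply(px, 1, stats::median)
  M <- stats::median(m)
  # guard against a degenerate MAD (many identical row medians)
  s <- max(stats::mad(m), 1e-12)
  # amplitude floor: capillaries lying along the fast axis also elevate
  # their row median, but only a whole-frame decorrelation (true streak)
  # exceeds the bulk of the row-median distribution by a large factor
  floor_amp <- 2 * stats::quantile(m, 0.9, names = FALSE)
  flag <- which(m > pmax(M + k * s, floor_amp) & m > 0)
  # a bulk-motion event decorrelates its whole B-scan (and, through the
  # slow-axis PSF, leaks into adjacent rows), so no vessel signal is
  # recoverable in place: the flagged band is reconstructed by linear
  # interpolation between the nearest clean rows, which restores vessels
  # crossing the band
  correct <- sort(unique(as.vector(outer(flag, -neighbor_rows:neighbor_rows,
                                         `+`))))
  correct <- correct[correct >= 1 & correct <= nrow(px)]
  if (length(correct)) {
    clean <- setdiff(seq_len(nrow(px)), correct)
    if (length(clean) >= 2) {
      for (j in seq_len(ncol(px))) {
        px[correct, j] <- stats::approx(clean, px[clean, j], xout = correct,
                                        rule = 2)$y
      }
    } else {
      for (i in correct) px[i, ] <- px[i, ] * (M / max(m[i], 1e-12))
    }
  }
  enface$pixels <- px
  attr(enface, "streak_rows") <- flag
  attr(enface, "corrected_rows") <- correct
  enface
}

#' Project a speckle-variance volume to an en-face image over a layer slab
#'
#' For every lateral position, reduces sv over the depths between two named
#' layer boundaries (by default the RNFL slab between the ILM and the
#' RNFL/GCL boundary), yielding the en-face angiogram of that slab.
#'
#' @param sv_volume an `sv_volume`.
#' @param layer_model a [layer_model()] (or [retina_layers()] truth) whose
#'   depth maps cover the lateral grid.
#' @param slab character pair naming the bounding surfaces among
#'   `"ILM"`, `"RNFL/GCL"`, `"RPE"`.
#' @param reducer `"mean"` or `"max"` over the slab depths.
#' @return An [enface_image()].
#' @export
enface_project <- function(sv_volume, layer_model,
                           slab = c("ILM", "RNFL/GCL"), reducer = "mean") {
  if (!inherits(sv_volume, "sv_volume")) stop("'sv_volume' must be an sv_volume")
  reducer <- match.arg(reducer, c("mean", "max"))
  maps <- list("ILM" = layer_model$ilm, "RNFL/GCL" = layer_model$rnfl_gcl,
               "RPE" = layer_model$rpe)
  if (!all(slab %in% names(maps)))
    stop("'slab' must name two of: ", paste(names(maps), collapse = ", "))
  lo <- maps[[slab[1]]]; hi <- maps[[slab[2]]]
  d <- dim(sv_volume$sv); ny <- d[1]; nz <- d[2]; nx <- d[3]
  if (!all(dim(lo) == c(ny, nx)))
    stop("layer maps do not cover the lateral grid")
  dz <- sv_volume$spacing[["depth"]]
  z_um <- (seq_len(nz) - 0.5) * dz
  # per-pixel depth index range [klo, khi]
  klo <- matrix(findInterval(lo - 1e-9, z_um) + 1L, ny, nx)
  khi <- matrix(findInterval(hi - 1e-9, z_um), ny, nx)
  bad <- which(khi < klo)
  if (length(bad)) {
    ij <- arrayInd(bad, c(ny, nx))
    stop(sprintf(
      "empty slab (boundaries crossed or thinner than one depth pixel) at %d positions, e.g. (slow=%d, fast=%d)",
      length(bad), ij[1, 1], ij[1, 2]))
  }
  out <- matrix(0, ny, nx)
  if (reducer == "mean") {
    # cumulative sum along depth gives every slab mean in O(1) per pixel
    cs <- apply(sv_volume$sv, c(1, 3), cumsum)     # [depth, slow, fast]
    iy <- rep(seq_len(ny), times = nx)
    ix <- rep(seq_len(nx), each = ny)
    hi_idx <- cbind(as.vector(khi), iy, ix)
    lo <- as.vector(klo)
    lo_sum <- ifelse(lo > 1, cs[cbind(lo - 1L, iy, ix)], 0)
    out[] <- (cs[hi_idx] - lo_sum) / (as.vector(khi) - lo + 1)
  } else {
    # group lateral positions by identical (klo, khi); each group is one
    # vectorized slab reduction
    key <- paste(klo, khi)
    for (kk in unique(key)) {
      sel <- which(key == kk)
      ij <- arrayInd(sel, c(ny, nx))
      rng <- klo[sel[1]]:khi[sel[1]]
      sub <- sv_volume$sv[, rng, , drop = FALSE]
      red <- apply(sub, c(1, 3), max)
      out[sel] <- red[ij]
    }
  }
  enface_image(out, pixel_um = sv_volume$spacing[["fast"]],
               slab = sprintf("%s..%s (%s)", slab[1], slab[2], reducer))
}

#' Centered crop of an en-face image
#'
#' Crops to a centered square of side `crop_um`, matching the histology
#' field of view (636.5 x 636.5 um). The pixel window is
#' `floor(crop_um / pixel_um)` pixels, aligned with `floor((n - m) / 2)`
#' leading pixels discarded, so cropping is idempotent.
#'
#' @param enface an [enface_image()].
#' @param crop_um side of the crop in micrometres.
#' @return An [enface_image()].
#' @export
crop_enface <- function(enface, crop_um = 636.5) {
  if (!inherits(enface, "enface_image"))
    stop("'enface' must be an enface_image")
  px <- enface$pixels
  m <- floor(crop_um / enface$pixel_um + 1e-9)
  if (m > nrow(px) || m > ncol(px))
    stop(sprintf("crop of %g um (%d px) exceeds the %d x %d px image",
                 crop_um, m, nrow(px), ncol(px)))
  r0 <- floor((nrow(px) - m) / 2)
  c0 <- floor((ncol(px) - m) / 2)
  enface$pixels <- px[(r0 + 1):(r0 + m), (c0 + 1):(c0 + m), drop = FALSE]
  enface
}
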