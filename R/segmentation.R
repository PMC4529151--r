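# Retinal boundary segmentation and RNFL thickness.
#
# The ILM (vitreoretinal interface) is the anterior-most strong positive
# vertical intensity edge; the RPE/BM complex is the brightest posterior
# band. Both are extracted per B-scan as connected minimum-cost paths by
# dynamic programming across the fast axis, which realizes the same
# single-boundary objective as graph-cut layer segmentation. The RNFL/GCL
# boundary, which has no strong intrinsic edge at this resolution, is
# derived from the RPE by a fixed anterior offset.

#' Layer model container
#'
#' Per-(slow, fast) depth maps (micrometres) of the ILM, the derived
#' RNFL/GCL boundary, and the RPE/BM complex, with the ordering invariant
#' `ilm <= rnfl_gcl <= rpe` asserted at construction.
#'
#' @param ilm,rnfl_gcl,rpe depth matrices `[slow, fast]`, micrometres.
#' @param offset_um the anterior offset used to derive `rnfl_gcl`.
#' @return Object of class `layer_model`.
#' @export
layer_model <- function(ilm, rnfl_gcl, rpe, offset_um = NA_real_) {
  if (!all(dim(ilm) == dim(rpe)) || !all(dim(ilm) == dim(rnfl_gcl)))
    stop("layer maps must share dimensions")
  if (any(ilm > rnfl_gcl + 1e-9) || any(rnfl_gcl > rpe + 1e-9))
    stop("layer ordering violated: need ilm <= rnfl_gcl <= rpe")
  structure(list(ilm = ilm, rnfl_gcl = rnfl_gcl, rpe = rpe,
                 offset_um = offset_um), class = "layer_model")
}

#' @exportS3Method base::print
print.layer_model <- function(x, ...) {
  cat(sprintf("layer_model on %d x %d lateral grid\n",
              nrow(x$ilm), ncol(x$ilm)))
  cat(sprintf("  mean depths (um): ILM %.1f, RNFL/GCL %.1f, RPE %.1f (offset %.1f)\n",
              mean(x$ilm), mean(x$rnfl_gcl), mean(x$rpe), x$offset_um))
  invisible(x)
}

# Minimum-cost connected path through cost[z, x, b] (depth x fast x bscan):
# one depth per fast column, |delta z| <= max_jump between columns. All
# B-scans are solved simultaneously (vectorized over the slow axis).
# Returns the path depth index matrix [b, x].
min_cost_path <- function(cost, max_jump = 5L) {
  nz <- dim(cost)[1]; nx <- dim(cost)[2]; nb <- dim(cost)[3]
  acc <- matrix(cost[, 1, ], nz, nb)
  ptr <- array(0L, c(nz, nx, nb))
  shifts <- -max_jump:max_jump
  for (x in 2:nx) {
    best <- matrix(Inf, nz, nb)
    bidx <- matrix(0L, nz, nb)
    for (s in shifts) {
      # candidate: previous column value at depth z + s
      idx <- seq_len(nz) + s
      ok <- idx >= 1L & idx <= nz
      cand <- matrix(Inf, nz, nb)
      cand[ok, ] <- acc[idx[ok], , drop = FALSE]
      upd <- cand < best
      if (any(upd)) {
        best[upd] <- cand[upd]
        bidx[upd] <- s
      }
    }
    ptr[, x, ] <- bidx
    acc <- best + matrix(cost[, x, ], nz, nb)
  }
  path <- matrix(0L, nb, nx)
  for (b in seq_len(nb)) {
    z <- which.min(acc[, b])
    path[b, nx] <- z
    for (x in nx:2) {
      z <- z + ptr[z, x, b]
      path[b, x - 1L] <- z
    }
  }
  path
}

#' Segment the ILM and RPE/BM boundaries
#'
#' Works on the repeat-averaged intensity volume. Per B-scan, the ILM is
#' the minimum-cost connected path on the negated positive vertical
#' intensity gradient (the anterior-most strong dark-to-bright edge found
#' first along depth), and the RPE is the brightest-layer path constrained
#' to lie at least `min_separation_um` posterior to the ILM. The volume is
#' lightly Gaussian-smoothed first to suppress speckle.
#'
#' @param volume an [oct_volume()] (repeats are averaged internally) or a
#'   3-D array `[slow, depth, fast]`.
#' @param spacing spacing vector if a bare array is given.
#' @param max_jump maximum depth step (pixels) between adjacent columns.
#' @param smooth_sigma_px Gaussian pre-smoothing SD (pixels) for the edge
#'   image used by the ILM.
#' @param rpe_smooth_sigma_px lateral-only smoothing SD (pixels) for the
#'   brightness image used by the RPE; lateral-only so the thin bright
#'   band is not diluted axially.
#' @param min_separation_um minimum ILM-to-RPE separation.
#' @param edge_snr minimum ratio of the strongest positive gradient to the
#'   gradient MAD for a B-scan to be considered segmentable.
#' @return List with `ilm` and `rpe` depth matrices `[slow, fast]` in
#'   micrometres (boundary positions at voxel centers).
#' @export
segment_boundaries <- function(volume, spacing = NULL, max_jump = 5L,
                               smooth_sigma_px = 1.5,
                               rpe_smooth_sigma_px = 4,
                               min_separation_um = 60, edge_snr = 4) {
  if (inherits(volume, "oct_volume")) {
    spacing <- volume$spacing
    nr <- volume$n_repeats
    d <- dim(volume$intensity)
    m <- matrix(volume$intensity, nrow = nr)
    mean_vol <- array(colMeans(m), d[-1])     # [slow, depth, fast]
  } else {
    if (is.null(spacing)) stop("'spacing' required for a bare array")
    mean_vol <- volume
  }
  ny <- dim(mean_vol)[1]; nz <- dim(mean_vol)[2]; nx <- dim(mean_vol)[3]
  dz <- spacing[["depth"]]
  sm <- mean_vol
  if (smooth_sigma_px > 0) {
    sm <- blur_dim(sm, 2L, smooth_sigma_px)
    sm <- blur_dim(sm, 3L, smooth_sigma_px)
  }
  # scale invariance: normalize by the volume median of positive values
  sc <- stats::median(sm[sm > 0])
  if (!is.finite(sc) || sc <= 0) stop("volume has no positive intensities")
  sm <- sm / sc

  # positive vertical gradient along depth, [slow, depth, fast]
  grad <- sm - shift_dim(sm, 2L, 1L)
  grad[grad < 0] <- 0
  gmax <- apply(grad, 1, max)
  # noise floor: robust spread of the gradient over the whole volume
  # (zeros included, so a noiseless step profile has floor ~0)
  gnoise <- stats::mad(as.vector(grad))
  if (!is.finite(gnoise)) gnoise <- 0
  weak <- which(gmax <= edge_snr * max(gnoise, 1e-9))
  if (length(weak))
    stop(sprintf("no edge above noise floor in B-scan(s): %s",
                 paste(utils::head(weak, 10), collapse = ", ")))

  # cost arrays [depth, fast, bscan]; the gradient is clipped at its upper
  # quantile so every strong edge (ILM, RPE top) saturates to ~zero cost,
  # and a linear anterior bias selects the anterior-most strong edge (the
  # ILM) among them
  gcap <- stats::quantile(grad[grad > 0], 0.9, names = FALSE)
  gclip <- grad
  gclip[gclip > gcap] <- gcap
  cost_ilm <- aperm(gcap - gclip, c(2, 3, 1))
  cost_ilm <- cost_ilm + array(rep(seq_len(nz) * (0.02 * gcap), nx * ny),
                               c(nz, nx, ny))
  ilm_px <- min_cost_path(cost_ilm, max_jump = max_jump)

  # the RPE band is thin (a few depth px): smooth laterally only, so the
  # band keeps its brightness while the speckle contrast drops
  sm_rpe <- mean_vol
  if (rpe_smooth_sigma_px > 0) {
    sm_rpe <- blur_dim(sm_rpe, 3L, rpe_smooth_sigma_px)
    sm_rpe <- blur_dim(sm_rpe, 1L, rpe_smooth_sigma_px)
  }
  sm_rpe <- sm_rpe / sc
  cost_rpe <- aperm(max(sm_rpe) - sm_rpe, c(2, 3, 1))
  min_sep_px <- ceiling(min_separation_um / dz)
  # forbid depths anterior to ILM + separation
  top <- pmin(nz, ilm_px + min_sep_px)              # [slow, fast]
  zidx <- array(seq_len(nz), c(nz, nx, ny))
  texp <- array(rep(t(top), each = nz), c(nz, nx, ny))
  cost_rpe[zidx < texp] <- Inf
  rpe_px <- min_cost_path(cost_rpe, max_jump = max_jump)

  # the ILM edge sits between the last vitreous voxel and the first tissue
  # voxel: report it at the voxel boundary; the RPE path is reported at the
  # voxel center of the brightest band
  list(ilm = (ilm_px - 1) * dz, rpe = (rpe_px - 0.5) * dz)
}

#' Derive the RNFL/GCL boundary by anterior offset from the RPE
#'
#' `rnfl_gcl = rpe - offset_um`, clipped so it never lies anterior to the
#' ILM; if clipping occurs a warning reports the affected fraction.
#' Setting `min_slab_um` to one depth-pixel pitch guarantees a non-empty
#' RNFL slab at every position, so a locally mis-segmented ILM cannot
#' make the subsequent en-face projection fail.
#'
#' @param ilm,rpe depth maps `[slow, fast]`, micrometres.
#' @param offset_um anterior shift, micrometres (>= 0).
#' @param min_slab_um minimum `rnfl_gcl - ilm` enforced when clipping
#'   (default 0: clip exactly to the ILM).
#' @return A [layer_model()].
#' @export
derive_rnfl_gcl <- function(ilm, rpe, offset_um, min_slab_um = 0) {
  if (offset_um < 0) stop("'offset_um' must be >= 0")
  rnfl_gcl <- rpe - offset_um
  clipped <- rnfl_gcl < ilm
  if (any(clipped)) {
    warning(sprintf(
      "offset %g um pushes the RNFL/GCL boundary anterior to the ILM at %.1f%% of positions; clipped",
      offset_um, 100 * mean(clipped)))
  }
  low <- rnfl_gcl < ilm + min_slab_um
  rnfl_gcl[low] <- ilm[low] + min_slab_um
  layer_model(ilm, rnfl_gcl, rpe, offset_um = offset_um)
}

#' Fit the RPE offset against a known RNFL/GCL boundary
#'
#' Helper for phantom studies: the median of `rpe - rnfl_gcl_truth`, i.e.
#' the offset that best recovers a known boundary.
#'
#' @param rpe segmented RPE depth map.
#' @param rnfl_gcl_truth true RNFL/GCL depth map.
#' @return Offset in micrometres.
#' @export
fit_rnfl_offset <- function(rpe, rnfl_gcl_truth) {
  stats::median(rpe - rnfl_gcl_truth)
}

#' RNFL thickness over selected B-scans
#'
#' Per selected B-scan, the lateral mean of `rnfl_gcl - ilm` in
#' micrometres; the summary is the arithmetic mean over the selected
#' B-scans (10 evenly spaced ones by default).
#'
#' @param layer_model a [layer_model()].
#' @param bscan_indices slow-axis indices; `NULL` = `n_bscans` evenly
#'   spaced.
#' @param n_bscans number of evenly spaced B-scans when `bscan_indices` is
#'   `NULL`.
#' @return Object of class `rnfl_thickness`: list with `per_bscan`,
#'   `mean_um`, `n_bscans`, `bscan_indices`.
#' @export
rnfl_thickness <- function(layer_model, bscan_indices = NULL, n_bscans = 10) {
  ny <- nrow(layer_model$ilm)
  if (is.null(bscan_indices)) {
    n_bscans <- min(n_bscans, ny)
    bscan_indices <- unique(round(seq(1, ny, length.out = n_bscans)))
  }
  if (length(bscan_indices) == 0) stop("empty B-scan index list")
  if (any(bscan_indices < 1 | bscan_indices > ny))
    stop("B-scan indices out of range")
  thick <- layer_model$rnfl_gcl - layer_model$ilm
  per <- rowMeans(thick[bscan_indices, , drop = FALSE])
  structure(list(per_bscan = per, mean_um = mean(per),
                 n_bscans = length(bscan_indices),
                 bscan_indices = bscan_indices),
            class = "rnfl_thickness")
}

#' @exportS3Method base::print
print.rnfl_thickness <- function(x, ...) {
  cat(sprintf("RNFL thickness: %.1f um (mean over %d B-scans, range %.1f-%.1f)\n",
              x$mean_um, x$n_bscans, min(x$per_bscan), max(x$per_bscan)))
  invisible(x)
}
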