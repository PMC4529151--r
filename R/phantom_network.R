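# Ground-truth capillary network generator.
#
# Radial peripapillary capillaries run long, nearly straight and parallel to
# one another within any one peripapillary sector; the sector determines the
# dominant orientation (radially outward from the disc). The generator builds
# such a network as evenly spaced parallel polylines with optional waviness,
# confined to the lateral FOV and to a depth band inside the RNFL.

#' Dominant capillary orientation for a peripapillary region
#'
#' Orientation (degrees from the +x fast axis, in `[0, 180)`) of capillaries
#' radiating outward from the optic disc, as seen in a small FOV centered on
#' each sector: temporal and nasal sectors run horizontally, superior and
#' inferior vertically, and the arcuate sectors diagonally.
#'
#' @param region_label one of `"Sup"`, `"ST"`, `"Temp"`, `"IT"`, `"Inf"`, `"N"`.
#' @return Angle in degrees.
#' @export
region_dominant_angle <- function(region_label) {
  angles <- c(Sup = 90, ST = 45, Temp = 0, IT = 135, "Inf" = 90, N = 0)
  region_label <- match.arg(region_label, names(angles))
  unname(angles[region_label])
}

#' Generate a parallel capillary network
#'
#' Builds `n_capillaries` approximately parallel capillary centerlines with
#' mean perpendicular spacing `spacing_um`, oriented along the region's
#' dominant angle, confined to a square lateral FOV and a depth band within
#' the RNFL. With `waviness = 0` the construction is exactly parallel and
#' exactly evenly spaced; `waviness > 0` adds a smooth sinusoidal
#' perpendicular displacement of amplitude `waviness * spacing_um` per
#' capillary.
#'
#' @param region_label peripapillary sector, see [region_dominant_angle()].
#' @param spacing_um perpendicular center-to-center spacing, micrometres.
#' @param diameter_um capillary diameter (common to all), micrometres.
#' @param n_capillaries number of capillaries; `NULL` = as many as fit.
#' @param waviness dimensionless perpendicular displacement amplitude as a
#'   fraction of `spacing_um` (0 = perfectly straight).
#' @param seed RNG seed; identical seeds give bit-identical networks.
#' @param fov_um lateral field of view (square), micrometres.
#' @param z_range_um depth band (min, max) the capillaries occupy,
#'   micrometres below the volume's top surface; should lie inside the RNFL.
#' @param angle_deg optional explicit orientation overriding the region map.
#' @param flow logical, capillaries carry flow (recycled).
#' @return Object of class `capillary_network`: list with `capillaries`
#'   (list of n x 3 matrices, columns x/y/z in micrometres), `diameters_um`,
#'   `flow`, `region_label`, `dominant_angle`, `fov_um`, `spacing_um`,
#'   `seed`.
#' @examples
#' net <- generate_network("Temp", spacing_um = 35, diameter_um = 5,
#'                         n_capillaries = 18, seed = 1)
#' net
#' @export
generate_network <- function(region_label = "Temp", spacing_um = 35,
                             diameter_um = 5, n_capillaries = NULL,
                             waviness = 0, seed = 1, fov_um = 636.5,
                             z_range_um = c(60, 130), angle_deg = NULL,
                             flow = TRUE) {
  stopifnot_positive(spacing_um, diameter_um, fov_um)
  if (spacing_um <= diameter_um)
    stop("'spacing_um' must exceed 'diameter_um'")
  if (waviness < 0) stop("'waviness' must be >= 0")
  angle <- angle_deg %||% region_dominant_angle(region_label)
  theta <- angle * pi / 180
  u <- c(cos(theta), sin(theta))        # along-capillary direction
  v <- c(-sin(theta), cos(theta))       # perpendicular direction

  # perpendicular extent of the FOV box, minus a margin of one diameter,
  # bounds how many capillaries fit at the requested spacing
  corners <- rbind(c(0, 0), c(fov_um, 0), c(0, fov_um), c(fov_um, fov_um))
  proj <- corners %*% v
  usable <- (max(proj) - min(proj)) - diameter_um
  max_n <- max(1L, floor(usable / spacing_um) + 1L)
  if (is.null(n_capillaries)) n_capillaries <- max_n
  if (n_capillaries > max_n)
    stop(sprintf(
      "spacing %g um too large for a %g um FOV: at most %d capillaries fit",
      spacing_um, fov_um, max_n))
  if (n_capillaries < 1) stop("'n_capillaries' must be >= 1")

  center <- c(fov_um / 2, fov_um / 2)
  offsets <- (seq_len(n_capillaries) - (n_capillaries + 1) / 2) * spacing_um

  caps <- with_seed(seed, {
    lapply(seq_len(n_capillaries), function(i) {
      base <- center + offsets[i] * v
      tr <- line_box_range(base, u, fov_um)
      if (is.null(tr)) return(NULL)
      z <- stats::runif(1, z_range_um[1], z_range_um[2])
      if (waviness == 0) {
        t_pts <- tr
      } else {
        t_pts <- seq(tr[1], tr[2], by = 5)
        if (t_pts[length(t_pts)] < tr[2]) t_pts <- c(t_pts, tr[2])
      }
      pts <- cbind(base[1] + t_pts * u[1], base[2] + t_pts * u[2])
      if (waviness > 0) {
        amp <- waviness * spacing_um
        wl <- stats::runif(1, fov_um / 3, fov_um)
        ph <- stats::runif(1, 0, 2 * pi)
        disp <- amp * sin(2 * pi * t_pts / wl + ph)
        pts <- pts + cbind(disp * v[1], disp * v[2])
        pts[, 1] <- pmin(pmax(pts[, 1], 0), fov_um)
        pts[, 2] <- pmin(pmax(pts[, 2], 0), fov_um)
      }
      cbind(x = pts[, 1], y = pts[, 2], z = z)
    })
  })
  keep <- !vapply(caps, is.null, logical(1))
  caps <- caps[keep]
  n <- length(caps)
  net <- structure(list(
    capillaries = caps,
    diameters_um = rep_len(diameter_um, n),
    flow = rep_len(flow, n),
    region_label = region_label,
    dominant_angle = network_dominant_angle(caps),
    fov_um = fov_um,
    spacing_um = spacing_um,
    z_range_um = z_range_um,
    seed = seed
  ), class = "capillary_network")
  net
}

# Parameter range [tmin, tmax] of line base + t*u clipped to [0, fov]^2,
# or NULL if the line misses the box.
line_box_range <- function(base, u, fov) {
  tmin <- -Inf; tmax <- Inf
  for (k in 1:2) {
    if (abs(u[k]) < 1e-12) {
      if (base[k] < 0 || base[k] > fov) return(NULL)
    } else {
      t1 <- (0 - base[k]) / u[k]
      t2 <- (fov - base[k]) / u[k]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin >= tmax) return(NULL)
  c(tmin, tmax)
}

# Length-weighted circular mean (period 180 deg) of segment orientations.
network_dominant_angle <- function(caps) {
  sx <- 0; sy <- 0
  for (p in caps) {
    if (nrow(p) < 2) next
    dx <- diff(p[, 1]); dy <- diff(p[, 2])
    len <- sqrt(dx^2 + dy^2)
    ang2 <- 2 * atan2(dy, dx)
    sx <- sx + sum(len * cos(ang2))
    sy <- sy + sum(len * sin(ang2))
  }
  a <- (atan2(sy, sx) / 2) * 180 / pi
  a %% 180
}

#' @exportS3Method base::print
print.capillary_network <- function(x, ...) {
  cat(sprintf("capillary_network: %d capillaries, region %s\n",
              length(x$capillaries), x$region_label))
  cat(sprintf("  FOV %g um, spacing %g um, diameters %g-%g um\n",
              x$fov_um, x$spacing_um, min(x$diameters_um),
              max(x$diameters_um)))
  cat(sprintf("  dominant angle %.2f deg, depth band %g-%g um, seed %g\n",
              x$dominant_angle, x$z_range_um[1], x$z_range_um[2], x$seed))
  invisible(x)
}

#' @export
plot.capillary_network <- function(x, ...) {
  plot(NA, xlim = c(0, x$fov_um), ylim = c(0, x$fov_um), asp = 1,
       xlab = "x (um)", ylab = "y (um)",
       main = sprintf("Capillary network (%s)", x$region_label), ...)
  for (p in x$capillaries) graphics::lines(p[, 1], p[, 2])
  invisible(x)
}

#' Mean perpendicular spacing of a parallel network
#'
#' Measures the mean center-to-center distance between adjacent capillaries
#' along the direction perpendicular to the dominant orientation, using each
#' capillary's mean perpendicular offset.
#'
#' @param network a [generate_network()] result.
#' @return Mean adjacent spacing in micrometres.
#' @export
network_mean_spacing <- function(network) {
  theta <- network$dominant_angle * pi / 180
  v <- c(-sin(theta), cos(theta))
  off <- vapply(network$capillaries,
                function(p) mean(p[, 1] * v[1] + p[, 2] * v[2]), numeric(1))
  mean(diff(sort(off)))
}

#' Serialize / read a capillary network as JSON
#'
#' Polylines are stored in micrometres; the file round-trips all fields.
#'
#' @param network a `capillary_network`.
#' @param path file path to write to / read from.
#' @return `read_network` returns a `capillary_network`.
#' @export
write_network <- function(network, path) {
  obj <- unclass(network)
  obj$capillaries <- lapply(obj$capillaries, function(p)
    list(x = p[, 1], y = p[, 2], z = p[, 3]))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$capillaries <- lapply(seq_len(nrow_list(obj$capillaries)), function(i) {
    p <- if (is.data.frame(obj$capillaries)) obj$capillaries[i, ]
         else obj$capillaries[[i]]
    cbind(x = unlist(p$x), y = unlist(p$y), z = unlist(p$z))
  })
  structure(obj, class = "capillary_network")
}

nrow_list <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
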