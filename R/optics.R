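# Closed-form beam optics and reduced-eye scan calibration.
#
# These four formulas convert the imaging device's source and delivery-optics
# parameters into the physical scales the rest of the pipeline needs: axial
# resolution (coherence length in tissue), lateral resolution (focal waist and
# its FWHM), and the retinal scan field of view from the beam scan angle and
# the subject's eye length.

#' Coherence length (axial resolution) in tissue
#'
#' Round-trip coherence length of a Gaussian-spectrum source,
#' \eqn{l_c = (2 \ln 2 / \pi) \, \lambda_0^2 / (\Delta\lambda \, n)},
#' i.e. the in-air value divided by the tissue refractive index. For a
#' 1060 nm swept source with 61.5 nm FWHM bandwidth in tissue (n = 1.33)
#' this gives about 6 um.
#'
#' @param lambda0_nm center wavelength in nm.
#' @param delta_lambda_nm FWHM spectral bandwidth in nm.
#' @param n_tissue refractive index of the medium (default 1.33, vitreous).
#' @return Coherence length in micrometres.
#' @examples
#' coherence_length_um(1060, 61.5, 1.33)  # ~6.06
#' @export
coherence_length_um <- function(lambda0_nm, delta_lambda_nm, n_tissue = 1.33) {
  stopifnot_positive(lambda0_nm, delta_lambda_nm, n_tissue)
  lc_nm <- (2 * log(2) / pi) * lambda0_nm^2 / (delta_lambda_nm * n_tissue)
  lc_nm / 1000
}

#' Lateral FWHM of a Gaussian focal spot
#'
#' Full width at half maximum of the intensity profile of a Gaussian beam
#' with \eqn{1/e^2} waist radius \eqn{\omega_0}:
#' \eqn{\mathrm{FWHM} = \sqrt{2 \ln 2}\,\omega_0}. With \eqn{\omega_0 =
#' 7.3} um this gives 8.6 um. (The constant is \eqn{\sqrt{2\ln 2} \approx
#' 1.177}; the occasionally quoted \eqn{2\ln 2\,\omega_0} is a typo for the
#' intensity-profile width and does not reproduce 8.6 um from 7.3 um.)
#'
#' @param omega0_um 1/e^2 intensity waist radius in micrometres.
#' @return Lateral FWHM in micrometres.
#' @examples
#' lateral_fwhm_um(7.3)  # ~8.59
#' @export
lateral_fwhm_um <- function(omega0_um) {
  stopifnot_positive(omega0_um)
  sqrt(2 * log(2)) * omega0_um
}

#' Focal waist on the retina from Gaussian optics
#'
#' Diffraction-limited waist radius for a collimated Gaussian beam of radius
#' \eqn{w_p} at the pupil focused by the eye:
#' \eqn{\omega_0 = (\lambda_0 / n) f / (\pi w_p)}.
#' The eye is modelled with schematic-eye constants (Gullstrand-LeGrand):
#' posterior focal length 22.29 mm inside media of index 1.336. A 1.5 mm
#' beam at 1060 nm gives a waist of about 7.5 um.
#'
#' @param pupil_beam_diameter_mm 1/e^2 beam diameter at the pupil, mm.
#' @param lambda0_nm center wavelength in nm.
#' @param eye_focal_length_mm posterior focal length of the schematic eye
#'   (default 22.29 mm).
#' @param n_medium refractive index of the ocular media (default 1.336).
#' @return Waist radius \eqn{\omega_0} in micrometres.
#' @export
focal_waist_um <- function(pupil_beam_diameter_mm, lambda0_nm = 1060,
                           eye_focal_length_mm = 22.29, n_medium = 1.336) {
  stopifnot_positive(pupil_beam_diameter_mm, lambda0_nm,
                     eye_focal_length_mm, n_medium)
  w_pupil_mm <- pupil_beam_diameter_mm / 2
  lambda_mm <- lambda0_nm * 1e-6 / n_medium
  w0_mm <- lambda_mm * eye_focal_length_mm / (pi * w_pupil_mm)
  w0_mm * 1000
}

#' Retinal arc length swept by a scanned beam (reduced eye)
#'
#' The scan dimension on the retina is modelled as the arc traced by the
#' beam over a circle of radius equal to the eye length, with the scan
#' angle refracted at a single surface (Snell's law):
#' \eqn{\theta' = \arcsin(\sin\theta / n)}, arc \eqn{= 2 L \theta'}.
#'
#' @param scan_half_angle_deg half scan angle in air, degrees (0 <= angle < 90).
#' @param eye_length_mm axial eye length in mm.
#' @param n_media refractive index of the ocular media (default 1.33).
#' @return Arc length on the retina in millimetres.
#' @export
scan_arc_length_mm <- function(scan_half_angle_deg, eye_length_mm,
                               n_media = 1.33) {
  if (!is.numeric(scan_half_angle_deg) || scan_half_angle_deg < 0 ||
      scan_half_angle_deg >= 90)
    stop("'scan_half_angle_deg' must be in [0, 90)")
  stopifnot_positive(eye_length_mm, n_media)
  s <- sin(scan_half_angle_deg * pi / 180) / n_media
  if (s > 1) stop("refraction impossible: sin(theta)/n > 1")
  theta_int <- asin(s)
  2 * eye_length_mm * theta_int
}

#' Device beam optics summary
#'
#' Bundles the closed-form optics into one object: coherence length in
#' tissue, focal waist, and lateral FWHM, from source and delivery
#' parameters. Defaults reproduce a 1060 nm swept-source prototype.
#'
#' @param lambda0_nm center wavelength, nm.
#' @param delta_lambda_nm FWHM bandwidth, nm.
#' @param n_tissue tissue index used for the coherence length.
#' @param pupil_beam_diameter_mm beam diameter at the pupil, mm.
#' @param omega0_um waist radius override; if `NULL`, computed from
#'   [focal_waist_um()].
#' @param eye_focal_length_mm,n_medium schematic-eye constants.
#' @return An object of class `beam_optics`: a list with fields
#'   `lambda0_nm`, `delta_lambda_nm`, `n_tissue`, `pupil_beam_diameter_mm`,
#'   `omega0_um`, `lateral_fwhm_um`, `coherence_length_um`.
#' @examples
#' beam_optics()
#' @export
beam_optics <- function(lambda0_nm = 1060, delta_lambda_nm = 61.5,
                        n_tissue = 1.33, pupil_beam_diameter_mm = 1.5,
                        omega0_um = NULL, eye_focal_length_mm = 22.29,
                        n_medium = 1.336) {
  w0 <- omega0_um %||% focal_waist_um(pupil_beam_diameter_mm, lambda0_nm,
                                      eye_focal_length_mm, n_medium)
  structure(list(
    lambda0_nm = lambda0_nm,
    delta_lambda_nm = delta_lambda_nm,
    n_tissue = n_tissue,
    pupil_beam_diameter_mm = pupil_beam_diameter_mm,
    omega0_um = w0,
    lateral_fwhm_um = lateral_fwhm_um(w0),
    coherence_length_um = coherence_length_um(lambda0_nm, delta_lambda_nm,
                                              n_tissue)
  ), class = "beam_optics")
}

#' @exportS3Method base::print
print.beam_optics <- function(x, ...) {
  cat("svOCT beam optics\n")
  cat(sprintf("  source: %g nm, bandwidth %g nm (FWHM)\n",
              x$lambda0_nm, x$delta_lambda_nm))
  cat(sprintf("  coherence length in tissue (n=%g): %.2f um\n",
              x$n_tissue, x$coherence_length_um))
  cat(sprintf("  focal waist w0: %.2f um -> lateral FWHM %.2f um\n",
              x$omega0_um, x$lateral_fwhm_um))
  invisible(x)
}

#' Scan geometry of an OCT acquisition
#'
#' Physical sampling grid of a repeat-frame svOCT volume: lateral field of
#' view sampled `n_fast` x `n_slow` with `n_repeats` repeat B-scans, and a
#' depth range sampled with `n_depth` pixels. Lateral pixel pitch is
#' `fov_um / n_fast`. The default is a 300 x 300 (x3) grid over ~1 x 1 mm.
#'
#' @param fov_um lateral field of view, micrometres (square FOV).
#' @param n_fast,n_slow,n_repeats grid dimensions.
#' @param n_depth number of depth pixels.
#' @param depth_range_um depth range covered, micrometres.
#' @param ascan_rate_hz A-scan rate (metadata only).
#' @param eye_length_mm axial eye length (metadata; used when the FOV is
#'   derived from a scan angle via [scan_arc_length_mm()]).
#' @param optics a [beam_optics()] object giving the PSF scales.
#' @return Object of class `scan_geometry` with derived `pixel_um`
#'   (lateral) and `dz_um` (axial) pitches.
#' @export
scan_geometry <- function(fov_um = 1000, n_fast = 300, n_slow = 300,
                          n_repeats = 3, n_depth = 96, depth_range_um = 288,
                          ascan_rate_hz = 1e5, eye_length_mm = 24,
                          optics = beam_optics()) {
  stopifnot_positive(fov_um, n_fast, n_slow, n_repeats, n_depth,
                     depth_range_um)
  structure(list(
    fov_um = fov_um, n_fast = as.integer(n_fast),
    n_slow = as.integer(n_slow), n_repeats = as.integer(n_repeats),
    n_depth = as.integer(n_depth), depth_range_um = depth_range_um,
    pixel_um = fov_um / n_fast, pixel_slow_um = fov_um / n_slow,
    dz_um = depth_range_um / n_depth,
    ascan_rate_hz = ascan_rate_hz, eye_length_mm = eye_length_mm,
    optics = optics
  ), class = "scan_geometry")
}

#' @exportS3Method base::print
print.scan_geometry <- function(x, ...) {
  cat(sprintf("OCT scan geometry: %d x %d (x%d repeats), FOV %g um (%.2f um/px)\n",
              x$n_fast, x$n_slow, x$n_repeats, x$fov_um, x$pixel_um))
  cat(sprintf("  depth: %d px over %g um (%.2f um/px)\n",
              x$n_depth, x$depth_range_um, x$dz_um))
  invisible(x)
}
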