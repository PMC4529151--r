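# Synthetic study tables: the statistical stand-in for a multi-subject,
# two-eye, six-region study feeding the mixed models.

#' Generate a synthetic study table
#'
#' Emulates a peripapillary study in which each subject contributes one or
#' two eyes and each eye is measured in six regions. ICD is generated as
#'
#' `icd = icd_mean[region] + slope * (rnfl - rnfl_mean[region]) + b_subject
#'  + b_eye + noise`
#'
#' (the RNFL covariate is centered within region, so `icd_mean` is the
#' region mean for both techniques and the slope acts within region, as
#' in the region-adjusted mixed model)
#'
#' with independent Gaussian subject and eye-within-subject random
#' intercepts. RNFL thickness is drawn per eye x region around
#' region-specific means (arcuate bundles thickest, temporal thinnest).
#' Histology records, when requested, come from a separate donor cohort
#' (one flat-mounted eye each, no RNFL) with an optional additive
#' technique offset. Density is `100 / icd`; diameters are drawn around a
#' technique-specific mean (the OCT point-spread function makes in vivo
#' capillaries measure wider than histology).
#'
#' Defaults emulate 9 subjects / 16 eyes with region means inside the
#' 30-42 um ICD envelope, arcuate (ST, IT) regions densest, and an ICD
#' slope of -0.065 um per um RNFL.
#'
#' @param n_subjects number of imaged subjects (>= 2).
#' @param regions regions measured per eye.
#' @param icd_means named vector of region ICD means, micrometres.
#' @param rnfl_slope ICD change per um of RNFL thickness.
#' @param noise_sd residual SD of ICD, micrometres.
#' @param random_intercept_sd named vector `c(subject=, eye=)` of random
#'   intercept SDs (a single number is used for the subject SD with half
#'   of it for the eye SD).
#' @param seed RNG seed.
#' @param n_eyes total eyes; default two per subject, capped at 16 as in a
#'   typical cohort; subjects beyond the cap contribute one eye.
#' @param rnfl_means,rnfl_sd region means and SD of RNFL thickness, um.
#' @param techniques `"svOCT"`, `"histology"`, or both.
#' @param n_donors donors for the histology arm.
#' @param technique_offset additive ICD offset of histology relative to
#'   svOCT; scalar or named per-region vector.
#' @param diameter_means named vector of mean diameters per technique.
#' @param diameter_sd SD of diameters.
#' @return data.frame of study records: `subject_id`, `eye`, `region`,
#'   `technique`, `icd_um`, `density_per_100um`, `diameter_um`, `rnfl_um`
#'   (NA for histology).
#' @export
generate_study_table <- function(n_subjects = 9,
                                 regions = c("Sup", "ST", "Temp", "IT",
                                             "Inf", "N"),
                                 icd_means = c(Sup = 38, ST = 31, Temp = 36,
                                               IT = 32, "Inf" = 38, N = 40),
                                 rnfl_slope = -0.065, noise_sd = 2.5,
                                 random_intercept_sd = c(subject = 1.5,
                                                         eye = 0.75),
                                 seed = 1, n_eyes = NULL,
                                 rnfl_means = c(Sup = 120, ST = 140,
                                                Temp = 80, IT = 140,
                                                "Inf" = 120, N = 90),
                                 rnfl_sd = 15, techniques = "svOCT",
                                 n_donors = 9, technique_offset = 0,
                                 diameter_means = c(svOCT = 7, histology = 4.7),
                                 diameter_sd = 0.5) {
  if (n_subjects < 2) stop("'n_subjects' must be >= 2")
  if (!all(regions %in% study_regions)) stop("unknown region label(s)")
  if (!all(regions %in% names(icd_means)))
    stop("'icd_means' must cover all requested regions")
  if (length(random_intercept_sd) == 1)
    random_intercept_sd <- c(subject = unname(random_intercept_sd),
                             eye = unname(random_intercept_sd) / 2)
  n_eyes <- n_eyes %||% min(2L * n_subjects, 16L)
  if (n_eyes < n_subjects || n_eyes > 2L * n_subjects)
    stop("'n_eyes' must allow 1-2 eyes per subject")
  # first eyes for everyone, second eyes for the first (n_eyes - n_subjects)
  eye_tab <- data.frame(
    subject = c(sprintf("S%02d", seq_len(n_subjects)),
                sprintf("S%02d", seq_len(n_eyes - n_subjects))),
    eye = c(rep("OD", n_subjects), rep("OS", n_eyes - n_subjects)),
    stringsAsFactors = FALSE)
  offset_of <- function(region) {
    if (length(technique_offset) == 1 && is.null(names(technique_offset)))
      technique_offset
    else if (region %in% names(technique_offset)) technique_offset[[region]]
    else 0
  }

  with_seed(seed, {
    rows <- list()
    if ("svOCT" %in% techniques) {
      b_subj <- stats::setNames(
        stats::rnorm(n_subjects, 0, random_intercept_sd[["subject"]]),
        sprintf("S%02d", seq_len(n_subjects)))
      for (i in seq_len(nrow(eye_tab))) {
        b_eye <- stats::rnorm(1, 0, random_intercept_sd[["eye"]])
        for (rg in regions) {
          rnfl <- stats::rnorm(1, rnfl_means[[rg]], rnfl_sd)
          icd <- icd_means[[rg]] + rnfl_slope * (rnfl - rnfl_means[[rg]]) +
            b_subj[[eye_tab$subject[i]]] + b_eye +
            stats::rnorm(1, 0, noise_sd)
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = eye_tab$subject[i], eye = eye_tab$eye[i],
            region = rg, technique = "svOCT", icd_um = icd,
            density_per_100um = 100 / icd,
            diameter_um = stats::rnorm(1, diameter_means[["svOCT"]],
                                       diameter_sd),
            rnfl_um = rnfl, stringsAsFactors = FALSE)
        }
      }
    }
    if ("histology" %in% techniques) {
      b_don <- stats::rnorm(n_donors, 0, random_intercept_sd[["subject"]])
      for (i in seq_len(n_donors)) {
        for (rg in regions) {
          icd <- icd_means[[rg]] + offset_of(rg) + b_don[i] +
            stats::rnorm(1, 0, noise_sd)
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = sprintf("D%02d", i), eye = "OD",
            region = rg, technique = "histology", icd_um = icd,
            density_per_100um = 100 / icd,
            diameter_um = stats::rnorm(1, diameter_means[["histology"]],
                                       diameter_sd),
            rnfl_um = NA_real_, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
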