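# Mixed-effects analyses of study tables.
#
# Measurements come in multiples per eye and per subject (two eyes, six
# peripapillary regions), so comparisons use linear mixed models with
# random intercepts for eye nested within subject. ICD is log-transformed
# before technique comparisons to attain normality; the ICD-vs-RNFL
# regression is reported on the raw scale by default with the log-scale
# fit available through `transform`.

study_regions <- c("Sup", "ST", "Temp", "IT", "Inf", "N")

validate_records <- function(records, need_rnfl = FALSE) {
  req <- c("subject_id", "eye", "region", "technique", "icd_um")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  if (!all(records$region %in% study_regions))
    stop("unknown region label(s): ",
         paste(setdiff(unique(records$region), study_regions), collapse = ", "))
  if (!all(records$technique %in% c("svOCT", "histology")))
    stop("technique must be 'svOCT' or 'histology'")
  if (need_rnfl) {
    if (!"rnfl_um" %in% names(records) || any(is.na(records$rnfl_um)))
      stop("RNFL thickness is required (svOCT records) and must be complete")
  }
  records$subject_id <- factor(records$subject_id)
  records$eye <- factor(records$eye)
  records$region <- factor(records$region,
                           levels = intersect(study_regions,
                                              unique(records$region)))
  records$technique <- factor(records$technique,
                              levels = intersect(c("histology", "svOCT"),
                                                 unique(records$technique)))
  records
}

#' Mixed-model fit container
#'
#' @param fixed_effects data.frame with columns `term`, `estimate`, `se`,
#'   `p`.
#' @param varcomp named vector of variance components (subject,
#'   eye-in-subject, residual).
#' @param ... further fields stored verbatim.
#' @return Object of class `svrpc_mixed`.
#' @keywords internal
new_mixed_fit <- function(fixed_effects, varcomp, ...) {
  structure(c(list(fixed_effects = fixed_effects, varcomp = varcomp),
              list(...)), class = "svrpc_mixed")
}

#' @exportS3Method base::print
print.svrpc_mixed <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s), %d observations%s\n",
              x$formula_str, x$n_obs,
              if (isTRUE(x$degenerate)) " [degenerate: zero residual variance, OLS fit]"
              else ""))
  fe <- x$fixed_effects
  fe$estimate <- signif(fe$estimate, 5)
  fe$se <- signif(fe$se, 4)
  fe$p <- signif(fe$p, 3)
  print(fe, row.names = FALSE)
  cat("variance components:",
      paste(sprintf("%s=%.4g", names(x$varcomp), x$varcomp), collapse = ", "),
      "\n")
  if (!is.null(x$slope))
    cat(sprintf("RNFL slope: %.4g (SE %.3g, p = %.4g)\n",
                x$slope, x$slope_se, x$p_slope))
  invisible(x)
}

#' @export
coef.svrpc_mixed <- function(object, ...) {
  stats::setNames(object$fixed_effects$estimate, object$fixed_effects$term)
}

# Fit y ~ fixed + (1 | subject/eye) with a degenerate-data fallback.
# When the fixed-effects OLS fit already has (numerically) zero residual
# variance the mixed model is unidentifiable; the OLS fit with zero
# variance components is returned instead, flagged as degenerate.
fit_mixed <- function(df, fixed_formula, p_method = "satterthwaite",
                      test_term = NULL, test_var = NULL) {
  if (is.null(test_var)) test_var <- test_term
  ols <- stats::lm(fixed_formula, data = df)
  sigma_ols <- stats::sigma(ols)
  ytol <- 1e-8 * max(1, stats::sd(stats::model.frame(ols)[[1]]))
  if (!is.finite(sigma_ols) || sigma_ols < ytol) {
    cf <- stats::coef(ols)
    fe <- data.frame(term = names(cf), estimate = unname(cf),
                     se = 0, p = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(test_term)) {
      i <- match(test_term, fe$term)
      fe$p[i] <- if (abs(fe$estimate[i]) < 1e-10) 1 else 0
    }
    return(new_mixed_fit(fe, c(subject = 0, eye_in_subject = 0, residual = 0),
                         n_obs = nrow(df), converged = TRUE,
                         degenerate = TRUE,
                         formula_str = deparse(fixed_formula)))
  }
  # adaptive random structure: a grouping level with as many levels as
  # observations (e.g. one measurement per eye in a single-region subset)
  # is unidentifiable and is dropped
  n_eye_lv <- nlevels(droplevels(interaction(df$subject_id, df$eye)))
  n_subj_lv <- nlevels(droplevels(factor(df$subject_id)))
  msgs <- character(0)
  if (n_eye_lv < nrow(df)) {
    mixed_formula <- stats::update(fixed_formula,
                                   . ~ . + (1 | subject_id / eye))
  } else if (n_subj_lv < nrow(df)) {
    mixed_formula <- stats::update(fixed_formula, . ~ . + (1 | subject_id))
    msgs <- c(msgs, "eye-within-subject intercept dropped (one obs per eye)")
  } else {
    # no usable grouping: ordinary least squares
    cf <- stats::coef(summary(ols))
    fe <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                     p = cf[, 4], stringsAsFactors = FALSE)
    return(new_mixed_fit(fe, c(subject = 0, eye_in_subject = 0,
                               residual = sigma_ols^2),
                         n_obs = nrow(df), converged = TRUE,
                         degenerate = FALSE,
                         messages = "no grouping structure: OLS fit",
                         formula_str = deparse(fixed_formula)))
  }
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(mixed_formula, data = df, REML = TRUE,
                                control = lme4::lmerControl(
                                  calc.derivs = FALSE,
                                  check.conv.singular = "ignore"))),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- cf / se
  p_wald <- 2 * stats::pnorm(-abs(z))
  fe <- data.frame(term = names(cf), estimate = unname(cf), se = unname(se),
                   p = unname(p_wald), stringsAsFactors = FALSE)
  if (p_method == "satterthwaite") {
    # t-tests with Satterthwaite denominator degrees of freedom: the
    # finite-sample calibration the asymptotic Wald z and LRT chi-square
    # lack at study-sized n
    p_sat <- tryCatch({
      fit_t <- withCallingHandlers(
        suppressMessages(lmerTest::lmer(
          mixed_formula, data = df, REML = TRUE,
          control = lme4::lmerControl(check.conv.singular = "ignore"))),
        warning = function(w) {
          msgs <<- c(msgs, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      co <- stats::coef(summary(fit_t))
      co[match(fe$term, rownames(co)), "Pr(>|t|)"]
    }, error = function(e) NULL)
    if (!is.null(p_sat) && !any(is.na(p_sat))) fe$p <- unname(p_sat)
  }
  if (p_method == "lrt" && !is.null(test_term)) {
    p_lrt <- tryCatch({
      full_ml <- suppressMessages(stats::update(fit, REML = FALSE))
      red_formula <- drop_term_formula(mixed_formula, test_var)
      red_ml <- suppressMessages(lme4::lmer(red_formula, data = df,
                                            REML = FALSE,
                                            control = lme4::lmerControl(
                                              calc.derivs = FALSE,
                                              check.conv.singular = "ignore")))
      an <- stats::anova(red_ml, full_ml)
      an$`Pr(>Chisq)`[2]
    }, error = function(e) NA_real_)
    i <- match(test_term, fe$term)
    if (!is.na(i) && !is.na(p_lrt)) fe$p[i] <- p_lrt
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1] else 0
  }
  varcomp <- c(subject = pick("subject_id"),
               eye_in_subject = pick("eye:subject_id"),
               residual = pick("Residual"))
  conv <- length(msgs) == 0
  new_mixed_fit(fe, varcomp, n_obs = nrow(df), converged = conv,
                degenerate = FALSE, messages = msgs, model = fit,
                formula_str = deparse(fixed_formula))
}

# Remove a fixed-effect variable from a formula (for the LRT reduced model).
drop_term_formula <- function(formula, var) {
  stats::update(formula, paste(". ~ . -", var))
}

#' Linear mixed model of ICD against RNFL thickness
#'
#' Fits ICD (optionally log-transformed) on RNFL thickness and region as
#' fixed effects, with random intercepts for eye nested within subject.
#' The reported slope is the fixed effect of RNFL thickness after
#' accounting for region; its p-value uses Satterthwaite degrees of
#' freedom by default (likelihood-ratio and Wald-z alternatives are
#' exposed through `p_method`).
#'
#' @param records study-record data.frame with columns `subject_id`,
#'   `eye`, `region`, `technique`, `icd_um`, `rnfl_um` (svOCT rows).
#' @param transform `"none"` (raw-scale ICD, default) or `"log"`.
#' @param p_method `"satterthwaite"` (default), `"lrt"` or `"wald"`.
#' @return An `svrpc_mixed` fit with `slope`, `slope_se`, `p_slope`.
#' @export
fit_icd_rnfl <- function(records, transform = c("none", "log"),
                         p_method = c("satterthwaite", "lrt", "wald")) {
  transform <- match.arg(transform)
  p_method <- match.arg(p_method)
  records <- validate_records(records, need_rnfl = TRUE)
  records <- records[records$technique == "svOCT", , drop = FALSE]
  if (nlevels(droplevels(records$subject_id)) < 2)
    stop("need at least 2 subjects")
  if (nlevels(droplevels(records$region)) < 2)
    stop("need at least 2 regions")
  records$y <- if (transform == "log") log(records$icd_um) else records$icd_um
  fit <- fit_mixed(records, y ~ rnfl_um + region, p_method = p_method,
                   test_term = "rnfl_um", test_var = "rnfl_um")
  i <- match("rnfl_um", fit$fixed_effects$term)
  fit$slope <- fit$fixed_effects$estimate[i]
  fit$slope_se <- fit$fixed_effects$se[i]
  fit$p_slope <- fit$fixed_effects$p[i]
  fit$transform <- transform
  fit$formula_str <- sprintf("%s(ICD) ~ RNFL + region",
                             if (transform == "log") "log" else "identity")
  fit
}

#' Compare svOCT and histology measurements
#'
#' Per-region (data subset) and pooled mixed-model contrasts of a response
#' between the two techniques, with random intercepts for eye nested
#' within subject. ICD is log-transformed before testing; the estimate is
#' then a log-ratio (svOCT minus histology on the log scale).
#'
#' @param records study-record data.frame containing both techniques.
#' @param response `"icd"`, `"density"` or `"diameter"`.
#' @param by_region also fit each region separately.
#' @param include_region include region as a fixed effect in the pooled
#'   model.
#' @return data.frame with one row per contrast (`region` = "pooled" for
#'   the pooled model): `region`, `estimate`, `se`, `p`, `n`, `note`.
#' @export
compare_techniques <- function(records, response = c("icd", "density",
                                                     "diameter"),
                               by_region = TRUE, include_region = TRUE) {
  response <- match.arg(response)
  records <- validate_records(records)
  col <- switch(response, icd = "icd_um", density = "density_per_100um",
                diameter = "diameter_um")
  if (!col %in% names(records))
    stop(sprintf("records lack the '%s' column", col))
  if (nlevels(records$technique) < 2)
    stop("both techniques must be present")
  records$y <- if (response == "icd") log(records[[col]]) else records[[col]]
  out <- list()
  form <- if (include_region) y ~ technique + region else y ~ technique
  fit <- fit_mixed(records, form, test_term = "techniquesvOCT",
                   test_var = "technique")
  i <- match("techniquesvOCT", fit$fixed_effects$term)
  out[[1]] <- data.frame(region = "pooled",
                         estimate = fit$fixed_effects$estimate[i],
                         se = fit$fixed_effects$se[i],
                         p = fit$fixed_effects$p[i],
                         n = fit$n_obs, note = "", stringsAsFactors = FALSE)
  if (by_region) {
    for (rg in levels(records$region)) {
      sub <- droplevels(records[records$region == rg, , drop = FALSE])
      if (nlevels(sub$technique) < 2) {
        out[[length(out) + 1]] <- data.frame(
          region = rg, estimate = NA_real_, se = NA_real_, p = NA_real_,
          n = nrow(sub), note = "skipped: single technique",
          stringsAsFactors = FALSE)
        next
      }
      fit_r <- fit_mixed(sub, y ~ technique, test_term = "techniquesvOCT",
                         test_var = "technique")
      i <- match("techniquesvOCT", fit_r$fixed_effects$term)
      out[[length(out) + 1]] <- data.frame(
        region = rg, estimate = fit_r$fixed_effects$estimate[i],
        se = fit_r$fixed_effects$se[i], p = fit_r$fixed_effects$p[i],
        n = nrow(sub), note = "", stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "response") <- response
  attr(res, "log_transformed") <- response == "icd"
  res
}

#' Arcuate versus other-region contrast
#'
#' Pools the arcuate sectors (ST and IT, following the arcuate nerve fibre
#' bundles) against the other four regions with a binary fixed effect and
#' eye-within-subject random intercepts; ICD is log-transformed.
#'
#' @param records study-record data.frame (single technique or mixed; a
#'   `technique` column value can be selected with `technique`).
#' @param response `"icd"` or `"density"`.
#' @param technique optionally restrict to one technique first.
#' @return List with `estimate`, `se`, `p`, `n` (estimate is arcuate minus
#'   other, log scale for ICD).
#' @export
compare_arcuate <- function(records, response = c("icd", "density"),
                            technique = NULL) {
  response <- match.arg(response)
  records <- validate_records(records)
  if (!is.null(technique))
    records <- droplevels(records[records$technique == technique, ,
                                  drop = FALSE])
  if (!all(study_regions %in% unique(as.character(records$region))))
    stop("all six regions must be present")
  col <- if (response == "icd") "icd_um" else "density_per_100um"
  records$y <- if (response == "icd") log(records[[col]]) else records[[col]]
  records$arcuate <- factor(
    ifelse(records$region %in% c("ST", "IT"), "arcuate", "other"),
    levels = c("other", "arcuate"))
  fit <- fit_mixed(records, y ~ arcuate, test_term = "arcuatearcuate",
                   test_var = "arcuate")
  i <- match("arcuatearcuate", fit$fixed_effects$term)
  list(estimate = fit$fixed_effects$estimate[i],
       se = fit$fixed_effects$se[i],
       p = fit$fixed_effects$p[i],
       n = fit$n_obs, fit = fit)
}

#' Two-sample t-test on group ages
#'
#' Welch two-sided t-test comparing two age samples (e.g. imaged subjects
#' versus tissue donors), with means and SDs formatted for reporting.
#' Degenerate inputs (both groups constant) give `t = 0, p = 1` when the
#' means agree.
#'
#' @param group_a,group_b numeric age vectors (n >= 2 each).
#' @return List with `t`, `p`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `summary` (formatted "mean +/- sd vs mean +/- sd").
#' @export
ages_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need at least 2 ages per group")
  tt <- tryCatch(stats::t.test(group_a, group_b), error = function(e) NULL)
  if (is.null(tt)) {
    equal <- abs(mean(group_a) - mean(group_b)) < 1e-12
    tt <- list(statistic = c(t = 0), p.value = if (equal) 1 else 0)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_a = mean(group_a), sd_a = stats::sd(group_a),
       mean_b = mean(group_b), sd_b = stats::sd(group_b),
       summary = sprintf("%.1f +/- %.1f vs %.1f +/- %.1f years (p = %.3f)",
                         mean(group_a), stats::sd(group_a),
                         mean(group_b), stats::sd(group_b), tt$p.value))
}
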