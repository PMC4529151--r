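# Mixed-model analyses of study tables.

test_that("noise-free tables are recovered exactly", {
  # slope 0, no noise, no intercepts: ICD equals the region mean exactly
  tab0 <- generate_study_table(n_subjects = 4, rnfl_slope = 0, noise_sd = 0,
                               random_intercept_sd = 0, seed = 1)
  means <- c(Sup = 38, ST = 31, Temp = 36, IT = 32, "Inf" = 38, N = 40)
  expect_equal(tab0$icd_um, unname(means[tab0$region]))
  # nonzero slope, no noise: OLS recovers it to machine precision
  tab <- generate_study_table(n_subjects = 4, rnfl_slope = -0.065,
                              noise_sd = 0, random_intercept_sd = 0, seed = 2)
  ols <- stats::lm(icd_um ~ rnfl_um + region, data = tab)
  expect_equal(unname(coef(ols)["rnfl_um"]), -0.065, tolerance = 1e-10)
  # and the mixed-model entry point reports the same slope
  fit <- fit_icd_rnfl(tab)
  expect_equal(fit$slope, -0.065, tolerance = 1e-8)
  expect_true(fit$degenerate)
})

test_that("the generator is seed-deterministic", {
  a <- generate_study_table(seed = 5)
  b <- generate_study_table(seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 16 * 6)
})

test_that("with zero random variances the mixed fit matches OLS", {
  # data generated without group effects whose REML solution sits on the
  # zero-variance boundary: the fixed effects must coincide with OLS
  tab <- generate_study_table(n_subjects = 6, noise_sd = 2,
                              random_intercept_sd = 0, seed = 2)
  fit <- fit_icd_rnfl(tab)
  expect_lt(max(fit$varcomp[c("subject", "eye_in_subject")]), 1e-10)
  tab$region <- factor(tab$region,
                       levels = c("Sup", "ST", "Temp", "IT", "Inf", "N"))
  ols <- stats::lm(icd_um ~ rnfl_um + region, data = tab)
  expect_equal(fit$slope, unname(coef(ols)["rnfl_um"]), tolerance = 1e-6)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
})

test_that("fixed effects are invariant to subject relabeling", {
  tab <- generate_study_table(n_subjects = 6, seed = 4)
  fit1 <- fit_icd_rnfl(tab)
  relab <- tab
  map <- stats::setNames(sample(unique(tab$subject_id)),
                         unique(tab$subject_id))
  relab$subject_id <- unname(map[tab$subject_id])
  fit2 <- fit_icd_rnfl(relab)
  expect_equal(fit2$slope, fit1$slope, tolerance = 1e-8)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-8)
})

test_that("log-transform preserves the sign of effects", {
  tab <- generate_study_table(n_subjects = 6, rnfl_slope = -0.065, seed = 6)
  raw <- fit_icd_rnfl(tab, transform = "none")
  lg <- fit_icd_rnfl(tab, transform = "log")
  expect_equal(sign(raw$slope), sign(lg$slope))
})

test_that("identical techniques give a null contrast", {
  tab <- generate_study_table(n_subjects = 4, techniques = c("svOCT", "histology"),
                              noise_sd = 0, random_intercept_sd = 0,
                              rnfl_slope = 0, seed = 7)
  ct <- compare_techniques(tab)
  expect_true(all(abs(ct$estimate) < 1e-10, na.rm = TRUE))
  expect_true(all(ct$p > 0.99, na.rm = TRUE))
})

test_that("a constant additive technique offset is recovered exactly", {
  tab <- generate_study_table(n_subjects = 4, techniques = c("svOCT", "histology"),
                              noise_sd = 0, random_intercept_sd = 0,
                              rnfl_slope = 0, technique_offset = 5, seed = 8)
  # offset is applied to histology; estimate is svOCT - histology on the
  # log scale, region by region
  ct <- compare_techniques(tab)
  means <- c(Sup = 38, ST = 31, Temp = 36, IT = 32, "Inf" = 38, N = 40)
  for (rg in names(means)) {
    est <- ct$estimate[ct$region == rg]
    expect_equal(est, log(means[[rg]]) - log(means[[rg]] + 5),
                 tolerance = 1e-8)
  }
})

test_that("a nasal-only offset is flagged there and rarely elsewhere", {
  hits <- 0; false_other <- 0; n_other <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    tb <- generate_study_table(n_subjects = 8, n_eyes = 15,
                               techniques = c("svOCT", "histology"),
                               technique_offset = c(N = 6), seed = 3000 + r)
    ct <- compare_techniques(tb)
    pN <- ct$p[ct$region == "N"]
    pr <- ct$p[!ct$region %in% c("N", "pooled")]
    if (!is.na(pN) && pN < 0.05) hits <- hits + 1
    false_other <- false_other + sum(pr < 0.05, na.rm = TRUE)
    n_other <- n_other + sum(!is.na(pr))
  }
  expect_gte(hits / n_rep, 0.8)
  expect_lt(false_other / n_other, 0.12)
})

test_that("arcuate contrast finds a constructed density difference", {
  tab <- generate_study_table(n_subjects = 6, noise_sd = 0,
                              random_intercept_sd = 0, rnfl_slope = 0,
                              seed = 9)
  arc <- compare_arcuate(tab)
  expect_lt(arc$estimate, 0)        # ST/IT means are below the others
  expect_lt(arc$p, 1e-6)
})

test_that("arcuate p-values are uniform under permuted region labels", {
  ps <- vapply(1:500, function(r) {
    tb <- generate_study_table(n_subjects = 8, n_eyes = 15,
                               icd_means = c(Sup = 36, ST = 36, Temp = 36,
                                             IT = 36, "Inf" = 36, N = 36),
                               rnfl_slope = 0, seed = 5000 + r)
    # permute region labels within the table
    tb$region <- with_seed(6000 + r, sample(tb$region))
    compare_arcuate(tb)$p
  }, numeric(1))
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("the age comparison behaves like a Welch t-test", {
  a <- c(28, 35, 44, 52, 60); b <- c(15, 30, 45, 60, 75)
  res <- ages_ttest(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  # closed-form hand computation on 2+2 values
  x <- c(1, 3); y <- c(2, 6)
  t_hand <- (mean(x) - mean(y)) / sqrt(var(x) / 2 + var(y) / 2)
  expect_equal(ages_ttest(x, y)$t, t_hand, tolerance = 1e-10)
  # degenerate cases
  expect_equal(ages_ttest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(ages_ttest(c(2, 2, 2), c(2, 2, 2))$p, 1)
  expect_equal(ages_ttest(c(1, 2, 3), c(1, 2, 3))$t, 0)
})

test_that("record validation rejects malformed tables", {
  tab <- generate_study_table(seed = 1)
  bad <- tab; bad$region[1] <- "XX"
  expect_error(fit_icd_rnfl(bad), "region")
  expect_error(fit_icd_rnfl(tab[, -5]), "missing")
  one_subj <- tab[tab$subject_id == "S01", ]
  expect_error(fit_icd_rnfl(one_subj), "2 subjects")
})
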