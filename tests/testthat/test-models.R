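test_that("noiseless cohorts are recovered coefficient-for-coefficient", {
  fe <- list(intercept = 2.5, time = -0.012, fc = 0.05, pib = -0.03,
             fc_pib = 0.02, age = -0.002, sex = -0.04, edu = 0.003,
             fc_time = 0.04, pib_time = -0.025, fc_pib_time = -0.3,
             age_time = -0.001, sex_time = 0.002, edu_time = -0.0005)
  ch <- generate_cohort(cohort_config(n_subjects = 60, fixed_effects = fe,
                                      random_sd = c(0, 0), residual_sd = 0,
                                      with_optional = FALSE, seed = 31))
  fit <- suppressWarnings(fit_thinning_lme(ch$table))
  est <- coef(fit)
  expected <- c("(Intercept)" = fe$intercept, fc = fe$fc, pib = fe$pib,
                time = fe$time, age = fe$age, sex = fe$sex, edu = fe$edu,
                "fc:pib" = fe$fc_pib, "fc:time" = fe$fc_time,
                "pib:time" = fe$pib_time, "time:age" = fe$age_time,
                "time:sex" = fe$sex_time, "time:edu" = fe$edu_time,
                "fc:pib:time" = fe$fc_pib_time)
  expect_equal(est[names(expected)], expected, tolerance = 1e-6)
})

test_that("reported degrees of freedom follow the rows-minus-terms convention", {
  ch <- generate_cohort(cohort_config(n_subjects = 40, seed = 32))
  tab <- ch$table
  tab$group <- classify_amyloid(tab$pib)
  fit <- suppressWarnings(fit_thinning_lme(tab))
  expect_equal(nrow(fit$coefficients), 14)
  expect_true(all(fit$coefficients$df == fit$n_obs - 14))

  sf <- suppressWarnings(fit_thinning_lme(tab, model = "stratified", group = "low"))
  expect_equal(nrow(sf$coefficients), 10)
  expect_true(all(sf$coefficients$df == sf$n_obs - 10))
  expect_false("pib" %in% sf$coefficients$term)

  af <- suppressWarnings(fit_thinning_lme(tab, model = "stratified", group = "low",
                                          extras = c("fpcn_fc", "fpcn_thickness",
                                                     "it_tau")))
  expect_equal(nrow(af$coefficients), 15)
  expect_true(all(c("fpcn_fc", "time:fpcn_fc", "fpcn_thickness",
                    "it_tau", "time:it_tau") %in% af$coefficients$term))

  # consistency of the derived statistics
  cf <- fit$coefficients
  expect_equal(cf$t, cf$estimate / cf$se)
  expect_equal(cf$d, 2 * cf$t / sqrt(cf$df))
  expect_true(all(sign(cf$d) == sign(cf$t) | cf$t == 0))
})

test_that("a slope effect planted only in one group appears only there", {
  fe_hi <- list(fc_time = 0.12, fc_pib_time = 0, pib_time = 0)
  fe_lo <- list(fc_time = 0, fc_pib_time = 0, pib_time = 0)
  hi <- generate_cohort(cohort_config(n_subjects = 33, fixed_effects = fe_hi,
                                      seed = 33))$table
  lo <- generate_cohort(cohort_config(n_subjects = 87, fixed_effects = fe_lo,
                                      seed = 34))$table
  hi$subject <- hi$subject + 1000
  hi$group <- "high"; lo$group <- "low"
  tab <- rbind(hi, lo)
  f_hi <- suppressWarnings(fit_thinning_lme(tab, model = "stratified", group = "high"))
  f_lo <- suppressWarnings(fit_thinning_lme(tab, model = "stratified", group = "low"))
  t_hi <- f_hi$coefficients$t[f_hi$coefficients$term == "fc:time"]
  t_lo <- f_lo$coefficients$t[f_lo$coefficients$term == "fc:time"]
  expect_gt(t_hi, 2.5)
  expect_lt(abs(t_lo), 2)
})

test_that("augmenting a noiseless fit leaves existing estimates unchanged", {
  # no PiB dependence in the truth: the stratified model omits PiB terms, so
  # the noiseless data must lie exactly in its design span
  ch <- generate_cohort(cohort_config(n_subjects = 40,
                                      fixed_effects = list(fc_time = 0.08,
                                                           pib_time = 0,
                                                           fc_pib_time = 0),
                                      random_sd = c(0, 0), residual_sd = 0,
                                      seed = 35))
  tab <- ch$table
  tab$group <- "high"
  tab$fpcn_thickness <- NULL; tab$it_tau <- NULL
  base <- suppressWarnings(fit_thinning_lme(tab, model = "stratified", group = "high"))
  aug <- suppressWarnings(fit_thinning_lme(tab, model = "stratified", group = "high",
                                           extras = "fpcn_fc"))
  shared <- intersect(base$coefficients$term, aug$coefficients$term)
  expect_equal(coef(aug)[shared], coef(base)[shared], tolerance = 1e-6)
})

test_that("a collinear extra inflates the standard errors of its twin", {
  set.seed(36)
  ch <- generate_cohort(cohort_config(n_subjects = 50, seed = 36))
  tab <- ch$table
  tab$group <- "high"
  fc_subj <- tab$fc[!duplicated(tab$subject)]
  near <- fc_subj + rnorm(50, 0, 0.02 * sd(fc_subj))
  tab$fpcn_fc <- near[match(tab$subject, unique(tab$subject))]
  base <- suppressWarnings(fit_thinning_lme(tab, model = "stratified", group = "high"))
  aug <- suppressWarnings(fit_thinning_lme(tab, model = "stratified", group = "high",
                                           extras = "fpcn_fc"))
  se0 <- base$coefficients$se[base$coefficients$term == "fc:time"]
  se1 <- aug$coefficients$se[aug$coefficients$term == "fc:time"]
  expect_gt(se1 / se0, 3)
})

test_that("with no random effects the mixed fit converges to pooled OLS", {
  ch <- generate_cohort(cohort_config(n_subjects = 200, random_sd = c(0, 0),
                                      residual_sd = 0.02, seed = 37))
  fit <- suppressWarnings(fit_thinning_lme(ch$table))
  d <- fit$data
  ols <- lm(thickness ~ fc * pib * time + (age + sex + edu) * time, data = d)
  expect_lt(max(abs(coef(fit)[names(coef(ols))] - coef(ols))), 1e-3)
})

test_that("input validation catches malformed modelling tables", {
  ch <- generate_cohort(cohort_config(n_subjects = 12, seed = 38))
  expect_error(fit_thinning_lme(ch$table[, -3]), "missing columns")
  expect_error(fit_thinning_lme(ch$table, model = "stratified"), "group")
  expect_error(fit_thinning_lme(ch$table, extras = "banana"), "unknown extras")
})

test_that("Satterthwaite df mode yields smaller df for between-subject slopes", {
  skip_if_not_installed("lmerTest")
  ch <- generate_cohort(cohort_config(n_subjects = 40, seed = 39))
  f1 <- suppressWarnings(fit_thinning_lme(ch$table))
  f2 <- suppressWarnings(fit_thinning_lme(ch$table, df_method = "satterthwaite"))
  df1 <- f1$coefficients$df[f1$coefficients$term == "fc:pib:time"]
  df2 <- f2$coefficients$df[f2$coefficients$term == "fc:pib:time"]
  expect_lt(df2, df1)
  expect_equal(coef(f1), coef(f2))
})

test_that("effect sizes follow d = 2t/sqrt(df) with sign preserved", {
  expect_equal(effect_size_from_t(0, 100), 0)
  expect_equal(effect_size_from_t(2.43, 421), 2 * 2.43 / sqrt(421))
  expect_equal(effect_size_from_t(-3, 64), -0.75)
  expect_error(effect_size_from_t(1, 0), "df")
})

test_that("pooled two-sample t handles the degenerate variance cases", {
  gc <- pooled_two_sample_t(1, 0.5, 10, 1.4, 0.5, 12)
  sp <- sqrt((9 * 0.25 + 11 * 0.25) / 20)
  expect_equal(gc$statistic, 0.4 / (sp * sqrt(1 / 10 + 1 / 12)))
  expect_equal(gc$df, 20)
  expect_equal(pooled_two_sample_t(3, 0, 5, 3, 0, 5)$statistic, 0)
  expect_error(pooled_two_sample_t(3, 0, 5, 4, 0, 5), "infinite")
  expect_error(pooled_two_sample_t(3, 0.1, 1, 4, 0.1, 5), "n >= 2")
})

test_that("the 2x2 chi-square matches the direct formula", {
  # perfectly proportional table: no association
  expect_equal(chi_square_2x2(matrix(c(20, 10, 40, 20), 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(c(10, 0, 0, 10), 2))$statistic, 20)

  set.seed(40)
  tab <- matrix(rpois(4, 20) + 1, 2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_square_2x2(tab)$statistic, sum((tab - e)^2 / e))
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("demeaning is exact and idempotent", {
  expect_equal(demean(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50); x0 <- x - mean(x)
  expect_equal(demean(x0), x0)
  expect_equal(demean(demean(x)), demean(x))
})
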