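#' Demean a numeric vector
#'
#' Subtracts the full-sample mean (the convention for continuous predictors
#' before modelling). Idempotent.
#'
#' @param x numeric vector with at least one finite value.
#' @return `x - mean(x)` (NAs ignored in the mean, preserved in the output).
#' @export
demean <- function(x) {
  fail_if(sum(is.finite(x)) < 1, "demean: need at least one finite value")
  x - mean(x, na.rm = TRUE)
}

# Internal: demean a subject-constant column across subjects (each subject
# counted once), so variable visit counts do not weight the mean.
demean_by_subject <- function(x, subject) {
  firsts <- !duplicated(subject)
  x - mean(x[firsts], na.rm = TRUE)
}

#' Fit the longitudinal cortical-thinning mixed model
#'
#' Fits the linear mixed-effects model family relating time-varying network
#' composite thickness to baseline functional connectivity (FC) and amyloid
#' burden (PiB DVR), with correlated random intercept and slope per subject:
#'
#' `thickness ~ fc * pib * time + (age + sex + edu) * time + (time | subject)`
#'
#' The three-way `fc:pib:time` term is the primary effect: whether baseline
#' connectivity and amyloid interact to modulate the rate of thinning.
#' Stratified fits (`model = "stratified"`) drop every PiB term and restrict
#' the rows to one amyloid group; augmented fits add specificity covariates
#' (`extras`): `"fpcn_fc"` (control-network FC, with its time interaction),
#' `"fpcn_thickness"` (time-varying control-network composite thickness, main
#' effect), `"it_tau"` (inferior-temporal tau SUVR, with its time
#' interaction).
#'
#' Continuous predictors (fc, pib, fpcn_fc, it_tau, age, edu) are demeaned
#' over the *full* supplied table — before any stratification — with
#' subject-constant columns demeaned across subjects. Inference follows the
#' residual-df reporting convention: `df = rows - fixed effects`, t = estimate
#' / SE, p from the t distribution, and Cohen's d = 2t/sqrt(df)
#' (`df_method = "satterthwaite"` switches to Satterthwaite df via lmerTest).
#'
#' @param data data.frame with columns `subject`, `time` (years from first
#'   visit), `thickness` (mm), `fc`, `pib`, `age`, `sex` (0/1), `edu`, plus
#'   any `extras` columns and `group` for stratified fits.
#' @param model `"primary"` or `"stratified"`.
#' @param group for stratified fits, the level of `data$group` to keep.
#' @param extras character subset of `c("fpcn_fc", "fpcn_thickness", "it_tau")`.
#' @param demean demean continuous predictors (default TRUE).
#' @param df_method `"residual"` (default) or `"satterthwaite"`.
#' @param REML fit by REML (default) or ML.
#' @return An object of class `thinning_lme`: a list with `coefficients`
#'   (data.frame: term, estimate, se, t, df, p, d), `primary_term`,
#'   `formula`, `fit` (the underlying `lmerMod`), `n_obs`, `n_subjects`,
#'   `converged`, `singular`, `ranef_sd`, `dropped` (rows lost to missing
#'   extras), and the call.
#' @seealso [effect_size_from_t()], [make_report()]
#' @export
fit_thinning_lme <- function(data, model = c("primary", "stratified"),
                             group = NULL, extras = character(),
                             demean = TRUE,
                             df_method = c("residual", "satterthwaite"),
                             REML = TRUE) {
  model <- match.arg(model)
  df_method <- match.arg(df_method)
  allowed <- c("fpcn_fc", "fpcn_thickness", "it_tau")
  bad <- setdiff(extras, allowed)
  fail_if(length(bad) > 0, "fit_thinning_lme: unknown extras: %s",
          paste(bad, collapse = ", "))
  need <- c("subject", "time", "thickness", "fc", "age", "sex", "edu",
            if (model == "primary") "pib", extras,
            if (model == "stratified") "group")
  miss <- setdiff(need, names(data))
  fail_if(length(miss) > 0, "fit_thinning_lme: missing columns: %s",
          paste(miss, collapse = ", "))

  d <- as.data.frame(data)
  if (demean) {
    for (v in intersect(c("fc", "pib", "fpcn_fc", "it_tau", "age", "edu"), names(d)))
      d[[v]] <- demean_by_subject(d[[v]], d$subject)
  }
  if (model == "stratified") {
    fail_if(is.null(group), "fit_thinning_lme: stratified fit needs `group`")
    d <- d[d$group == group, , drop = FALSE]
    fail_if(length(unique(d$subject)) < 5,
            "fit_thinning_lme: group '%s' has fewer than 5 subjects", group)
  }
  used <- stats::complete.cases(d[, need[need %in% names(d)], drop = FALSE])
  dropped <- sum(!used)
  if (dropped > 0) {
    message(sprintf("fit_thinning_lme: dropping %d row(s) with missing values", dropped))
    d <- d[used, , drop = FALSE]
  }
  fail_if(length(unique(d$subject)) < 10 && model == "primary",
          "fit_thinning_lme: need at least 10 subjects")

  fixed <- if (model == "primary") "fc * pib * time" else "fc * time"
  for (e in extras)
    fixed <- paste(fixed, switch(e,
      fpcn_fc = "+ fpcn_fc * time",
      fpcn_thickness = "+ fpcn_thickness",
      it_tau = "+ it_tau * time"))
  fixed <- paste(fixed, "+ (age + sex + edu) * time")
  fml <- as.formula(paste("thickness ~", fixed, "+ (time | subject)"))

  conv_msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = d, REML = REML,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      conv_msgs <<- c(conv_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("fit_thinning_lme: singular random-effects covariance", call. = FALSE)

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  tstat <- beta / se
  n <- nrow(d); p <- length(beta)
  if (df_method == "residual") {
    df <- rep(n - p, p)
  } else {
    fail_if(!requireNamespace("lmerTest", quietly = TRUE),
            "fit_thinning_lme: df_method = 'satterthwaite' requires lmerTest")
    ft <- lmerTest::as_lmerModLmerTest(fit)
    df <- coef(summary(ft))[, "df"]
  }
  pval <- 2 * pt(-abs(tstat), df)
  dval <- 2 * tstat / sqrt(df)
  vc <- as.data.frame(lme4::VarCorr(fit))

  structure(list(
    coefficients = data.frame(term = names(beta), estimate = unname(beta),
                              se = unname(se), t = unname(tstat),
                              df = unname(df), p = unname(pval),
                              d = unname(dval), row.names = NULL),
    primary_term = if (model == "primary") "fc:pib:time" else "fc:time",
    formula = fml, fit = fit, model = model, group = group, extras = extras,
    n_obs = n, n_subjects = length(unique(d$subject)),
    df_method = df_method, REML = REML,
    converged = length(conv_msgs) == 0, messages = conv_msgs,
    singular = singular,
    ranef_sd = vc[vc$grp == "subject" & is.na(vc$var2), "sdcor"],
    residual_sd = vc[vc$grp == "Residual", "sdcor"],
    dropped = dropped, data = d, call = match.call()),
    class = "thinning_lme")
}

#' @export
print.thinning_lme <- function(x, digits = 4, ...) {
  hdr <- switch(x$model, primary = "primary model",
                stratified = sprintf("stratified model (group = %s)", x$group))
  if (length(x$extras) > 0)
    hdr <- paste0(hdr, " + ", paste(x$extras, collapse = ", "))
  cat(sprintf("Longitudinal thinning LME — %s\n", hdr))
  cat(sprintf("  %d observations, %d subjects; %s, df = n - p = %d\n",
              x$n_obs, x$n_subjects, if (x$REML) "REML" else "ML",
              x$n_obs - nrow(x$coefficients)))
  cf <- x$coefficients
  cf$estimate <- signif(cf$estimate, digits); cf$se <- signif(cf$se, digits)
  cf$t <- round(cf$t, 2); cf$p <- signif(cf$p, 3); cf$d <- round(cf$d, 2)
  star <- ifelse(cf$term == x$primary_term, " <-- primary", "")
  print(cbind(cf, ` ` = star), row.names = FALSE)
  if (!x$converged) cat("  note: optimizer reported:", x$messages[1], "\n")
  if (x$singular) cat("  note: singular random-effects covariance\n")
  invisible(x)
}

#' @export
summary.thinning_lme <- function(object, ...) {
  structure(list(object = object), class = "summary.thinning_lme")
}

#' @export
print.summary.thinning_lme <- function(x, ...) {
  print(x$object)
  o <- x$object
  cat(sprintf("Random effects: intercept SD %.4g, slope SD %.4g; residual SD %.4g\n",
              o$ranef_sd[1], o$ranef_sd[2], o$residual_sd))
  pr <- o$coefficients[o$coefficients$term == o$primary_term, ]
  if (nrow(pr) == 1)
    cat(sprintf("Primary term %s: t(%d) = %.2f, p = %.3g, d = %.2f\n",
                o$primary_term, pr$df, pr$t, pr$p, pr$d))
  invisible(x)
}

#' @export
coef.thinning_lme <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
predict.thinning_lme <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) predict(object$fit, ...) else predict(object$fit, newdata, ...)
}

#' @export
residuals.thinning_lme <- function(object, ...) residuals(object$fit, ...)

#' @export
simulate.thinning_lme <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' @export
plot.thinning_lme <- function(x, ...) {
  d <- x$data
  plot(range(d$time), range(d$thickness), type = "n",
       xlab = "time from first visit (years)", ylab = "composite thickness (mm)",
       main = "Observed trajectories", ...)
  for (s in unique(d$subject)) {
    di <- d[d$subject == s, ]
    graphics::lines(di$time, di$thickness, col = grDevices::grey(0.4, 0.5))
  }
  invisible(x)
}

#' Cohen's d from a model t statistic
#'
#' The reporting convention `d = 2 t / sqrt(df)`, sign-preserving.
#'
#' @param t t statistic.
#' @param df residual degrees of freedom (> 0).
#' @return Cohen's d (vectorized).
#' @export
effect_size_from_t <- function(t, df) {
  fail_if(any(df <= 0), "effect_size_from_t: df must be > 0")
  2 * t / sqrt(df)
}

#' Pooled-variance two-sample t comparison
#'
#' Computes the pooled two-sample t statistic from group summaries:
#' `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2)`,
#' `t = |mean2 - mean1| / (sp sqrt(1/n1 + 1/n2))`, df = n1+n2-2.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (n >= 2, sd >= 0).
#' @return A list of class `group_comparison`: `statistic`, `df`, `p`,
#'   `pooled_sd`, and the inputs.
#' @export
pooled_two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  fail_if(n1 < 2 || n2 < 2, "pooled_two_sample_t: need n >= 2 per group")
  fail_if(sd1 < 0 || sd2 < 0, "pooled_two_sample_t: SDs must be >= 0")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) {
    fail_if(mean1 != mean2,
            "pooled_two_sample_t: zero pooled SD with unequal means (infinite statistic)")
    t <- 0
  } else {
    t <- abs(mean2 - mean1) / (sp * sqrt(1 / n1 + 1 / n2))
  }
  df <- n1 + n2 - 2
  structure(list(statistic = t, df = df, p = 2 * pt(-abs(t), df), pooled_sd = sp,
                 means = c(mean1, mean2), sds = c(sd1, sd2), ns = c(n1, n2),
                 type = "t"), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  lbl <- if (identical(x$type, "t")) sprintf("t(%d) = %.3f", x$df, x$statistic)
         else sprintf("chi-square(%d) = %.3f", x$df, x$statistic)
  cat(sprintf("<group_comparison> %s, p = %.3g\n", lbl, x$p))
  invisible(x)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction, df = 1.
#'
#' @param counts 2x2 matrix of counts; all expected counts must be > 0.
#' @return A list of class `group_comparison` with `statistic` (chi-square),
#'   `df`, `p`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  fail_if(!all(dim(counts) == c(2, 2)), "chi_square_2x2: need a 2x2 table")
  fail_if(any(rowSums(counts) == 0) || any(colSums(counts) == 0),
          "chi_square_2x2: zero margin")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  fail_if(any(ct$expected <= 0), "chi_square_2x2: expected count <= 0")
  structure(list(statistic = unname(ct$statistic), df = 1,
                 p = unname(ct$p.value), type = "chisq"),
            class = "group_comparison")
}
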