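#' Cohort generator configuration
#'
#' Generative parameters for the longitudinal synthetic cohort. The defaults
#' emulate the target study population: 120 clinically normal older adults
#' with 2–8 structural visits whose total span averages 5.04 years (SD 0.8,
#' clipped to 3.69–6.96), baseline age 73.35 (SD 6.0) years, 70/120 female,
#' education 16.0 (SD 2.9) years, and an amyloid (PiB FLR DVR) distribution
#' drawn from a two-component Gaussian mixture with means 1.08 / 1.46, SDs
#' 0.1 / 0.1 and weights 87:33.
#'
#' Thickness trajectories follow
#' \deqn{y_{it} = \beta_0 + b_{0i} + \beta_{fc} FC_i + \beta_{pib} PiB_i +
#'   \beta_{fp} FC_i PiB_i + \beta_{age} age_i + \beta_{sex} sex_i +
#'   \beta_{edu} edu_i + (\beta_t + \beta_{fc:t} FC_i + \beta_{pib:t} PiB_i +
#'   \beta_{fp:t} FC_i PiB_i + \beta_{age:t} age_i + \beta_{sex:t} sex_i +
#'   \beta_{edu:t} edu_i + b_{1i})\, t_{it} + \varepsilon_{it}}
#' with correlated random intercept/slope \eqn{(b_{0i}, b_{1i})} and
#' continuous predictors entered sample-demeaned (sex as a 0/1 indicator),
#' matching how the model stage constructs its design. The default planted
#' FC x PiB x time coefficient is negative, an interaction of study-like
#' magnitude (single-fit |t| around 2.5 at n = 120).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param visit_probs probabilities for 2..8 visits per subject; default
#'   matches the study's visit-count distribution (4, 56, and 60/5 each).
#' @param span_mean,span_sd,span_range mean, SD and clipping range (years) of
#'   each subject's total follow-up span.
#' @param visit_jitter uniform jitter on interior visit times, as a fraction
#'   of the nominal inter-visit interval.
#' @param fixed_effects named list of generative coefficients; see Details.
#'   Unnamed entries keep their defaults.
#' @param random_sd length-2 vector: SD of the random intercept (mm) and
#'   random slope (mm/year).
#' @param random_corr correlation between random intercept and slope.
#' @param residual_sd residual SD (mm).
#' @param fc_sd SD of the Gaussian baseline-connectivity ground truth.
#' @param pib_mixture list with `means`, `sds`, `weights` for the
#'   two-component DVR mixture (weights normalized to sum to 1).
#' @param age_mean,age_sd,sex_p,edu_mean,edu_sd covariate distributions.
#' @param with_optional also generate FPCN connectivity, time-varying FPCN
#'   composite thickness and inferior-temporal tau SUVR columns.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 120L,
                          visit_probs = c(4, 56, rep(60 / 5, 5)) / 120,
                          span_mean = 5.04, span_sd = 0.8,
                          span_range = c(3.69, 6.96), visit_jitter = 0.1,
                          fixed_effects = list(),
                          random_sd = c(intercept = 0.12, slope = 0.012),
                          random_corr = -0.2, residual_sd = 0.05,
                          fc_sd = 0.1,
                          pib_mixture = list(means = c(1.08, 1.46),
                                             sds = c(0.1, 0.1),
                                             weights = c(87, 33) / 120),
                          age_mean = 73.35, age_sd = 6.0, sex_p = 70 / 120,
                          edu_mean = 16.02, edu_sd = 2.9,
                          with_optional = TRUE, seed = NULL) {
  fail_if(n_subjects < 2, "cohort_config: need at least 2 subjects")
  fail_if(any(random_sd < 0) || residual_sd < 0 || any(pib_mixture$sds < 0),
          "cohort_config: SDs must be non-negative")
  fail_if(length(visit_probs) != 7 || any(visit_probs < 0),
          "cohort_config: visit_probs must give probabilities for 2..8 visits")
  pib_mixture$weights <- pib_mixture$weights / sum(pib_mixture$weights)
  beta <- list(intercept = 2.55, time = -0.010,
               fc = 0, pib = 0, fc_pib = 0, age = 0, sex = 0, edu = 0,
               fc_time = 0.02, pib_time = -0.02, fc_pib_time = -0.2,
               age_time = -5e-4, sex_time = 0, edu_time = 0)
  bad <- setdiff(names(fixed_effects), names(beta))
  fail_if(length(bad) > 0, "cohort_config: unknown fixed effects: %s",
          paste(bad, collapse = ", "))
  beta <- modifyList(beta, fixed_effects)
  structure(list(n_subjects = as.integer(n_subjects), visit_probs = visit_probs,
                 span_mean = span_mean, span_sd = span_sd,
                 span_range = span_range, visit_jitter = visit_jitter,
                 fixed_effects = beta, random_sd = random_sd,
                 random_corr = random_corr, residual_sd = residual_sd,
                 fc_sd = fc_sd, pib_mixture = pib_mixture,
                 age_mean = age_mean, age_sd = age_sd, sex_p = sex_p,
                 edu_mean = edu_mean, edu_sd = edu_sd,
                 with_optional = with_optional, seed = seed),
            class = "cohort_config")
}

#' Draw from a two-component Gaussian mixture
#'
#' @param n number of draws.
#' @param mixture list with `means`, `sds`, `weights` (two components each).
#' @return Numeric vector of draws, with the latent component as attribute
#'   `"component"`.
#' @export
rmixture2 <- function(n, mixture) {
  z <- 1L + (runif(n) > mixture$weights[1])
  structure(rnorm(n, mixture$means[z], mixture$sds[z]), component = z)
}

#' Generate a longitudinal synthetic cohort
#'
#' Draws per-subject baseline connectivity, amyloid burden, covariates and
#' random effects, schedules 2–8 visits over a study-like follow-up span, and
#' builds thickness trajectories from the generative linear mixed model
#' described in [cohort_config()]. Continuous predictors enter the generative
#' formula demeaned across subjects, exactly as the fitting stage demeans
#' them, so that in the noiseless limit every fitted coefficient reproduces
#' its generative value to machine precision.
#'
#' @param config a [cohort_config()].
#' @return A list with `table` (data.frame: subject, visit, time, thickness,
#'   fc, pib, age, sex, edu and, if configured, fpcn_fc, fpcn_thickness,
#'   it_tau) and `truth` (list of the per-subject latent values: fc, pib,
#'   pib_component, b0, b1, slope, plus the config).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, {
    n <- config$n_subjects
    beta <- config$fixed_effects

    k <- sample(2:8, n, replace = TRUE, prob = config$visit_probs)
    span <- pmin(pmax(rnorm(n, config$span_mean, config$span_sd),
                      config$span_range[1]), config$span_range[2])
    fc <- rnorm(n, 0, config$fc_sd)
    pib <- rmixture2(n, config$pib_mixture)
    age <- rnorm(n, config$age_mean, config$age_sd)
    sex <- rbinom(n, 1, config$sex_p)
    edu <- rnorm(n, config$edu_mean, config$edu_sd)

    # correlated random intercept/slope
    z1 <- rnorm(n); z2 <- rnorm(n)
    b0 <- config$random_sd[1] * z1
    b1 <- config$random_sd[2] *
      (config$random_corr * z1 + sqrt(1 - config$random_corr^2) * z2)

    fcd <- fc - mean(fc); pibd <- pib - mean(pib)
    aged <- age - mean(age); edud <- edu - mean(edu)
    level <- beta$intercept + b0 + beta$fc * fcd + beta$pib * pibd +
      beta$fc_pib * fcd * pibd + beta$age * aged + beta$sex * sex +
      beta$edu * edud
    slope <- beta$time + b1 + beta$fc_time * fcd + beta$pib_time * pibd +
      beta$fc_pib_time * fcd * pibd + beta$age_time * aged +
      beta$sex_time * sex + beta$edu_time * edud

    rows <- lapply(seq_len(n), function(i) {
      t <- span[i] * (seq_len(k[i]) - 1) / (k[i] - 1)
      if (k[i] > 2) {
        dt <- span[i] / (k[i] - 1)
        mid <- 2:(k[i] - 1)
        t[mid] <- sort(t[mid] + runif(length(mid), -1, 1) * config$visit_jitter * dt)
      }
      data.frame(subject = i, visit = seq_len(k[i]), time = t)
    })
    tab <- do.call(rbind, rows)
    i <- tab$subject
    tab$thickness <- level[i] + slope[i] * tab$time +
      rnorm(nrow(tab), 0, config$residual_sd)
    tab$fc <- fc[i]; tab$pib <- unclass(pib)[i]
    tab$age <- age[i]; tab$sex <- sex[i]; tab$edu <- edu[i]

    truth <- list(fc = fc, pib = unclass(pib),
                  pib_component = attr(pib, "component"),
                  b0 = b0, b1 = b1, level = level, slope = slope,
                  visits = k, span = span, config = config)

    if (config$with_optional) {
      fpcn_fc <- 0.4 * fc + rnorm(n, 0, config$fc_sd * sqrt(1 - 0.4^2))
      it_tau <- 1.15 + 0.25 * pmax(pib - 1.2, 0) + rnorm(n, 0, 0.05)
      tab$fpcn_fc <- fpcn_fc[i]
      tab$it_tau <- it_tau[i]
      # FPCN composite thickness: shares part of the subject's random structure
      tab$fpcn_thickness <- 2.45 + 0.8 * b0[i] + (-0.01 + 0.8 * b1[i]) * tab$time +
        rnorm(nrow(tab), 0, config$residual_sd)
      truth$fpcn_fc <- fpcn_fc; truth$it_tau <- it_tau
    }
    rownames(tab) <- NULL
    list(table = tab, truth = truth)
  })
}
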