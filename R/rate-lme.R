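## Somatic mutation rate per year from branch burdens.
##
## Terminal-branch mutation burdens are regressed on age at surgery with a
## no-intercept random-slope linear mixed model:
##   burden_ib = (beta + u_i) * age_i + eps_ib,   u_i ~ N(0, sigma_u^2),
## fitted by REML. The fixed slope beta is the cohort mutation rate per
## year; the shrunken per-patient slopes beta + u_i are the patient-specific
## rates used downstream for timing. Branches within a patient share the
## random slope, which absorbs the within-patient correlation induced by
## shared ancestry.

#' Fit the no-intercept random-slope mutation-rate model
#'
#' @param burdens data.frame with columns patient, branch, burden, age.
#' @param ci_boot number of parametric-bootstrap draws for the 95% CI of
#'   the fixed slope (0 skips the bootstrap).
#' @param seed seed for the bootstrap.
#' @return object of class `rate_model`: `beta` (mutations/year), `beta_ci`,
#'   `sigma_u` (between-patient slope SD), `sigma_resid`,
#'   `patient_slopes` (named, shrunken), `loglik`, `singular`, `n_patients`.
#' @export
fit_rate_lme <- function(burdens, ci_boot = 0L, seed = 1L) {
  stopifnot(all(c("patient", "burden", "age") %in% names(burdens)))
  if (any(burdens$age <= 0)) stopf("ages must be positive")
  patients <- unique(burdens$patient)

  degenerate <- all(burdens$burden == 0)
  if (length(patients) < 2L || degenerate) {
    ## a single patient (or an all-zero cohort) cannot identify sigma_u;
    ## fall back to least squares through the origin
    beta <- if (degenerate) 0 else
      sum(burdens$burden * burdens$age) / sum(burdens$age^2)
    out <- list(beta = beta, beta_ci = c(NA_real_, NA_real_),
                sigma_u = 0, sigma_resid = 0,
                patient_slopes = setNames(rep(beta, length(patients)),
                                          patients),
                loglik = NA_real_, singular = TRUE,
                n_patients = length(patients), fit = NULL)
    class(out) <- "rate_model"
    return(out)
  }

  burdens$patient <- factor(burdens$patient)
  fit <- lme4::lmer(burden ~ 0 + age + (0 + age | patient),
                    data = burdens, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular)
    message("rate model: singular fit (between-patient slope variance at 0)")
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u <- vc$sdcor[vc$grp == "patient"][1]
  slopes <- coef(fit)$patient[, "age"]
  names(slopes) <- rownames(coef(fit)$patient)

  ci <- c(NA_real_, NA_real_)
  if (ci_boot > 0L) {
    bs <- with_seed(seed, {
      replicate(ci_boot, {
        yb <- stats::simulate(fit)[[1]]
        d <- burdens; d$burden <- yb
        fb <- suppressMessages(suppressWarnings(
          lme4::lmer(burden ~ 0 + age + (0 + age | patient), data = d,
                     REML = TRUE)))
        lme4::fixef(fb)[["age"]]
      })
    })
    ci <- unname(quantile(bs, c(0.025, 0.975)))
  }

  out <- list(beta = unname(lme4::fixef(fit)[["age"]]), beta_ci = ci,
              sigma_u = sigma_u, sigma_resid = stats::sigma(fit),
              patient_slopes = slopes,
              loglik = as.numeric(logLik(fit)), singular = singular,
              n_patients = length(patients), fit = fit)
  class(out) <- "rate_model"
  out
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("Mutation-rate model: %.1f mutations/year", x$beta))
  if (!anyNA(x$beta_ci))
    cat(sprintf(" (95%% CI %.1f-%.1f)", x$beta_ci[1], x$beta_ci[2]))
  cat(sprintf("\n  between-patient SD %.1f, %d patients\n",
              x$sigma_u, x$n_patients))
  invisible(x)
}

#' Quadratic-in-age sensitivity check for the mutation-rate model
#'
#' Refits the rate model by maximum likelihood with and without a fixed
#' quadratic age term and compares them by a 1-df likelihood-ratio test.
#' A significant quadratic term would indicate the mutation rate increases
#' (or decreases) with age.
#'
#' @inheritParams fit_rate_lme
#' @return list with `fit_linear`, `fit_quadratic`, `lrt_stat`, `p_value`,
#'   `quad_coef`.
#' @export
fit_rate_quadratic <- function(burdens) {
  stopifnot(all(c("patient", "burden", "age") %in% names(burdens)))
  if (length(unique(burdens$patient)) < 2L)
    stopf("need >= 2 patients for the mixed model")
  burdens$patient <- factor(burdens$patient)
  ## the quadratic term uses (age/100)^2 so both predictors share a scale;
  ## the likelihood-ratio test is unaffected by the rescaling
  burdens$age2 <- (burdens$age / 100)^2
  m1 <- lme4::lmer(burden ~ 0 + age + (0 + age | patient),
                   data = burdens, REML = FALSE)
  m2 <- lme4::lmer(burden ~ 0 + age + age2 + (0 + age | patient),
                   data = burdens, REML = FALSE)
  lrt <- 2 * (as.numeric(logLik(m2)) - as.numeric(logLik(m1)))
  list(fit_linear = m1, fit_quadratic = m2,
       lrt_stat = lrt, p_value = pchisq(max(lrt, 0), df = 1,
                                        lower.tail = FALSE),
       quad_coef = unname(lme4::fixef(m2)[["age2"]]) / 1e4)
}

#' Patient-specific mutation rate (shrunken slope)
#'
#' @param model a `rate_model`.
#' @param patient patient id present in the fit.
#' @return mutations per year, `beta + u_i`.
#' @export
patient_rate <- function(model, patient) {
  stopifnot(inherits(model, "rate_model"))
  if (!patient %in% names(model$patient_slopes))
    stopf("patient %s was not in the fit", patient)
  unname(model$patient_slopes[[patient]])
}
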