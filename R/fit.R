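# The two LOS estimators: a linear mixed model on log(LOS) and a
# gaussian-family, log-link GLMM on raw LOS, each with an ICU random
# intercept.  Both are fitted by maximum likelihood (not REML) so that
# information criteria are comparable across fixed-effect sets; the
# GLMM marginal likelihood is handled by Laplace approximation.

.new_icu_fit <- function(model, fit, beta_hat, tau2_hat, sigma2_hat, re,
                         loglik, p, n_used, n_dropped, converged, n_iter,
                         spec, data) {
  structure(list(
    model = model, beta_hat = beta_hat, tau2_hat = tau2_hat,
    sigma2_hat = sigma2_hat, re = re, loglik = loglik, p = p,
    aic = -2 * loglik + 2 * p, bic = -2 * loglik + p * log(n_used),
    n_used = n_used, n_dropped = n_dropped, converged = converged,
    n_iter = n_iter, spec = spec, fit = fit, data = data),
    class = "icu_fit")
}

#' @export
print.icu_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d patients (%d dropped), %d ICUs\n",
              toupper(x$model), x$n_used, x$n_dropped, nrow(x$re)))
  cat(sprintf("  tau2 = %.4f  sigma2 = %.4f  logLik = %.1f  AIC = %.1f  BIC = %.1f\n",
              x$tau2_hat, x$sigma2_hat, x$loglik, x$aic, x$bic))
  cat(sprintf("  converged: %s (%s iterations)\n", x$converged,
              ifelse(is.na(x$n_iter), "?", x$n_iter)))
  invisible(x)
}

# degenerate single-site fit: the mixed model collapses to (generalised)
# least squares with tau2 = 0
.fit_single_site <- function(registry, spec, d, model) {
  form <- .spec_formula(spec, random = FALSE)
  fit <- if (model == "lmm") {
    stats::lm(form, data = d)
  } else {
    stats::glm(form, data = d, family = stats::gaussian(link = "log"),
               start = c(log(mean(d$los_days)),
                         rep(0, ncol(stats::model.matrix(form, d)) - 1)))
  }
  ll <- as.numeric(stats::logLik(fit))
  p <- attr(stats::logLik(fit), "df")
  sigma2 <- sum(stats::residuals(fit)^2) / nrow(d)  # ML variance
  re <- data.frame(icu_id = levels(d$icu_id), re = 0, se = 0)
  .new_icu_fit(model, fit, stats::coef(fit), 0, sigma2, re, ll, p,
               nrow(d), attr(d, "n_dropped"), TRUE, NA_integer_, spec, d)
}

.ranef_table <- function(fit) {
  rr <- as.data.frame(lme4::ranef(fit, condVar = TRUE))
  rr <- rr[rr$term == "(Intercept)", , drop = FALSE]
  data.frame(icu_id = as.character(rr$grp), re = rr$condval, se = rr$condsd,
             stringsAsFactors = FALSE)
}

#' Fit the linear mixed model on log(LOS)
#'
#' Maximum-likelihood fit of \code{log(los_days)} on the specification's
#' fixed terms with an ICU random intercept.  Rows with missing
#' covariates are dropped (complete-case) and the count recorded.
#' Per-ICU random-effect predictions (posterior modes / BLUPs) are
#' returned with conditional standard errors.
#'
#' @param registry An \code{icu_registry}.
#' @param spec A \code{\link{los_model_spec}} with
#'   \code{response = "log_los"}.
#' @return An object of class \code{icu_fit}.
#' @export
fit_lmm <- function(registry, spec = los_model_spec("log_los")) {
  stopifnot(inherits(registry, "icu_registry"),
            spec$response == "log_los")
  d <- .prep_model_data(registry, spec)
  form_fixed <- .spec_formula(spec, random = FALSE)
  .check_design_rank(stats::model.matrix(form_fixed, d))
  if (nlevels(d$icu_id) < 2) return(.fit_single_site(registry, spec, d, "lmm"))

  fit <- lme4::lmer(.spec_formula(spec), data = d, REML = FALSE)
  vc <- lme4::VarCorr(fit)
  ll <- as.numeric(stats::logLik(fit))
  .new_icu_fit("lmm", fit, lme4::fixef(fit),
               as.numeric(vc$icu_id[1, 1]), stats::sigma(fit)^2,
               .ranef_table(fit), ll, attr(stats::logLik(fit), "df"),
               stats::nobs(fit), attr(d, "n_dropped"),
               fit@optinfo$conv$opt == 0,
               as.integer(fit@optinfo$feval), spec, d)
}

#' Fit the gaussian-family, log-link GLMM on raw LOS
#'
#' Fits \code{los_days} (days, original scale) with a log link, gaussian
#' errors and an ICU random intercept, maximising the
#' Laplace-approximated marginal likelihood.  By default the fixed
#' effects and the random-intercept variance of the companion LMM on
#' log(LOS) seed the optimisation, which substantially stabilises this
#' notoriously hard fit.  Non-convergence is flagged on the returned
#' object, never silently discarded.
#'
#' @param registry An \code{icu_registry}.
#' @param spec A \code{\link{los_model_spec}} with
#'   \code{response = "los_days"}.
#' @param start_from_lmm Seed the optimiser from the LMM fit.
#' @param fix_tau2 Optionally pin the random-intercept variance at a
#'   fixed value (e.g. effectively zero) instead of estimating it; used
#'   for boundary diagnostics and oracle comparisons.
#' @return An object of class \code{icu_fit}.
#' @export
fit_glmm_log_gaussian <- function(registry,
                                  spec = los_model_spec("los_days"),
                                  start_from_lmm = TRUE,
                                  fix_tau2 = NULL) {
  stopifnot(inherits(registry, "icu_registry"),
            spec$response == "los_days")
  d <- .prep_model_data(registry, spec)
  form_fixed <- .spec_formula(spec, random = FALSE)
  X <- stats::model.matrix(form_fixed, d)
  .check_design_rank(X)
  if (nlevels(d$icu_id) < 2) return(.fit_single_site(registry, spec, d, "glmm"))

  start <- NULL
  if (start_from_lmm && is.null(fix_tau2)) {
    lmm <- fit_lmm(registry, los_model_spec_like(spec, "log_los"))
    start <- list(beta = unname(lmm$beta_hat[colnames(X)]),
                  theta = log(max(sqrt(lmm$tau2_hat), 1e-3)))
    if (anyNA(start$beta)) start <- NULL
  }
  map <- NULL
  if (!is.null(fix_tau2)) {
    map <- list(theta = factor(NA))
    start <- list(theta = log(max(sqrt(fix_tau2), 1e-6)))
  }
  fit <- glmmTMB::glmmTMB(.spec_formula(spec), data = d,
                          family = stats::gaussian(link = "log"),
                          start = start, map = map, REML = FALSE)
  vc <- glmmTMB::VarCorr(fit)$cond
  tau2 <- if (!is.null(fix_tau2)) fix_tau2 else as.numeric(vc$icu_id[1, 1])
  rr <- as.data.frame(glmmTMB::ranef(fit))
  rr <- rr[rr$component == "cond", , drop = FALSE]
  re <- data.frame(icu_id = as.character(rr$grp), re = rr$condval,
                   se = rr$condsd, stringsAsFactors = FALSE)
  if (anyNA(re$se)) {
    # near the tau2 = 0 boundary the Hessian-based conditional SEs are
    # unavailable; use the analytic random-intercept approximation
    # 1 / (1/tau2 + sum_j mu_ij^2 / sigma2) for the conditional variance
    mu_hat <- exp(stats::predict(fit, type = "link"))
    info <- tapply(mu_hat^2, d$icu_id, sum) / stats::sigma(fit)^2
    approx_se <- sqrt(1 / (1 / max(tau2, 1e-12) + info))
    re$se[is.na(re$se)] <- approx_se[re$icu_id[is.na(re$se)]]
  }
  ll <- as.numeric(stats::logLik(fit))
  conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  if (!conv) warning("GLMM did not converge cleanly; inspect $fit")
  .new_icu_fit("glmm", fit, glmmTMB::fixef(fit)$cond, tau2,
               stats::sigma(fit)^2, re, ll, attr(stats::logLik(fit), "df"),
               stats::nobs(fit), attr(d, "n_dropped"), conv,
               as.integer(fit$fit$iterations), spec, d)
}

# clone a specification with a different response
#' @keywords internal
los_model_spec_like <- function(spec, response) {
  out <- spec
  out$response <- response
  out
}
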