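# Predictions, validation and diagnostics for the fitted LOS models.

#' Predict LOS from a fitted model
#'
#' FE mode uses the fixed part \code{x'beta} only — the form used for
#' quality metrics, which deliberately excludes the site effect so the
#' metric can measure it; RE mode adds the ICU's predicted random
#' intercept.  For the GLMM the days scale is \code{exp(eta)} (the log
#' link guarantees positive predictions); for the LMM predictions are
#' naturally on the log scale and the days scale is the plain
#' exponential, i.e. a geometric-mean-type value with no retransformation
#' correction.
#'
#' @param model An \code{icu_fit}.
#' @param registry Registry to predict for; defaults to the estimation
#'   data.
#' @param mode \code{"FE"} (fixed part only) or \code{"RE"} (plus site
#'   intercept).
#' @param scale \code{"days"} or \code{"log_days"}.
#' @return A data frame of class \code{los_predictions} with columns
#'   \code{icu_id}, \code{obs} and \code{pred} (both on the requested
#'   scale), with attributes \code{mode}, \code{scale} and \code{model}.
#' @export
predict_los <- function(model, registry = NULL, mode = c("FE", "RE"),
                        scale = c("days", "log_days")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  stopifnot(inherits(model, "icu_fit"))
  d <- if (is.null(registry)) model$data else
    .prep_model_data(registry, model$spec)
  if (mode == "RE") {
    unseen <- setdiff(unique(as.character(d$icu_id)), model$re$icu_id)
    if (length(unseen)) {
      stop("no estimated random effect for ICU(s): ",
           paste(unseen, collapse = ", "))
    }
  }
  eta <- .linear_predictor(model, d, mode)
  pred <- if (scale == "days") exp(eta) else eta
  obs <- if (scale == "days") d$los_days else log(d$los_days)
  out <- data.frame(icu_id = as.character(d$icu_id), obs = obs, pred = pred,
                    stringsAsFactors = FALSE)
  structure(out, mode = mode, scale = scale, model = model$model,
            class = c("los_predictions", "data.frame"))
}

# linear predictor on the link/log scale for either engine
.linear_predictor <- function(model, d, mode) {
  fit <- model$fit
  if (inherits(fit, "glmmTMB")) {
    re.form <- if (mode == "FE") NA else NULL
    stats::predict(fit, newdata = d, re.form = re.form, type = "link")
  } else if (inherits(fit, "merMod")) {
    re.form <- if (mode == "FE") NA else NULL
    stats::predict(fit, newdata = d, re.form = re.form)
  } else {
    # degenerate single-site least-squares branch (re = 0)
    if (inherits(fit, "glm")) {
      stats::predict(fit, newdata = d, type = "link")
    } else {
      stats::predict(fit, newdata = d)
    }
  }
}

#' Squared product-moment correlation of observations and predictions
#'
#' The simple validation statistic used for both estimators: the square
#' of the Pearson correlation between LOS and its model prediction, at
#' the patient level or aggregated to ICU means first.  Note the known
#' quirk that a perfectly anti-correlated prediction also scores 1.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param level \code{"patient"} or \code{"icu"}; the latter averages
#'   both vectors within ICU before correlating.
#' @param icu_id Site identifiers, required for \code{level = "icu"}.
#' @return R-squared in [0, 1], or \code{NA} (with a warning) when
#'   either vector is constant.
#' @export
r_squared <- function(observed, predicted, level = c("patient", "icu"),
                      icu_id = NULL) {
  level <- match.arg(level)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  if (level == "icu") {
    if (is.null(icu_id)) stop("icu_id is required for ICU-level R2")
    observed <- tapply(observed, icu_id, mean)
    predicted <- tapply(predicted, icu_id, mean)
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("constant vector: R2 undefined")
    return(NA_real_)
  }
  stats::cor(observed, predicted)^2
}

#' Split-sample validation with sites as strata
#'
#' Randomly allocates whole ICUs to a development and a validation arm,
#' refits the chosen estimator on the development sites, and reports
#' patient-level R-squared in both arms: RE (fitted) predictions
#' in-sample, FE predictions out-of-sample — validation sites have no
#' estimated random effect.
#'
#' @param registry An \code{icu_registry}.
#' @param spec A \code{\link{los_model_spec}}.
#' @param estimator \code{"lmm"} or \code{"glmm"}.
#' @param fraction Development-arm share of sites (default 0.6).
#' @param seed Seed for the site allocation.
#' @return A list with the site lists, per-arm sample sizes and
#'   R-squared values.
#' @export
split_sample_validation <- function(registry, spec, estimator = c("lmm", "glmm"),
                                    fraction = 0.6, seed = 1L) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(registry, "icu_registry"))
  sites <- registry$sites$icu_id
  n_dev <- round(fraction * length(sites))
  if (n_dev < 2 || length(sites) - n_dev < 2) {
    stop("split leaves fewer than 2 sites in one arm")
  }
  dev_sites <- .with_seed(seed, sample(sites, n_dev))
  val_sites <- setdiff(sites, dev_sites)
  sub <- function(ids) {
    structure(list(patients = registry$patients[
                     registry$patients$icu_id %in% ids, , drop = FALSE],
                   sites = registry$sites[
                     registry$sites$icu_id %in% ids, , drop = FALSE],
                   provenance = registry$provenance),
              class = "icu_registry")
  }
  dev_reg <- sub(dev_sites)
  val_reg <- sub(val_sites)
  fit <- if (estimator == "lmm") fit_lmm(dev_reg, spec) else
    fit_glmm_log_gaussian(dev_reg, spec)
  scale <- if (estimator == "lmm") "log_days" else "days"
  pr_dev <- predict_los(fit, dev_reg, mode = "RE", scale = scale)
  pr_val <- predict_los(fit, val_reg, mode = "FE", scale = scale)
  list(estimator = estimator,
       development_sites = sort(dev_sites),
       validation_sites = sort(val_sites),
       n_development = nrow(pr_dev), n_validation = nrow(pr_val),
       r2_development = r_squared(pr_dev$obs, pr_dev$pred),
       r2_validation = r_squared(pr_val$obs, pr_val$pred),
       fit = fit)
}

#' Residual diagnostics
#'
#' For the LMM: conventional (conditional) residuals and residuals
#' standardised by the estimated residual SD.  For the gaussian-family
#' GLMM both the deviance and the Anscombe residual reduce to the raw
#' response residual \code{y - mu}, which is reported under both names.
#'
#' @param model An \code{icu_fit}.
#' @return A list with a per-patient residual table and a summary
#'   (mean, SD, counts beyond 2 and 4 SDs).
#' @export
residual_diagnostics <- function(model) {
  stopifnot(inherits(model, "icu_fit"))
  d <- model$data
  if (model$model == "lmm") {
    eta <- .linear_predictor(model, d, "RE")
    raw <- log(d$los_days) - eta
    std <- raw / sqrt(model$sigma2_hat)
    tab <- data.frame(icu_id = as.character(d$icu_id),
                      raw = raw, standardized = std)
  } else {
    mu <- exp(.linear_predictor(model, d, "RE"))
    raw <- d$los_days - mu
    tab <- data.frame(icu_id = as.character(d$icu_id),
                      deviance = raw, anscombe = raw)
    std <- raw / sqrt(model$sigma2_hat)
  }
  list(residuals = tab,
       summary = data.frame(mean_raw = mean(raw), sd_raw = stats::sd(raw),
                            mean_standardized = mean(std),
                            n_beyond_2sd = sum(abs(std) > 2),
                            n_beyond_4sd = sum(abs(std) > 4)))
}

#' Omnibus skewness/kurtosis normality test
#'
#' D'Agostino-Pearson K-squared: combines the transformed sample
#' skewness and kurtosis into a chi-squared(2) statistic.  Very large
#' inputs are subsampled (deterministically given \code{seed}) since at
#' registry scale the test rejects for immaterial deviations.
#'
#' @param values Numeric vector, \code{n >= 20}.
#' @param alpha Rejection level for the verdict (default 0.05).
#' @param max_n Subsample cap (default 50000).
#' @param seed Seed for the subsample draw.
#' @return List with \code{statistic}, \code{p_value}, \code{verdict}
#'   (\code{"rejected"}/\code{"not rejected"}), \code{skewness},
#'   \code{kurtosis} and \code{n}.
#' @export
normality_check <- function(values, alpha = 0.05, max_n = 50000L,
                            seed = 20231L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 20) stop("need at least 20 finite values")
  if (stats::sd(values) == 0) stop("constant input: normality undefined")
  if (n > max_n) {
    values <- .with_seed(seed, sample(values, max_n))
    n <- max_n
  }
  m <- mean(values)
  m2 <- mean((values - m)^2)
  g1 <- mean((values - m)^3) / m2^1.5
  b2 <- mean((values - m)^4) / m2^2

  # D'Agostino (1970) transformed skewness
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  a <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / a)

  # Anscombe-Glynn (1983) transformed kurtosis
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  x <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z2 <- ((1 - 2 / (9 * aa)) -
           ((1 - 2 / aa) / (1 + x * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))

  k2 <- z1^2 + z2^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  list(statistic = k2, p_value = p,
       verdict = if (p < alpha) "rejected" else "not rejected",
       skewness = g1, kurtosis = b2, n = n)
}
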