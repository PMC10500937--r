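# Generation of synthetic patient-level ICU registries.

# evaluate `code` under a given seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# largest-remainder apportionment of `total` into shares `w`
.apportion <- function(total, w) {
  x <- total * w / sum(w)
  n <- floor(x)
  rem <- x - n
  k <- total - sum(n)
  if (k > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(k)]
    n[idx] <- n[idx] + 1
  }
  as.integer(n)
}

# conditional mean of lognormal(mu, sdlog) restricted to [lo, hi]
.cond_lnorm_mean <- function(mu, sdlog, lo, hi) {
  plo <- plnorm(lo, mu, sdlog); phi <- plnorm(hi, mu, sdlog)
  f <- function(x) x * dlnorm(x, mu, sdlog)
  integrate(f, lo, hi, rel.tol = 1e-9)$value / (phi - plo)
}

.solve_volume_mu <- function(target, sdlog, lo, hi) {
  uniroot(function(m) .cond_lnorm_mean(m, sdlog, lo, hi) - target,
          interval = log(c(max(lo, target / 8), target * 2)), tol = 1e-8)$root
}

# systematic mid-quantiles of the truncated lognormal volume law
.class_volumes <- function(n, mean_vol, log_sd, lo, hi) {
  mu <- .solve_volume_mu(mean_vol, log_sd, lo, hi)
  p <- (seq_len(n) - 0.5) / n
  plo <- plnorm(lo, mu, log_sd); phi <- plnorm(hi, mu, log_sd)
  round(qlnorm(plo + p * (phi - plo), mu, log_sd))
}

# draw n patient covariate rows under the current RNG state
.draw_covariates <- function(cfg, n) {
  cp <- cfg$covariate_params
  age <- qnorm(pnorm((cp$age$min - cp$age$mu) / cp$age$sd) +
                 runif(n) * (1 - pnorm((cp$age$min - cp$age$mu) / cp$age$sd)),
               cp$age$mu, cp$age$sd)
  ap <- cp$apache
  z1 <- abs(rnorm(n)); z2 <- rnorm(n)
  sn <- ap$delta * z1 + sqrt(1 - ap$delta^2) * z2
  apache3 <- round(pmin(pmax(ap$xi + ap$omega * sn, ap$min), ap$max))
  az <- cp$anzrod
  lg <- (az$logit_median - az$slope * ap$mean) + az$slope * apache3 +
    rnorm(n, 0, az$resid_sd)
  anzrod <- plogis(lg)
  preicu_days <- rlnorm(n, cp$preicu$meanlog, cp$preicu$sdlog)
  pv <- cp$prev
  bin <- function(p) as.integer(runif(n) < p)
  dx_group <- sample.int(length(cp$dx_probs), n, replace = TRUE,
                         prob = cp$dx_probs)
  data.frame(age = age, apache3 = apache3, anzrod = anzrod,
             preicu_days = preicu_days,
             male = bin(pv[["male"]]), died_icu = bin(pv[["died_icu"]]),
             arf = bin(pv[["arf"]]), limitation = bin(pv[["limitation"]]),
             arrest = bin(pv[["arrest"]]), vent_d1 = bin(pv[["vent_d1"]]),
             dx_group = dx_group)
}

# design matrix for the generating (and default fitted) fixed effects
.design_from_covariates <- function(covs, dx_levels) {
  dx <- outer(covs$dx_group, seq_len(dx_levels), "==") + 0
  colnames(dx) <- paste0("dx", seq_len(dx_levels))
  X <- cbind(age = covs$age, age_sq = covs$age^2,
             apache3 = covs$apache3, apache3_sq = covs$apache3^2,
             log_anzrod = log(pmax(covs$anzrod, 1e-04)),
             preicu_days = covs$preicu_days,
             died_icu = covs$died_icu, arf = covs$arf,
             limitation = covs$limitation, arrest = covs$arrest,
             vent_d1 = covs$vent_d1)
  cbind(X, dx)
}

#' Generate a synthetic ICU registry
#'
#' Simulates a patient-level registry under a \code{\link{sim_config}}:
#' sites receive a hospital class, an annual volume and a latent random
#' intercept \code{u ~ N(0, tau2)}; each site contributes exactly
#' \code{annual_volume} patients; per patient the linear predictor is
#' \code{eta = beta0 + x'beta + u} on the log-mean scale and LOS is drawn
#' from the configured noise family with conditional mean
#' \code{exp(eta)} (lognormal: \code{log LOS ~ N(eta - sigma2/2, sigma2)};
#' gamma: shape/scale matched to the mean and the configured shape),
#' then truncated at \code{los_truncation_days}.
#'
#' Generation is fully determined by \code{config$seed} and does not
#' disturb the caller's RNG state.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An object of class \code{icu_registry}: a list with
#'   \code{patients} (one row per admission), \code{sites} (one row per
#'   ICU, including the latent \code{true_re}) and \code{provenance}
#'   (the configuration).
#' @examples
#' reg <- generate_registry(sim_config(n_icus = 5, seed = 7,
#'                                     volume_model = list(fixed = 40)))
#' nrow(reg$patients)
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    vm <- config$volume_model
    classes <- names(config$class_mix)
    n_c <- .apportion(config$n_icus,
                      config$class_mix / vm$mean[classes])
    hosp_class <- rep(classes, n_c)
    if (!is.null(vm$fixed)) {
      volume <- rep(as.integer(vm$fixed), config$n_icus)
    } else {
      volume <- unlist(lapply(seq_along(classes), function(i) {
        if (n_c[i] == 0) return(integer(0))
        .class_volumes(n_c[i], vm$mean[[classes[i]]],
                       vm$log_sd[[classes[i]]], vm$min, vm$max)
      }), use.names = FALSE)
    }
    # site intercepts are drawn conditionally on a zero volume-weighted
    # cohort mean, so the marginal LOS calibration does not hinge on the
    # luck of a single draw of ~100 site effects
    u <- rnorm(config$n_icus, 0, sqrt(config$tau2))
    if (config$tau2 > 0) u <- u - weighted.mean(u, volume)
    sites <- data.frame(icu_id = seq_len(config$n_icus),
                        hosp_class = hosp_class,
                        annual_volume = volume,
                        true_re = u)

    n <- sum(sites$annual_volume)
    icu_id <- rep(sites$icu_id, sites$annual_volume)
    covs <- .draw_covariates(config, n)
    X <- .design_from_covariates(covs, config$dx_levels)
    xb <- drop(X %*% config$beta[colnames(X)])
    # half-weight correction for the non-normality of x'beta: splits the
    # residual calibration error between the arithmetic mean and the
    # median/geometric mean of the marginal LOS distribution
    skew_adj <- 0.5 * (config$xb_K - config$xb_var / 2)
    beta0 <- config$mu + config$sigma2 / 2 - config$xb_mean - skew_adj
    eta <- beta0 + xb + sites$true_re[icu_id]
    if (any(!is.finite(eta))) stop("non-finite linear predictor; check beta")

    los <- switch(config$noise_family,
      lognormal = rlnorm(n, eta - config$sigma2 / 2, sqrt(config$sigma2)),
      gamma = {
        shape <- config$gamma_shape
        if (is.null(shape)) shape <- 1 / (exp(config$sigma2) - 1)
        rgamma(n, shape = shape, scale = exp(eta) / shape)
      })
    los <- pmin(pmax(los, 1e-3), config$los_truncation_days)

    patients <- cbind(data.frame(icu_id = icu_id), covs,
                      data.frame(los_days = los))
    if (config$missing_rate > 0) {
      drop_idx <- which(runif(n) < config$missing_rate)
      patients$apache3[drop_idx] <- NA_integer_
      patients$anzrod[drop_idx] <- NA_real_
    }
    structure(list(patients = patients, sites = sites, provenance = config),
              class = "icu_registry")
  })
}

#' @export
print.icu_registry <- function(x, ...) {
  cat(sprintf("ICU registry: %d patients across %d ICUs\n",
              nrow(x$patients), nrow(x$sites)))
  cat(sprintf("  LOS (days): mean %.2f, median %.2f, max %.1f\n",
              mean(x$patients$los_days), median(x$patients$los_days),
              max(x$patients$los_days)))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$sites$hosp_class)),
                            table(x$sites$hosp_class)), collapse = " ")))
  invisible(x)
}

.geo_mean <- function(x) exp(mean(log(x)))

#' Demographic summary of a registry
#'
#' Long-format cohort summary in the style of a registry demographics
#' table: LOS location/spread (arithmetic and geometric), covariate
#' means, binary prevalences, annual-volume statistics and hospital-class
#' patient shares.
#'
#' @param registry An \code{icu_registry}.
#' @return A data frame with columns \code{variable}, \code{stat},
#'   \code{value}.
#' @export
summarize_registry <- function(registry) {
  stopifnot(inherits(registry, "icu_registry"))
  p <- registry$patients
  s <- registry$sites
  if (nrow(p) == 0) stop("empty registry")
  vol_by_patient <- s$annual_volume[match(p$icu_id, s$icu_id)]
  class_by_patient <- s$hosp_class[match(p$icu_id, s$icu_id)]
  row <- function(variable, stat, value)
    data.frame(variable = variable, stat = stat, value = value)
  out <- rbind(
    row("n_patients", "count", nrow(p)),
    row("n_icus", "count", nrow(s)),
    row("los_days", "mean", mean(p$los_days)),
    row("los_days", "sd", sd(p$los_days)),
    row("los_days", "median", median(p$los_days)),
    row("los_days", "q25", unname(quantile(p$los_days, 0.25))),
    row("los_days", "q75", unname(quantile(p$los_days, 0.75))),
    row("los_days", "geo_mean", .geo_mean(p$los_days)),
    row("los_days", "geo_sd", exp(sd(log(p$los_days)))),
    row("age", "mean", mean(p$age, na.rm = TRUE)),
    row("age", "sd", sd(p$age, na.rm = TRUE)),
    row("apache3", "mean", mean(p$apache3, na.rm = TRUE)),
    row("apache3", "sd", sd(p$apache3, na.rm = TRUE)),
    row("anzrod", "median", median(p$anzrod, na.rm = TRUE)),
    row("preicu_days", "median", median(p$preicu_days, na.rm = TRUE)),
    row("annual_volume", "patient_weighted_mean", mean(vol_by_patient)),
    row("annual_volume", "site_median", median(s$annual_volume)))
  for (v in c("male", "died_icu", "vent_d1", "arf", "limitation", "arrest")) {
    if (!is.null(p[[v]])) out <- rbind(out, row(v, "proportion", mean(p[[v]])))
  }
  for (cl in sort(unique(s$hosp_class))) {
    out <- rbind(out, row(paste0("class_", cl), "patient_share",
                          mean(class_by_patient == cl)))
  }
  rownames(out) <- NULL
  out
}
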