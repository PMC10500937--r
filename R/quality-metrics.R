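# Per-ICU quality metrics — OMELOS, arithmetic and geometric RALOSR and
# site random effects — with bias-corrected and accelerated (BCa)
# bootstrap confidence intervals.

# stable integer hash of an id, for per-ICU bootstrap substreams
.stable_hash <- function(id) {
  v <- utf8ToInt(as.character(id))
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147480009
  as.integer(h)
}

#' Bias-corrected and accelerated bootstrap interval
#'
#' Nonparametric bootstrap of a scalar statistic with BCa endpoints:
#' bias correction \code{z0 = qnorm(#\{theta* < theta_hat\} / B)} and
#' acceleration \code{a} from the jackknife third-moment formula.
#' Deterministic given \code{seed}.  If the bootstrap distribution is
#' degenerate the interval collapses to the point estimate; if \code{z0}
#' is infinite the function falls back to percentile endpoints with a
#' warning.
#'
#' @param values A numeric vector, or a data frame resampled by rows
#'   (for paired statistics).
#' @param statistic Function of a sample returning a scalar.
#' @param B Bootstrap replications (default 1000).
#' @param alpha Two-sided level (default 0.05 for 95\% intervals).
#' @param seed Seed for resampling.
#' @return List with \code{point}, \code{ci_low}, \code{ci_high},
#'   \code{method} ("bca" or "percentile"), \code{se} (bootstrap SD),
#'   \code{z0}, \code{accel} and the replicate vector \code{theta_star}.
#' @examples
#' bca_interval(rexp(50), mean, B = 200, seed = 1)
#' @export
bca_interval <- function(values, statistic, B = 1000L, alpha = 0.05,
                         seed = 1L) {
  n <- NROW(values)
  if (n < 2) stop("need at least 2 observations")
  take <- if (is.data.frame(values)) {
    function(idx) values[idx, , drop = FALSE]
  } else {
    function(idx) values[idx]
  }
  theta_hat <- statistic(values)
  theta_star <- .with_seed(seed, {
    vapply(seq_len(B),
           function(b) statistic(take(sample.int(n, n, replace = TRUE))),
           numeric(1))
  })
  if (all(theta_star == theta_star[1])) {
    return(list(point = theta_hat, ci_low = theta_hat, ci_high = theta_hat,
                method = "bca", se = 0, z0 = 0, accel = 0,
                theta_star = theta_star))
  }
  z0 <- qnorm(mean(theta_star < theta_hat))
  if (!is.finite(z0)) {
    warning("all bootstrap replicates on one side of the estimate; ",
            "falling back to percentile interval")
    ci <- unname(quantile(theta_star, c(alpha / 2, 1 - alpha / 2)))
    return(list(point = theta_hat, ci_low = ci[1], ci_high = ci[2],
                method = "percentile", se = stats::sd(theta_star),
                z0 = z0, accel = NA_real_, theta_star = theta_star))
  }
  theta_jack <- vapply(seq_len(n),
                       function(i) statistic(take(-i)), numeric(1))
  dev <- mean(theta_jack) - theta_jack
  denom <- sum(dev^2)^1.5
  accel <- if (denom == 0) 0 else sum(dev^3) / (6 * denom)
  zq <- qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- pnorm(z0 + (z0 + zq) / (1 - accel * (z0 + zq)))
  ci <- unname(quantile(theta_star, adj))
  list(point = theta_hat, ci_low = ci[1], ci_high = ci[2], method = "bca",
       se = stats::sd(theta_star), z0 = z0, accel = accel,
       theta_star = theta_star)
}

# shared driver for the per-ICU paired-bootstrap metric tables
.metric_table <- function(predictions, metric_kind, source_model, statistic,
                          B, alpha, seed, log_se = FALSE) {
  stopifnot(inherits(predictions, "los_predictions"))
  if (attr(predictions, "mode") != "FE") {
    stop("quality metrics use fixed-effect predictions only")
  }
  ids <- unique(predictions$icu_id)
  rows <- lapply(ids, function(id) {
    d <- predictions[predictions$icu_id == id, c("obs", "pred")]
    n_i <- nrow(d)
    if (n_i < 2) {
      point <- statistic(d)
      return(data.frame(icu_id = id, metric_kind = metric_kind,
                        source_model = source_model, point = point,
                        ci_low = point, ci_high = point,
                        ci_method = "wald", n_patients = n_i,
                        se = 0, se_log = if (log_se) 0 else NA_real_))
    }
    bb <- bca_interval(d, statistic, B = B, alpha = alpha,
                       seed = (seed + .stable_hash(id)) %% 2147480009)
    data.frame(icu_id = id, metric_kind = metric_kind,
               source_model = source_model, point = bb$point,
               ci_low = bb$ci_low, ci_high = bb$ci_high,
               ci_method = bb$method, n_patients = n_i, se = bb$se,
               se_log = if (log_se) stats::sd(log(bb$theta_star))
                        else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, alpha = alpha, bootstrap_reps = B,
            class = c("metric_table", "data.frame"))
}

#' Observed minus expected LOS (OMELOS) per ICU
#'
#' For each ICU, the mean observed LOS minus the mean risk-adjusted
#' (fixed-effect predicted) LOS in days, with a BCa interval from
#' jointly resampling that ICU's (observed, predicted) pairs.  ICUs with
#' fewer than 2 patients fall back to a flagged zero-width Wald row.
#'
#' @param fe_predictions_days \code{\link{predict_los}} output, FE mode,
#'   days scale (GLMM source).
#' @param B,alpha,seed Bootstrap controls; per-ICU substreams are
#'   derived from \code{seed} and the ICU id, so results do not depend
#'   on iteration order.
#' @return A \code{metric_table} data frame.
#' @export
omelos_table <- function(fe_predictions_days, B = 1000L, alpha = 0.05,
                         seed = 1L) {
  stopifnot(attr(fe_predictions_days, "scale") == "days")
  .metric_table(fe_predictions_days, "omelos",
                attr(fe_predictions_days, "model"),
                function(d) mean(d$obs) - mean(d$pred), B, alpha, seed)
}

#' Arithmetic risk-adjusted LOS ratio (RALOSR) per ICU
#'
#' Ratio of mean observed to mean fixed-effect-predicted LOS (days),
#' bootstrapped as in \code{\link{omelos_table}}.  The bootstrap SD of
#' the log ratio is recorded for downstream rank inference on the log
#' scale.
#'
#' @inheritParams omelos_table
#' @export
ralosr_arith_table <- function(fe_predictions_days, B = 1000L, alpha = 0.05,
                               seed = 1L) {
  stopifnot(attr(fe_predictions_days, "scale") == "days")
  .metric_table(fe_predictions_days, "ralosr_arith",
                attr(fe_predictions_days, "model"),
                function(d) mean(d$obs) / mean(d$pred), B, alpha, seed,
                log_se = TRUE)
}

#' Geometric-mean RALOSR per ICU
#'
#' Ratio of the geometric mean of observed LOS to the geometric mean of
#' the (back-transformed) log-scale fixed-effect predictions — the
#' natural ratio metric for the log-LOS linear mixed model.
#'
#' @param fe_predictions_log \code{\link{predict_los}} output, FE mode,
#'   log-days scale (LMM source).
#' @inheritParams omelos_table
#' @export
ralosr_geo_table <- function(fe_predictions_log, B = 1000L, alpha = 0.05,
                             seed = 1L) {
  stopifnot(attr(fe_predictions_log, "scale") == "log_days")
  .metric_table(fe_predictions_log, "ralosr_geo",
                attr(fe_predictions_log, "model"),
                function(d) exp(mean(d$obs) - mean(d$pred)), B, alpha, seed,
                log_se = TRUE)
}

#' Site random effects with Wald intervals
#'
#' The predicted ICU random intercepts of a fitted model with
#' \code{point +/- z[1-alpha/2] * SE} intervals from the conditional
#' (prediction) standard errors.
#'
#' @param model An \code{icu_fit}.
#' @param alpha Two-sided level.
#' @return A \code{metric_table} data frame.
#' @export
site_re_table <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "icu_fit"))
  re <- model$re
  if (any(is.na(re$se))) stop("random-effect standard errors unavailable")
  z <- qnorm(1 - alpha / 2)
  out <- data.frame(icu_id = re$icu_id, metric_kind = "site_re",
                    source_model = model$model, point = re$re,
                    ci_low = re$re - z * re$se, ci_high = re$re + z * re$se,
                    ci_method = "wald", n_patients = as.integer(
                      table(model$data$icu_id)[re$icu_id]),
                    se = re$se, se_log = NA_real_)
  rownames(out) <- NULL
  structure(out, alpha = alpha, bootstrap_reps = 0L,
            class = c("metric_table", "data.frame"))
}
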