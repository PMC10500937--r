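# Confidence sets for provider ranks: point ranks plus marginal (one
# unit's true rank covered with probability 1 - alpha) and simultaneous
# (all true ranks covered jointly) rank intervals, built from
# (estimate, SE) pairs under a Gaussian approximation with Monte-Carlo
# critical values for the studentised pairwise differences.

#' Rank-inference configuration
#'
#' @param alpha Miscoverage level (default 0.05).
#' @param n_draws Monte-Carlo draws for critical values (>= 1000).
#' @param orientation \code{"ascending_best"} (default: a lower adjusted
#'   LOS metric ranks 1) or \code{"descending_best"}.
#' @param seed Seed for the Monte-Carlo draws.
#' @export
rank_config <- function(alpha = 0.05, n_draws = 10000L,
                        orientation = c("ascending_best", "descending_best"),
                        seed = 1L) {
  orientation <- match.arg(orientation)
  stopifnot(alpha > 0, alpha < 1, n_draws >= 1000)
  structure(list(alpha = alpha, n_draws = as.integer(n_draws),
                 orientation = orientation, seed = as.integer(seed)),
            class = "rank_config")
}

#' Point ranks with minimal-rank ties
#'
#' \code{rank_i = 1 + #\{j : theta_j strictly better than theta_i\}};
#' exact ties share the minimal rank.
#'
#' @param estimates Finite numeric vector.
#' @param orientation See \code{\link{rank_config}}.
#' @export
point_ranks <- function(estimates,
                        orientation = c("ascending_best", "descending_best")) {
  orientation <- match.arg(orientation)
  if (any(!is.finite(estimates))) stop("estimates must be finite")
  x <- if (orientation == "ascending_best") estimates else -estimates
  rank(x, ties.method = "min")
}

# one set of centred Gaussian draws shared by both constructions so the
# marginal-within-simultaneous nesting holds draw by draw
.rank_critvals <- function(ses, config) {
  N <- length(ses)
  draws <- .with_seed(config$seed,
                      matrix(rnorm(config$n_draws * N), config$n_draws, N) *
                        rep(ses, each = config$n_draws))
  pair_se <- sqrt(outer(ses^2, ses^2, "+"))
  max_i <- matrix(NA_real_, config$n_draws, N)
  for (i in seq_len(N)) {
    z <- abs(draws[, -i, drop = FALSE] - draws[, i]) /
      rep(pair_se[i, -i], each = config$n_draws)
    max_i[, i] <- apply(z, 1, max)
  }
  c_marg <- apply(max_i, 2, quantile, probs = 1 - config$alpha, names = FALSE)
  c_sim <- quantile(apply(max_i, 1, max), 1 - config$alpha, names = FALSE)
  list(marginal = c_marg, simultaneous = rep(c_sim, N))
}

.rank_table_from_crit <- function(estimates, ses, crit, kind, config, ids) {
  N <- length(estimates)
  s <- if (config$orientation == "ascending_best") 1 else -1
  th <- s * estimates
  pair_se <- sqrt(outer(ses^2, ses^2, "+"))
  rank_low <- rank_high <- integer(N)
  for (i in seq_len(N)) {
    diff <- th[-i] - th[i]
    se_ij <- pair_se[i, -i]
    better <- sum(diff + crit[i] * se_ij < 0)   # confidently better units
    worse <- sum(diff - crit[i] * se_ij > 0)    # confidently worse units
    rank_low[i] <- 1L + better
    rank_high[i] <- N - worse
  }
  out <- data.frame(icu_id = ids, point_rank = point_ranks(estimates,
                                                           config$orientation),
                    rank_low = rank_low, rank_high = rank_high, kind = kind)
  rownames(out) <- NULL
  structure(out, alpha = config$alpha, orientation = config$orientation,
            seed = config$seed, class = c("rank_table", "data.frame"))
}

.check_rank_inputs <- function(estimates, ses) {
  if (any(!is.finite(estimates))) stop("estimates must be finite")
  if (any(!is.finite(ses)) || any(ses < 0)) stop("SEs must be finite and >= 0")
  zero <- ses == 0
  if (any(zero)) {
    tied <- duplicated(estimates[zero]) | duplicated(estimates[zero],
                                                     fromLast = TRUE)
    if (any(tied)) {
      stop("zero SE with exactly tied estimates: supply a jitter or an ",
           "explicit tie policy")
    }
  }
}

# both constructions from a single set of Monte-Carlo draws
.rank_sets_both <- function(estimates, ses, config, ids) {
  .check_rank_inputs(estimates, ses)
  crit <- .rank_critvals(ses, config)
  list(marginal = .rank_table_from_crit(estimates, ses, crit$marginal,
                                        "marginal", config, ids),
       simultaneous = .rank_table_from_crit(estimates, ses,
                                            crit$simultaneous,
                                            "simultaneous", config, ids))
}

#' Marginal rank confidence sets
#'
#' For each unit i a critical value is calibrated (by Monte Carlo over
#' independent Gaussian draws with the supplied SEs) so that the
#' \code{N - 1} studentised differences against unit i are jointly
#' covered with probability \code{1 - alpha}; the rank set counts units
#' confidently better and not confidently worse.  Covers a single
#' unit's true rank with probability \code{1 - alpha}.
#'
#' @param estimates Metric point estimates (one per unit); ratio metrics
#'   should be supplied on the log scale.
#' @param ses Standard errors of the estimates.
#' @param config A \code{\link{rank_config}}.
#' @param ids Optional unit identifiers.
#' @return A \code{rank_table} data frame with \code{point_rank},
#'   \code{rank_low}, \code{rank_high}.
#' @export
marginal_rank_sets <- function(estimates, ses, config = rank_config(),
                               ids = seq_along(estimates)) {
  .rank_sets_both(estimates, ses, config, ids)$marginal
}

#' Simultaneous rank confidence sets
#'
#' As \code{\link{marginal_rank_sets}} but with a single critical value
#' calibrated for all pairwise studentised differences jointly, so the
#' resulting rank sets cover every unit's true rank simultaneously with
#' probability \code{1 - alpha}.  Always contains the marginal set.
#'
#' @inheritParams marginal_rank_sets
#' @export
simultaneous_rank_sets <- function(estimates, ses, config = rank_config(),
                                   ids = seq_along(estimates)) {
  .rank_sets_both(estimates, ses, config, ids)$simultaneous
}

#' Build both rank tables from a metric table
#'
#' Convenience wrapper: ratio metrics (RALOSR variants) are analysed on
#' the log scale with the bootstrap SE of the log ratio; difference and
#' random-effect metrics on their own scale.
#'
#' @param metric_table A \code{metric_table}.
#' @param config A \code{\link{rank_config}}.
#' @return List with elements \code{marginal} and \code{simultaneous}.
#' @export
rank_sets_for_metric <- function(metric_table, config = rank_config()) {
  stopifnot(inherits(metric_table, "metric_table"))
  ratio <- all(metric_table$metric_kind %in% c("ralosr_arith", "ralosr_geo"))
  if (ratio) {
    est <- log(metric_table$point)
    ses <- metric_table$se_log
  } else {
    est <- metric_table$point
    ses <- metric_table$se
  }
  ses <- pmax(ses, 1e-12)
  .rank_sets_both(est, ses, config, metric_table$icu_id)
}

#' Monte-Carlo coverage of the rank-set constructions
#'
#' Validation harness: simulates estimates around known true effects,
#' builds both kinds of rank sets, and reports empirical marginal
#' per-unit coverage and simultaneous joint coverage of the true ranks,
#' with binomial Monte-Carlo standard errors.
#'
#' @param true_effects Vector of true unit effects.
#' @param ses Standard errors of the estimators.
#' @param n_reps Simulation replicates.
#' @param config A \code{\link{rank_config}}; \code{config$seed} also
#'   seeds the data draws.
#' @return List with coverage estimates and their Monte-Carlo SEs.
#' @export
rank_coverage_sim <- function(true_effects, ses, n_reps = 200L,
                              config = rank_config()) {
  N <- length(true_effects)
  true_rank_lo <- rank(true_effects, ties.method = "min")
  true_rank_hi <- rank(true_effects, ties.method = "max")
  if (config$orientation == "descending_best") {
    true_rank_lo <- rank(-true_effects, ties.method = "min")
    true_rank_hi <- rank(-true_effects, ties.method = "max")
  }
  marg_cover <- matrix(NA, n_reps, N)
  sim_cover <- nested <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    est <- .with_seed(config$seed + 7 * r,
                      rnorm(N, true_effects, ses))
    cfg_r <- config
    cfg_r$seed <- config$seed + 104729L + r
    both <- .rank_sets_both(est, ses, cfg_r, seq_len(N))
    mm <- both$marginal
    ss <- both$simultaneous
    # a set covers when it intersects the unit's true rank range
    marg_cover[r, ] <- mm$rank_low <= true_rank_hi &
      mm$rank_high >= true_rank_lo
    sim_cover[r] <- all(ss$rank_low <= true_rank_hi &
                          ss$rank_high >= true_rank_lo)
    nested[r] <- all(ss$rank_low <= mm$rank_low &
                       ss$rank_high >= mm$rank_high)
  }
  marginal <- colMeans(marg_cover)
  list(marginal_coverage = marginal,
       nesting_fraction = mean(nested),
       marginal_coverage_mean = mean(marginal),
       marginal_mc_se = sqrt(mean(marginal) * (1 - mean(marginal)) / n_reps),
       simultaneous_coverage = mean(sim_cover),
       simultaneous_mc_se = sqrt(mean(sim_cover) * (1 - mean(sim_cover)) /
                                   n_reps),
       n_reps = n_reps)
}
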