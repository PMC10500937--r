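# The two estimators: degenerate cases, information-criterion
# identities, predictions, validation R2 and diagnostics.

test_that("single-ICU intercept-only fits collapse to the scale means", {
  p <- patients_with_los(list(c(1, 2, 4, 8, 3, 5)))
  reg <- registry_from_df(p, sites_for(p))
  m_lmm <- fit_lmm(reg, intercept_spec("log_los"))
  expect_equal(unname(m_lmm$beta_hat[1]), mean(log(p$los_days)))
  expect_equal(m_lmm$tau2_hat, 0)
  m_glmm <- fit_glmm_log_gaussian(reg, intercept_spec("los_days"))
  expect_equal(exp(unname(m_glmm$beta_hat[1])), mean(p$los_days),
               tolerance = 1e-6)
})

test_that("information criteria identities hold exactly", {
  reg <- small_registry(n_icus = 6, volume = 60, seed = 21)
  for (m in list(fit_lmm(reg, reduced_model_spec("log_los")),
                 suppressWarnings(fit_glmm_log_gaussian(
                   reg, reduced_model_spec("los_days"))))) {
    expect_equal(m$aic, -2 * m$loglik + 2 * m$p)
    expect_equal(m$bic, -2 * m$loglik + m$p * log(m$n_used))
    expect_gte(m$tau2_hat, 0)
    expect_gt(m$sigma2_hat, 0)
    expect_equal(nrow(m$re), 6)
  }
})

test_that("a noise-free linear registry is recovered almost exactly", {
  reg <- small_registry(n_icus = 5, volume = 80, seed = 22, tau2 = 0)
  b <- reduced_beta()
  d <- reg$patients
  eta <- 0.4 + d$apache3 * b["apache3"] +
    log(pmax(d$anzrod, 1e-4)) * b["log_anzrod"] +
    d$preicu_days * b["preicu_days"] + d$died_icu * b["died_icu"] +
    d$vent_d1 * b["vent_d1"]
  d$los_days <- exp(eta + rnorm(length(eta), 0, 1e-6))
  reg$patients <- d
  m <- fit_lmm(reg, reduced_model_spec("log_los"))
  expect_equal(unname(m$beta_hat["apache3"]), unname(b["apache3"]),
               tolerance = 1e-4)
  expect_equal(unname(m$beta_hat["died_icu"]), unname(b["died_icu"]),
               tolerance = 1e-4)
  expect_lt(m$sigma2_hat, 1e-8)
})

test_that("non-positive LOS and singular designs are rejected", {
  reg <- small_registry(seed = 23)
  reg$patients$los_days[1] <- 0
  expect_error(fit_lmm(reg, reduced_model_spec("log_los")), "non-positive")
  reg2 <- small_registry(seed = 23)
  spec <- reduced_model_spec("log_los")
  spec$fixed_terms <- c(spec$fixed_terms, "I(2 * apache3)")
  expect_error(fit_lmm(reg2, spec), "aliased")
})

test_that("complete-case drops are counted", {
  reg <- generate_registry(sim_config(n_icus = 6, seed = 24,
                                      volume_model = list(fixed = 100),
                                      missing_rate = 0.09))
  m <- fit_lmm(reg, reduced_model_spec("log_los"))
  expect_equal(m$n_dropped, sum(is.na(reg$patients$apache3)))
  expect_equal(m$n_used, nrow(reg$patients) - m$n_dropped)
})

test_that("predictions are positive on the days scale and additive in RE", {
  reg <- small_registry(n_icus = 6, volume = 80, seed = 25)
  glmm <- suppressWarnings(fit_glmm_log_gaussian(
    reg, reduced_model_spec("los_days")))
  fe <- predict_los(glmm, mode = "FE", scale = "days")
  re <- predict_los(glmm, mode = "RE", scale = "days")
  expect_true(all(fe$pred > 0))
  # RE prediction = FE prediction scaled by exp(site intercept)
  ratio <- tapply(log(re$pred) - log(fe$pred), fe$icu_id, mean)
  expect_equal(as.numeric(ratio[glmm$re$icu_id]), glmm$re$re,
               tolerance = 1e-6)

  lmm <- fit_lmm(reg, reduced_model_spec("log_los"))
  fe_l <- predict_los(lmm, mode = "FE", scale = "log_days")
  re_l <- predict_los(lmm, mode = "RE", scale = "log_days")
  shift <- tapply(re_l$pred - fe_l$pred, fe_l$icu_id, mean)
  expect_equal(as.numeric(shift[lmm$re$icu_id]), lmm$re$re,
               tolerance = 1e-6)
})

test_that("RE-mode prediction for an unseen site names the site", {
  reg <- small_registry(n_icus = 5, volume = 60, seed = 26)
  lmm <- fit_lmm(reg, reduced_model_spec("log_los"))
  other <- small_registry(n_icus = 7, volume = 10, seed = 27)
  expect_error(predict_los(lmm, other, mode = "RE"), "6")
  expect_silent({p <- predict_los(lmm, other, mode = "FE")})
})

test_that("random-effect predictions shrink relative to raw site deviations", {
  reg <- small_registry(n_icus = 10, volume = 50, seed = 28, tau2 = 0.05)
  lmm <- fit_lmm(reg, reduced_model_spec("log_los"))
  fe <- predict_los(lmm, mode = "FE", scale = "log_days")
  raw_dev <- tapply(fe$obs - fe$pred, fe$icu_id, mean)
  expect_true(all(abs(lmm$re$re) <= abs(raw_dev[lmm$re$icu_id]) + 1e-10))
  expect_lt(abs(mean(lmm$re$re)), 0.05)
})

test_that("r_squared matches a hand Pearson oracle and flags edge cases", {
  obs <- c(1, 2, 3, 6); pred <- c(1, 2, 4, 5)
  num <- sum((obs - mean(obs)) * (pred - mean(pred)))
  den <- sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(r_squared(obs, pred), (num / den)^2)
  expect_equal(r_squared(obs, pred), 121 / 140)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, -obs), 1)
  expect_error(r_squared(obs, pred[-1]), "equal length")
  expect_warning(r2c <- r_squared(obs, rep(2, 4)), "constant")
  expect_true(is.na(r2c))
  # ICU level first averages within site
  icu <- c(1, 1, 2, 2)
  expect_equal(r_squared(obs, pred, level = "icu", icu_id = icu),
               cor(tapply(obs, icu, mean), tapply(pred, icu, mean))^2)
})

test_that("split-sample validation is reproducible and near-homogeneous", {
  reg <- generate_registry(sim_config(n_icus = 20, seed = 29,
                                      volume_model = list(fixed = 150)))
  v1 <- split_sample_validation(reg, reduced_model_spec("log_los"), "lmm",
                                seed = 5)
  v2 <- split_sample_validation(reg, reduced_model_spec("log_los"), "lmm",
                                seed = 5)
  expect_identical(v1$development_sites, v2$development_sites)
  expect_equal(length(v1$development_sites), 12)
  expect_length(intersect(v1$development_sites, v1$validation_sites), 0)
  expect_error(split_sample_validation(reg, reduced_model_spec("log_los"),
                                       "lmm", fraction = 1), "fewer than 2")
})

test_that("development and validation R2 agree on the default registry", {
  # at full registry scale the in-sample (RE) and out-of-sample (FE)
  # R2 differ only by the modest between-ICU variance share
  reg <- generate_registry(sim_config(seed = 20160101L))
  v <- split_sample_validation(reg, reduced_model_spec("log_los"), "lmm",
                               seed = 9)
  expect_lt(abs(v$r2_development - v$r2_validation), 0.05)
  expect_gt(v$r2_development, 0.15)
  expect_lt(v$r2_development, 0.45)
})

test_that("residual diagnostics behave at their reference points", {
  # perfect fit: all residuals vanish
  reg <- small_registry(n_icus = 4, volume = 50, seed = 30, tau2 = 0)
  d <- reg$patients
  d$los_days <- exp(0.5 + 0.01 * d$apache3)
  reg$patients <- d
  spec <- reduced_model_spec("log_los")
  spec$fixed_terms <- "apache3"
  # a zero-residual likelihood makes the optimiser grumble; only the
  # residuals matter here
  m <- suppressWarnings(fit_lmm(reg, spec))
  expect_lt(max(abs(residual_diagnostics(m)$residuals$raw)), 1e-6)

  # LMM standardised residuals centre near zero on stochastic data
  m2 <- fit_lmm(small_registry(n_icus = 8, volume = 100, seed = 31),
                reduced_model_spec("log_los"))
  expect_lt(abs(residual_diagnostics(m2)$summary$mean_standardized), 0.02)

  # single-site intercept-only GLMM: response residuals sum to zero
  p <- patients_with_los(list(c(2, 3, 7, 9, 4)))
  regs <- registry_from_df(p, sites_for(p))
  mg <- fit_glmm_log_gaussian(regs, intercept_spec("los_days"))
  expect_equal(sum(residual_diagnostics(mg)$residuals$deviance), 0,
               tolerance = 1e-5)
})

test_that("omnibus normality test holds its level and detects skew", {
  verdicts <- vapply(1:100, function(i) {
    set.seed(i)
    normality_check(rnorm(5000))$verdict
  }, character(1))
  expect_gte(mean(verdicts == "not rejected"), 0.90)
  set.seed(1)
  expect_equal(normality_check(rexp(5000))$verdict, "rejected")
  expect_error(normality_check(rep(1, 100)), "constant")
  expect_error(normality_check(rnorm(10)), "at least 20")
  # log LOS under gamma noise is detectably non-lognormal
  reg <- generate_registry(sim_config(n_icus = 10, seed = 32,
                                      volume_model = list(fixed = 500),
                                      noise_family = "gamma"))
  expect_equal(normality_check(log(reg$patients$los_days))$verdict,
               "rejected")
})
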