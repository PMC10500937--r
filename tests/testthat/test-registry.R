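# Synthetic registry generator: calibration solver, determinism,
# structural invariants and the demographic summary.

test_that("lognormal calibration solves the moment equations", {
  cal <- calibrate_los_marginal(3.2, 1.8)
  expect_equal(cal$mu, log(1.8))
  expect_equal(cal$total_var, 2 * log(3.2 / 1.8))
  # closed form against Monte-Carlo moments of the implied lognormal
  set.seed(1)
  x <- rlnorm(1e6, cal$mu, sqrt(cal$total_var))
  expect_equal(mean(x), 3.2, tolerance = 0.01)
  expect_equal(median(x), 1.8, tolerance = 0.01)

  cal2 <- calibrate_los_marginal(exp(1), 1)
  expect_equal(cal2$mu, 0)
  expect_equal(cal2$total_var, 2)
})

test_that("degenerate calibration targets are rejected", {
  expect_error(calibrate_los_marginal(exp(1), exp(1)), "exceed")
  expect_error(calibrate_los_marginal(1.5, 2), "exceed")
  expect_error(calibrate_los_marginal(3, -1), "positive")
})

test_that("round-trip property: solved parameters reproduce any target pair", {
  set.seed(7)
  for (i in 1:25) {
    med <- runif(1, 0.5, 10)
    mn <- med * runif(1, 1.01, 3)
    cal <- calibrate_los_marginal(mn, med)
    expect_equal(exp(cal$mu), med)
    expect_equal(exp(cal$mu + cal$total_var / 2), mn)
  }
})

test_that("generation is deterministic given the seed", {
  r1 <- small_registry(seed = 11)
  r2 <- small_registry(seed = 11)
  expect_identical(r1$patients, r2$patients)
  expect_identical(r1$sites, r2$sites)
  r3 <- small_registry(seed = 12)
  expect_false(identical(r1$patients$los_days, r3$patients$los_days))
})

test_that("registry structure honours the configuration", {
  reg <- small_registry(n_icus = 8, volume = 40, seed = 2)
  expect_equal(nrow(reg$sites), 8)
  counts <- table(reg$patients$icu_id)
  expect_true(all(counts == reg$sites$annual_volume))
  expect_true(all(reg$patients$icu_id %in% reg$sites$icu_id))
  expect_true(all(reg$patients$age >= 16))
  expect_true(all(reg$patients$anzrod > 0 & reg$patients$anzrod < 1))
  expect_true(all(reg$patients$apache3 >= 0 & reg$patients$apache3 <= 299))
  expect_true(all(reg$patients$dx_group %in% 1:30))
})

test_that("LOS truncation holds in every registry", {
  for (s in 1:3) {
    reg <- small_registry(seed = s, volume = 120)
    expect_true(all(reg$patients$los_days <= 180))
    expect_true(all(reg$patients$los_days > 0))
  }
  reg10 <- generate_registry(sim_config(n_icus = 4, seed = 1,
                                        volume_model = list(fixed = 200),
                                        los_truncation_days = 10))
  expect_true(all(reg10$patients$los_days <= 10))
})

test_that("tau2 = 0 yields exactly null site effects", {
  reg <- small_registry(seed = 3, tau2 = 0)
  expect_true(all(reg$sites$true_re == 0))
})

test_that("site-effect variance approaches tau2 with many sites", {
  reg <- generate_registry(sim_config(n_icus = 1000, seed = 5,
                                      volume_model = list(fixed = 2),
                                      tau2 = 0.05))
  expect_lt(abs(var(reg$sites$true_re) - 0.05), 0.10 * 0.05)
})

test_that("geometric mean never exceeds arithmetic mean within any ICU", {
  for (fam in c("lognormal", "gamma")) {
    reg <- small_registry(seed = 4, noise_family = fam)
    by_icu <- split(reg$patients$los_days, reg$patients$icu_id)
    for (v in by_icu) {
      gm <- exp(mean(log(v)))
      expect_lte(gm, mean(v))
      if (length(unique(v)) > 1) expect_lt(gm, mean(v))
    }
  }
})

test_that("gamma noise family produces positive skewed LOS", {
  reg <- small_registry(seed = 6, noise_family = "gamma", volume = 200)
  los <- reg$patients$los_days
  expect_true(all(los > 0))
  expect_gt(mean(los), median(los))
})

test_that("missing_rate blanks severity fields at the requested rate", {
  reg <- generate_registry(sim_config(n_icus = 10, seed = 8,
                                      volume_model = list(fixed = 500),
                                      missing_rate = 0.09))
  expect_lt(abs(mean(is.na(reg$patients$apache3)) - 0.09), 0.01)
  expect_identical(is.na(reg$patients$apache3), is.na(reg$patients$anzrod))
})

test_that("demographic summary reports the standard statistics", {
  p <- patients_with_los(list(c(1, 4)))
  reg <- registry_from_df(p, sites_for(p))
  s <- summarize_registry(reg)
  pick <- function(v, st) s$value[s$variable == v & s$stat == st]
  expect_equal(pick("los_days", "mean"), 2.5)
  expect_equal(pick("los_days", "geo_mean"), 2)
  expect_equal(pick("male", "proportion"), 1)
  expect_error(summarize_registry(registry_from_df(p[0, ], sites_for(p))),
               "empty")
})

test_that("non-finite linear predictors are rejected", {
  cfg <- sim_config(n_icus = 3, seed = 1, volume_model = list(fixed = 10))
  cfg$beta["apache3"] <- 1e308
  expect_error(generate_registry(cfg), "non-finite")
})
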