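# BCa bootstrap and the per-ICU quality-metric tables.

test_that("BCa interval degenerates gracefully and is seed-stable", {
  bb <- bca_interval(c(2, 2, 2, 2), mean, B = 100, seed = 1)
  expect_equal(c(bb$point, bb$ci_low, bb$ci_high), c(2, 2, 2))
  x <- rexp(40)
  b1 <- bca_interval(x, mean, B = 500, seed = 9)
  b2 <- bca_interval(x, mean, B = 500, seed = 9)
  expect_identical(b1[c("ci_low", "ci_high")], b2[c("ci_low", "ci_high")])
  expect_lt(b1$ci_low, b1$point)
  expect_gt(b1$ci_high, b1$point)
})

test_that("bias correction vanishes for a symmetric statistic", {
  set.seed(4)
  x <- rnorm(200)
  bb <- bca_interval(x, mean, B = 2000, seed = 2)
  expect_lt(abs(bb$z0), 0.1)
  # with z0 ~ 0 and a ~ 0 the endpoints sit near the plain percentiles
  perc <- quantile(bb$theta_star, c(0.025, 0.975))
  expect_lt(abs(bb$ci_low - perc[1]), 0.25 * bb$se)
  expect_lt(abs(bb$ci_high - perc[2]), 0.25 * bb$se)
})

test_that("BCa endpoints agree with the boot package on a shared sample", {
  skip_if_not_installed("boot")
  set.seed(8)
  x <- rexp(60)
  ours <- bca_interval(x, mean, B = 4000, seed = 3)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  ci <- boot::boot.ci(bt, type = "bca")$bca
  expect_equal(ours$ci_low, ci[4], tolerance = 0.25 * ours$se)
  expect_equal(ours$ci_high, ci[5], tolerance = 0.25 * ours$se)
})

test_that("OMELOS and RALOSR reduce correctly on hand examples", {
  pr <- manual_predictions(c(1, 1), obs = c(2, 4), pred = c(1, 3))
  om <- omelos_table(pr, B = 200)
  expect_equal(om$point, 1.0)
  ra <- ralosr_arith_table(pr, B = 200)
  expect_equal(ra$point, 1.5)

  # perfect predictions: null metric with zero-width interval
  pr0 <- manual_predictions(rep(1, 5), obs = 1:5, pred = 1:5)
  om0 <- omelos_table(pr0, B = 200)
  expect_equal(c(om0$point, om0$ci_low, om0$ci_high), c(0, 0, 0))
  ra0 <- ralosr_arith_table(pr0, B = 200)
  expect_equal(c(ra0$point, ra0$ci_low, ra0$ci_high), c(1, 1, 1))

  # geometric variant on the log scale
  prg <- manual_predictions(c(1, 1), obs = log(c(1, 4)), pred = c(0, 0),
                            scale = "log_days", model = "lmm")
  rg <- ralosr_geo_table(prg, B = 200)
  expect_equal(rg$point, 2.0)
})

test_that("metrics refuse RE-based predictions", {
  pr <- manual_predictions(c(1, 1), obs = c(2, 4), pred = c(1, 3),
                           mode = "RE")
  expect_error(omelos_table(pr), "fixed-effect")
})

test_that("omelos = 0 exactly when ralosr = 1 on shared predictions", {
  set.seed(11)
  for (i in 1:10) {
    obs <- rexp(30, 1 / 3)
    pred <- if (i <= 5) obs + rnorm(30, 0, 0.5) else obs * (sum(obs) / sum(obs))
    pr <- manual_predictions(rep(1, 30), obs, pred)
    om <- omelos_table(pr, B = 50)$point
    ra <- ralosr_arith_table(pr, B = 50)$point
    expect_equal(om == 0, ra == 1)
    expect_equal(sign(om), sign(ra - 1))
  }
})

test_that("scaling LOS scales OMELOS and leaves both RALOSR variants fixed", {
  set.seed(12)
  obs <- rexp(40, 1 / 3); pred <- rexp(40, 1 / 3)
  pr1 <- manual_predictions(rep(1, 40), obs, pred)
  pr3 <- manual_predictions(rep(1, 40), 3 * obs, 3 * pred)
  om1 <- omelos_table(pr1, B = 300, seed = 5)
  om3 <- omelos_table(pr3, B = 300, seed = 5)
  expect_equal(om3$point, 3 * om1$point)
  expect_equal(om3$ci_low, 3 * om1$ci_low)
  expect_equal(om3$ci_high, 3 * om1$ci_high)
  ra1 <- ralosr_arith_table(pr1, B = 300, seed = 5)
  ra3 <- ralosr_arith_table(pr3, B = 300, seed = 5)
  expect_equal(ra3$point, ra1$point)
  expect_equal(ra3$ci_low, ra1$ci_low)
  prg1 <- manual_predictions(rep(1, 40), log(obs), log(pred),
                             scale = "log_days", model = "lmm")
  prg3 <- manual_predictions(rep(1, 40), log(3 * obs), log(3 * pred),
                             scale = "log_days", model = "lmm")
  rg1 <- ralosr_geo_table(prg1, B = 300, seed = 5)
  rg3 <- ralosr_geo_table(prg3, B = 300, seed = 5)
  expect_equal(rg3$point, rg1$point)
})

test_that("arithmetic and geometric RALOSR can rank ICUs differently", {
  # ICU 1: one long stay well above prediction; ICU 2: uniformly close
  pr_arith <- manual_predictions(c(1, 1, 2, 2), obs = c(1, 10, 3, 4),
                                 pred = c(2, 5, 2, 5))
  ra <- ralosr_arith_table(pr_arith, B = 100)
  pr_geo <- manual_predictions(c(1, 1, 2, 2), obs = log(c(1, 10, 3, 4)),
                               pred = log(c(2, 5, 2, 5)),
                               scale = "log_days", model = "lmm")
  rg <- ralosr_geo_table(pr_geo, B = 100)
  expect_false(identical(order(ra$point), order(rg$point)))
})

test_that("single-patient ICUs fall back to a flagged Wald row", {
  pr <- manual_predictions(c(1, 2, 2, 2), obs = c(5, 2, 3, 4),
                           pred = c(4, 2, 3, 4))
  om <- omelos_table(pr, B = 100)
  expect_equal(om$ci_method[om$icu_id == "1"], "wald")
  expect_equal(om$n_patients[om$icu_id == "1"], 1L)
})

test_that("per-ICU bootstrap streams do not depend on table order", {
  set.seed(13)
  pr_a <- manual_predictions(rep(c("a", "b"), each = 25),
                             rexp(50), rexp(50))
  pr_b <- pr_a[c(26:50, 1:25), ]
  attributes(pr_b)[c("mode", "scale", "model", "class")] <-
    attributes(pr_a)[c("mode", "scale", "model", "class")]
  t_a <- omelos_table(pr_a, B = 200, seed = 7)
  t_b <- omelos_table(pr_b, B = 200, seed = 7)
  t_b <- t_b[match(t_a$icu_id, t_b$icu_id), ]
  expect_equal(t_a$ci_low, t_b$ci_low)
  expect_equal(t_a$ci_high, t_b$ci_high)
})

test_that("site RE table applies the Wald construction", {
  m <- list(model = "lmm",
            re = data.frame(icu_id = c("1", "2"), re = c(0.5, 0),
                            se = c(0.1, 0)),
            data = data.frame(icu_id = factor(c(1, 1, 2))))
  class(m) <- "icu_fit"
  tab <- site_re_table(m)
  expect_equal(tab$ci_low[1], 0.5 - qnorm(0.975) * 0.1, tolerance = 1e-10)
  expect_equal(round(c(tab$ci_low[1], tab$ci_high[1]), 3), c(0.304, 0.696))
  expect_equal(c(tab$ci_low[2], tab$ci_high[2]), c(0, 0))
  m$re$se[2] <- NA
  expect_error(site_re_table(m), "unavailable")
})
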