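test_that("flow exceedance matches direct quantiles and guards short records", {
  set.seed(4)
  q <- rlnorm(365, 0, 1)
  expect_equal(flow_exceedance(q, 80), unname(quantile(q, 0.2, type = 7)))
  expect_equal(flow_exceedance(q, 2), unname(quantile(q, 0.98, type = 7)))
  expect_error(flow_exceedance(q[1:10], 80), "at least 30")
  expect_warning(flow_exceedance(q[1:100], 80), "shorter than a year")
})

test_that("rating curve recovers a noiseless power law to 6 significant figures", {
  a <- 0.0573; b <- 0.8214
  areas <- c(2.3, 11, 47, 180, 410)
  fit <- fit_rating_curve(areas, a * areas^b, level = "Q80")
  expect_equal(signif(fit$a, 6), signif(a, 6))
  expect_equal(signif(fit$b, 6), signif(b, 6))
  expect_equal(reach_discharge(fit, 100), a * 100^b, tolerance = 1e-6)
})

test_that("rating curve rejects unidentifiable or insufficient gauges", {
  expect_error(fit_rating_curve(5, 2), "insufficient")
  expect_error(fit_rating_curve(c(10, 10, 10), c(1, 2, 3)), "unidentifiable")
})

test_that("rating curve tolerates realistic lognormal scatter", {
  set.seed(9)
  areas <- exp(runif(30, log(1), log(500)))
  q <- 0.05 * areas^0.8 * exp(rnorm(30, 0, 0.3))
  fit <- fit_rating_curve(areas, q)
  expect_lt(abs(fit$b - 0.8), 0.15)
})

test_that("stream power follows the closed form rho g Q S", {
  expect_equal(stream_power(2, 0.01), 1000 * 9.8 * 2 * 0.01)
  expect_equal(stream_power(c(1, 10), c(0.001, 0.02)),
               1000 * 9.8 * c(1, 10) * c(0.001, 0.02))
  expect_error(stream_power(-1, 0.01), "negative")
})

test_that("gauge ratings pipeline produces Q2 >= Q80 curves", {
  scn <- small_scenario(seed = 13)
  cm <- generate_terrain(scn)
  gf <- generate_flows(scn, cm)
  rt <- fit_gauge_ratings(gf$flows, gf$gauges)
  expect_s3_class(rt$q2, "rating_curve")
  a <- c(1, 10, 100)
  expect_true(all(reach_discharge(rt$q2, a) > reach_discharge(rt$q80, a)))
})
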