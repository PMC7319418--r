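sim_zinb_data <- function(n, seed, b0 = -0.8, b1 = 0.5, g0 = 1.0, g1 = -0.8,
                          theta = 1.2) {
  set.seed(seed)
  x <- runif(n, 0, 5)
  pi0 <- plogis(g0 + g1 * x)
  mu <- exp(b0 + b1 * x)
  y <- rnbinom(n, mu = mu, size = theta)
  y[rbinom(n, 1, pi0) == 1] <- 0L
  data.frame(observed_dams = y, max_dams = x)
}

test_that("dispersion test guards its inputs", {
  expect_error(dispersion_test(c(0, 1, 2), c(1, 2, 3)), "at least 30")
  expect_error(dispersion_test(rep(0L, 50), runif(50)), "all counts are zero")
})

test_that("ZINB fit recovers generating parameters and orders models by AIC", {
  d <- sim_zinb_data(4000, seed = 1)
  fit <- fit_zinb(d)
  est <- fit$coefficients$estimate
  expect_equal(est[1], -0.8, tolerance = 0.15)
  expect_equal(est[2], 0.5, tolerance = 0.1)
  expect_equal(est[3], 1.0, tolerance = 0.25)
  expect_equal(est[4], -0.8, tolerance = 0.2)
  expect_equal(fit$theta, 1.2, tolerance = 0.35)
  cmp <- fit$comparison
  expect_equal(cmp$model[which.min(cmp$AIC)], "ZINB")
  expect_lt(cmp$AIC[cmp$model == "ZINB"], cmp$AIC[cmp$model == "Poisson"])
  # Wald p-values of both slopes are significant at this sample size
  expect_lt(max(fit$coefficients$p_value[c(2, 4)]), 0.01)
})

test_that("own ZINB maximum likelihood matches glmmTMB", {
  d <- sim_zinb_data(1500, seed = 7)
  fit <- fit_zinb(d)
  tmb <- glmmTMB::glmmTMB(observed_dams ~ max_dams,
                          ziformula = ~max_dams,
                          family = glmmTMB::nbinom2(), data = d)
  expect_equal(fit$loglik, as.numeric(logLik(tmb)), tolerance = 1e-4)
  cf <- glmmTMB::fixef(tmb)
  expect_equal(fit$coefficients$estimate[1:2], unname(cf$cond), tolerance = 1e-3)
  expect_equal(fit$coefficients$estimate[3:4], unname(cf$zi), tolerance = 1e-3)
  expect_equal(fit$theta, glmmTMB::sigma(tmb), tolerance = 1e-3)
})

test_that("fit guards: sample size, inactive rows, constant covariate", {
  d <- sim_zinb_data(40, seed = 2)
  expect_error(fit_zinb(d), "at least 50")
  d2 <- sim_zinb_data(200, seed = 3)
  d2$is_active <- rep(c(TRUE, FALSE), 100)
  fit <- fit_zinb(d2)
  expect_equal(fit$n, 100)
  d3 <- data.frame(observed_dams = rpois(100, 1), max_dams = rep(2, 100))
  expect_error(fit_zinb(d3), "covariate does not vary")
})

test_that("predictions combine the two components", {
  d <- sim_zinb_data(2000, seed = 4)
  fit <- fit_zinb(d)
  pr <- predict(fit, data.frame(max_dams = c(0, 2, 4)))
  expect_equal(pr$expected, (1 - pr$pi) * pr$mu)
  expect_true(all(diff(pr$expected) > 0))  # increasing in capacity
})

test_that("catchment prediction totals and bootstrap intervals are coherent", {
  d <- sim_zinb_data(600, seed = 5)
  fit <- fit_zinb(d)
  reaches <- data.frame(max_dams = runif(200, 0, 5),
                        category = sample(c("Rare", "Frequent"), 200, TRUE),
                        length_m = runif(200, 50, 200))
  pred <- predict_catchment_dams(fit, reaches, bootstrap_reps = 60, seed = 9)
  expect_equal(sum(pred$by_category$expected_dams), pred$total)
  expect_true(pred$total_ci[1] <= pred$total && pred$total <= pred$total_ci[2])
  expect_equal(pred$density_dpkm, pred$total / pred$network_km)
  expect_equal(sum(pred$by_category$pct), 100)
  # reproducible with the same seed
  pred2 <- predict_catchment_dams(fit, reaches, bootstrap_reps = 60, seed = 9)
  expect_equal(pred$total_ci, pred2$total_ci)
})

test_that("cross-validation pools percentile subsets with a near-unit slope", {
  d <- sim_zinb_data(500, seed = 6)
  cv <- cross_validate(d, n_splits = 8, n_percentile_subsets = 20, seed = 2)
  expect_equal(cv$slope, 1, tolerance = 0.15)
  expect_gt(nrow(cv$points), 100)
  expect_true(cv$rmse >= cv$mae * 0.9)  # RMSE dominates MAE up to rounding
  expect_error(cross_validate(d[1:50, ]), "at least 100")
})
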