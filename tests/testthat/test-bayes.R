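test_that("posterior summaries have the exact conjugate form", {
  f <- fit_category_binomial(7, 20)
  expect_equal(f$map, 7 / 20)
  expect_equal(f$alpha, 8); expect_equal(f$beta, 14)
  expect_equal(f$ci_low, qbeta(0.025, 8, 14))
  expect_equal(f$ci_high, qbeta(0.975, 8, 14))
  expect_error(fit_category_binomial(5, 0), "at least 1")
  expect_error(fit_category_binomial(9, 5), "\\[0, n\\]")
})

test_that("HPD interval is shorter than equal-tailed for skewed posteriors", {
  et <- fit_category_binomial(1, 30)
  hpd <- fit_category_binomial(1, 30, interval = "hpd")
  expect_lt(hpd$ci_high - hpd$ci_low, et$ci_high - et$ci_low)
  # both contain 95% mass
  expect_equal(pbeta(hpd$ci_high, 2, 30) - pbeta(hpd$ci_low, 2, 30), 0.95,
               tolerance = 1e-4)
})

test_that("closed-form posterior agrees with an independent Metropolis sampler", {
  draws <- oracle_binom_metropolis(12, 40, iters = 2e5, seed = 42)
  f <- fit_category_binomial(12, 40)
  expect_equal(mean(draws), 13 / 42, tolerance = 0.005)       # Beta mean
  expect_equal(unname(quantile(draws, 0.025)), f$ci_low, tolerance = 0.01)
  expect_equal(unname(quantile(draws, 0.975)), f$ci_high, tolerance = 0.01)
})

test_that("bayes factor matrix is seeded, complete and flags zero denominators", {
  post <- fit_category_posteriors(data.frame(
    category = c("low", "high", "none"), k = c(5, 45, 0), n = c(50, 50, 20)))
  bf1 <- bayes_factor_matrix(post, seed = 7)
  bf2 <- bayes_factor_matrix(post, seed = 7)
  expect_identical(bf1, bf2)
  expect_equal(nrow(bf1), 6)  # all ordered pairs
  hl <- bf1[bf1$numerator == "high" & bf1$denominator == "low", ]
  expect_gt(hl$map, 5)        # 90% vs 10% activity
  expect_true(all(bf1$unbounded[bf1$denominator == "none"]))
  expect_false(any(bf1$unbounded[bf1$denominator != "none"]))
  expect_error(bayes_factor_matrix(post, mc_draws = 1e4), "at least 1e|100000")
})

test_that("ratio MAP is consistent with the analytic ratio of point estimates", {
  post <- fit_category_posteriors(data.frame(
    category = c("a", "b"), k = c(30, 10), n = c(100, 100)))
  bf <- bayes_factor_matrix(post, mc_draws = 2e5, seed = 3)
  ab <- bf[bf$numerator == "a" & bf$denominator == "b", ]
  expect_equal(ab$map, 3, tolerance = 0.35)
  expect_true(ab$ci_low < 3 && 3 < ab$ci_high)
})

test_that("bayes factor table renders the lower triangle", {
  post <- fit_category_posteriors(data.frame(
    category = c("a", "b"), k = c(3, 6), n = c(10, 10)))
  bf <- bayes_factor_matrix(post, seed = 1)
  m <- bayes_factor_table(bf, c("a", "b"))
  expect_equal(m["a", "a"], "1")
  expect_match(m["b", "a"], "^\\d+\\.\\d+ \\[")
  expect_equal(m["a", "b"], "")
})
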