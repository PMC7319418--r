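test_that("trapezoid membership handles interior and vertical edges", {
  expect_equal(trapmf(c(0, 1, 2, 3, 4), c(1, 2, 2, 3)),
               c(0, 0, 1, 0, 0))
  expect_equal(trapmf(1.5, c(1, 2, 3, 4)), 0.5)
  expect_equal(trapmf(3.5, c(1, 2, 3, 4)), 0.5)
  # shoulder terms: plateau extends to the universe edge
  expect_equal(trapmf(c(0, 0.3), c(0, 0, 0.5, 1)), c(1, 1))
  expect_equal(trapmf(c(29, 30), c(12, 15, 30, 30)), c(1, 1))
})

test_that("fuzzy variables must cover their universe", {
  expect_error(fuzzy_variable("x", c(0, 10),
                              list(lo = c(0, 0, 1, 2), hi = c(8, 9, 10, 10))),
               "cover the universe")
  expect_error(fuzzy_variable("x", c(0, 10), list(bad = c(2, 1, 3, 4))),
               "non-decreasing")
})

test_that("config validation rejects undefined rule terms", {
  v <- fuzzy_variable("in", c(0, 1), list(lo = c(0, 0, 0.4, 0.6),
                                          hi = c(0.4, 0.6, 1, 1)))
  expect_error(fis_config(list(v), v, list(c("nope", "lo"))), "undefined term")
  expect_error(fis_config(list(v), v, list(c("lo"))), "plus a consequent")
})

test_that("default configs load, are cached, and round-trip through YAML", {
  cfg <- fis_vegetation_config()
  expect_s3_class(cfg, "fis_config")
  expect_length(cfg$rules, 25)
  cmb <- fis_combined_config()
  expect_length(cmb$rules, 180)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_fis_config(cmb, f)
  back <- read_fis_config(f)
  x <- cbind(runif(20, 0, 30), runif(20, 0, 0.3), runif(20, 0, 2000),
             runif(20, 0, 5000))
  expect_equal(evaluate_fis(back, x), evaluate_fis(cmb, x))
})

test_that("vegetation capacity is monotone and hits the documented anchors", {
  hi <- vegetation_capacity(5, 5)
  lo <- vegetation_capacity(0, 0)
  expect_gt(hi, 15)  # pervasive
  expect_lt(lo, 0.5) # effectively none
  sweep <- vegetation_capacity(seq(0, 5, 0.1), seq(0, 5, 0.1))
  expect_true(all(diff(sweep) >= -1e-9))
  expect_error(vegetation_capacity(6, 1), "\\[0, 5\\]")
})

test_that("combined capacity responds in the expected directions", {
  base <- combined_capacity(20, 0.01, 50, 400)
  expect_lt(combined_capacity(20, 0.22, 50, 400), base)   # steep slope kills
  expect_lt(combined_capacity(20, 0.01, 3000, 400), base) # Q80 oblivion
  expect_lt(combined_capacity(20, 0.01, 50, 30000), base) # Q2 blowout
  expect_lt(combined_capacity(0.01, 0.01, 50, 400), 0.5)  # no vegetation
  expect_error(combined_capacity(35, 0.01, 50, 400), "\\[0, 30\\]")
  expect_error(combined_capacity(20, -0.1, 50, 400), "negative slope")
})

test_that("an input firing zero rules raises an informative error", {
  v <- fuzzy_variable("x", c(0, 1), list(lo = c(0, 0, 0.4, 0.6),
                                         hi = c(0.4, 0.6, 1, 1)))
  cfg <- fis_config(list(v), v, list(c("lo", "lo")))
  expect_error(evaluate_fis(cfg, cbind(0.9)), "fires zero rules")
})

test_that("constraints zero out wide, large or high-order reaches", {
  cap <- c(10, 10, 10, 10, 10)
  out <- apply_constraints(cap,
                           width_m = c(5, 30, 5, 5, 5),
                           contrib_area_km2 = c(10, 10, 300, 10, 10),
                           order = c(2, 2, 2, 6, 5))
  expect_equal(out, c(10, 0, 0, 0, 0.9))
})

test_that("capacity categories use half-open intervals", {
  x <- categorize_capacity(c(0, 0.5, 1, 1.2, 4, 7, 15, 16, 30))
  expect_equal(as.character(x),
               c("None", "Rare", "Rare", "Occasional", "Occasional",
                 "Frequent", "Frequent", "Pervasive", "Pervasive"))
  expect_error(categorize_capacity(31), "out of range")
  expect_equal(max_dams(c(2, 0), c(500, 800)), c(1, 0))
})
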