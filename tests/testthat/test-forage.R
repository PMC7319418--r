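test_that("suitability tables load and reclassify all four source types", {
  tabs <- default_suitability()
  expect_setequal(names(tabs), c("os_vector", "lcm_raster", "tcd_percent",
                                 "wlff_lines"))
  # categorical raster
  lev <- c("Broadleaf woodland", "Water", "Improved grassland")
  r <- dc_raster(matrix(c(1L, 2L, 3L, 1L), 2, 2), cellsize = 10)
  attr(r, "levels") <- lev
  rc <- reclassify_source(r, tabs$lcm_raster)
  expect_equal(rc$values, matrix(c(5, 0, 1, 5), 2, 2))
  # percent bands: 1-3 -> 1, 4-10 -> 2, 11-50 -> 3, 51-100 -> 4, <1 -> NA
  p <- dc_raster(matrix(c(0.5, 2, 8, 30, 80, 100), 2, 3), cellsize = 20)
  pc <- reclassify_source(p, tabs$tcd_percent)
  expect_equal(as.vector(pc$values), c(NA, 1, 2, 3, 4, 4))
  # vector layers gain a suit column
  v <- dc_features(list(rbind(c(0, 0), c(5, 0))), "LineString",
                   class = "Woody linear feature")
  expect_equal(reclassify_source(v, tabs$wlff_lines)$suit, 4)
  # unmapped class without default errors
  v$class <- "Motorway"
  expect_error(reclassify_source(v, tabs$wlff_lines), "unmapped")
})

test_that("composite honours priority then maximum, and nodata scores 0", {
  g <- function(v) dc_raster(matrix(v, 1, 3), cellsize = 5)
  prio <- g(c(5, NA, NA))
  a <- g(c(1, 2, NA))
  b <- g(c(3, 1, NA))
  out <- composite_bfi(list(prio, a, b), priority = 1)
  expect_equal(as.vector(out$values), c(5, 2, 0))
})

test_that("rasterize_and_align rejects disjoint frames and aligns grids", {
  v <- dc_features(list(rbind(c(0, 0), c(50, 0))), "LineString", suit = 3)
  far <- dc_features(list(rbind(c(1e6, 1e6), c(1e6 + 50, 1e6))), "LineString",
                     suit = 2)
  expect_error(rasterize_and_align(list(v, far), extent = c(0, 0, 100, 100)),
               "coordinate frame")
  r10 <- dc_raster(matrix(2, 5, 5), cellsize = 10)
  out <- rasterize_and_align(list(v, r10), cellsize = 5,
                             extent = c(0, 0, 50, 50))
  expect_true(all(vapply(out, function(x) x$cellsize == 5, TRUE)))
  expect_true(same_grid(out[[1]], out[[2]]))
})

test_that("top_half_mean matches its definition", {
  expect_equal(top_half_mean(c(1, 2, 3, 4)), 3.5)
  expect_equal(top_half_mean(c(5)), 5)
  expect_equal(top_half_mean(c(0, 0, 6)), mean(c(6, 0)))
})

test_that("reach forage extraction picks up the riparian signal", {
  # uniform BFI 2 everywhere except a 5-valued stripe along the reach
  m <- matrix(2, 40, 40)
  m[19:21, ] <- 5
  bfi <- dc_raster(m, cellsize = 5)
  reach <- dc_features(list(rbind(c(20, 100), c(180, 100))), "LineString")
  near <- extract_reach_forage(reach, bfi, distance = 10)
  wide <- extract_reach_forage(reach, bfi, distance = 40)
  expect_gt(near, wide)      # stripe dominates the narrow band
  expect_gte(wide, 2); expect_lte(near, 5)
  # empty window scores 0 with a warning
  off <- dc_features(list(rbind(c(900, 900), c(950, 900))), "LineString")
  expect_warning(z <- extract_reach_forage(off, bfi, distance = 10),
                 "empty forage sample")
  expect_equal(as.numeric(z), 0)
})

test_that("BFI categories split at integer breakpoints", {
  x <- classify_bfi_category(c(0, 1, 1.5, 2.2, 3.7, 4.2, 5))
  expect_equal(as.character(x), c("unsuitable", "unsuitable", "low", "medium",
                                  "high", "preferred", "preferred"))
})
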