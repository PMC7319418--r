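test_that("priority-flood fill removes pits and keeps drained cells", {
  # a bowl: centre pit must fill to its spill level
  z <- matrix(5, 9, 9)
  z[5, 5] <- 1
  z[5, 6] <- 3  # spill path
  z[5, 7:9] <- c(2.5, 2, 1.5)
  r <- dc_raster(z, cellsize = 1)
  fg <- flow_accumulation(r)
  expect_gte(fg$filled$values[5, 5], 3)           # pit raised to spill level
  expect_equal(fg$filled$values[5, 9], 1.5)       # drained cells untouched
  expect_true(all(fg$filled$values >= z))
  # every cell eventually drains off-grid: walk each cell downstream; the
  # path must terminate at dir 0 without cycling
  dirv <- as.vector(fg$dir)
  for (i in seq_along(dirv)) {
    steps <- 0L; j <- i
    while (dirv[j] != 0L && steps < length(dirv)) { j <- dirv[j]; steps <- steps + 1L }
    expect_lt(steps, length(dirv))
  }
})

test_that("accumulation on a tilted plane is column-monotone", {
  set.seed(1)
  z <- dc_raster(matrix(rep(8:1, each = 8), 8, 8) +
                   0.001 * matrix(runif(64), 8, 8), cellsize = 1)
  fg <- flow_accumulation(z)
  expect_equal(sum(fg$acc$values == 1) > 0, TRUE)     # ridge cells
  expect_equal(max(fg$acc$values) <= 64, TRUE)
  # total accumulation leaving the grid equals the cell count
  dirv <- as.vector(fg$dir); accv <- as.vector(fg$acc$values)
  expect_equal(sum(accv[dirv == 0L]), 64)
})

test_that("stream burning requires intersection and lowers only the mask", {
  dtm <- dc_raster(matrix(100, 20, 20), cellsize = 5)
  net <- list(rbind(c(10, 50), c(90, 50)))
  b <- burn_dtm(dtm, net)
  expect_equal(sort(unique(as.vector(b$values))), c(70, 100))
  expect_error(burn_dtm(dtm, list(rbind(c(1e5, 1e5), c(1e5 + 10, 1e5)))),
               "does not intersect")
})

test_that("reach slope uses the unburned terrain and floors at 1e-4", {
  dtm <- dc_raster(matrix(rep(seq(100, 81, length.out = 20), each = 20), 20, 20),
                   cellsize = 5)
  rch <- dc_features(list(rbind(c(10, 50), c(90, 50)),
                          rbind(c(10, 20), c(10.5, 20))), "LineString")
  s <- reach_slope(rch, dtm)
  expect_equal(s[1], (raster_extract(dtm, 10, 50) - raster_extract(dtm, 90, 50)) / 80)
  expect_equal(s[2], 1e-4)   # flat micro-reach floored
  off <- dc_features(list(rbind(c(-50, 0), c(-10, 0))), "LineString")
  expect_error(reach_slope(off, dtm), "outside the terrain grid")
})

test_that("contributing area converts max accumulation to km2", {
  scn <- small_scenario(seed = 21)
  cm <- generate_terrain(scn)
  fg <- flow_accumulation(burn_dtm(cm$dtm, cm$network))
  rch <- segment_network(cm$network)
  a <- contributing_area(rch, fg)
  expect_true(all(a > 0))
  cellkm2 <- fg$acc$cellsize^2 / 1e6
  expect_lte(max(a), max(fg$acc$values) * cellkm2 + 1e-12)
  # the outlet-most reach drains nearly the whole grid
  expect_gt(max(a) / (length(fg$acc$values) * cellkm2), 0.8)
})

test_that("corrected Strahler orders match the vector-network oracle", {
  for (seed in c(31, 32)) {
    scn <- small_scenario(seed = seed, n = 128, tribs = 3)
    cm <- generate_terrain(scn)
    fg <- flow_accumulation(burn_dtm(cm$dtm, cm$network))
    rch <- segment_network(cm$network)
    so <- strahler_with_correction(fg, rch, cm$network)
    want_net <- oracle_vector_strahler(cm$network, cm$outlet)
    want <- want_net[match(rch$parent_id, cm$network$id)]
    expect_equal(so$reach_order, want, info = paste("seed", seed))
  }
})
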