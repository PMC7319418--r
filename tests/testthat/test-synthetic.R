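test_that("scenario validation rejects degenerate configurations", {
  expect_error(catchment_scenario(grid_shape = c(8, 8)), "degenerate")
  expect_error(catchment_scenario(cell_size = -1))
  expect_error(catchment_scenario(gauge_count = 1))
  expect_error(catchment_scenario(flow_law = c(a = -1, b = 0.8)))
  bad <- default_mosaic()
  bad$os_vector["Water"] <- 2  # fractions sum above 1
  expect_error(catchment_scenario(mosaic = bad))
})

test_that("terrain generation is reproducible and drains to the outlet", {
  scn <- small_scenario(seed = 11)
  cm1 <- generate_terrain(scn)
  cm2 <- generate_terrain(scn)
  expect_identical(cm1$dtm$values, cm2$dtm$values)
  # elevation decreases monotonically down the main stem
  stem <- cm1$network$geometry[[1]]
  z <- vapply(seq_len(nrow(stem)), function(i)
    raster_extract(cm1$dtm, stem[i, 1], stem[i, 2]), numeric(1))
  expect_true(all(diff(z) <= 1e-9) || all(diff(z) >= -1e-9))
  # outlet is the lowest network point
  zo <- raster_extract(cm1$dtm, cm1$outlet[1], cm1$outlet[2])
  expect_lte(zo, min(z) + 1e-9)
})

test_that("different seeds give different catchments", {
  a <- generate_terrain(small_scenario(seed = 1))
  b <- generate_terrain(small_scenario(seed = 2))
  expect_false(identical(a$dtm$values, b$dtm$values))
})

test_that("landcover respects mosaic fractions and validates labels", {
  scn <- small_scenario(seed = 3)
  cm <- generate_terrain(scn)
  lc <- generate_landcover(scn, cm)
  # lcm raster class shares within a few points of the requested mosaic
  lev <- attr(lc$lcm_raster, "levels")
  tab <- table(factor(lev[lc$lcm_raster$values], levels = lev))
  frac <- as.numeric(tab) / sum(tab)
  lcrows <- scn$landcover_mosaic[scn$landcover_mosaic$source_layer == "lcm_raster", ]
  want <- lcrows$target_fraction[match(lev, lcrows$class_label)]
  expect_true(all(abs(frac - want) < 0.08))
  # unknown labels rejected
  bad <- scn
  bad$landcover_mosaic$class_label[1] <- "Lava field"
  expect_error(generate_landcover(bad, cm), "unknown class label")
})

test_that("flows are reproducible and follow the generating power law", {
  scn <- small_scenario(seed = 5, flow_sigma = 1e-6)
  cm <- generate_terrain(scn)
  gf1 <- generate_flows(scn, cm)
  gf2 <- generate_flows(scn, cm)
  expect_identical(gf1$flows$flow_m3s, gf2$flows$flow_m3s)
  expect_equal(nrow(gf1$gauges), scn$gauge_count)
  expect_equal(nrow(gf1$flows), scn$gauge_count * scn$n_days)
  # with negligible noise, median flow ~ a * A^b
  med <- tapply(gf1$flows$flow_m3s, gf1$flows$gauge_id, stats::median)
  want <- scn$flow_law[["a"]] * gf1$gauges$area_km2^scn$flow_law[["b"]]
  expect_equal(as.numeric(med[gf1$gauges$gauge_id]), want, tolerance = 1e-3)
})

test_that("simulated observations carry a coherent truth attribute", {
  scn <- small_scenario(seed = 8)
  reaches <- data.frame(reach_id = sprintf("R%02d", 1:40),
                        max_dams = runif(40, 0, 4))
  reaches$bfi_category <- sample(c("unsuitable", "low", "medium", "high",
                                   "preferred"), 40, replace = TRUE)
  reaches$geometry <- lapply(1:40, function(i)
    rbind(c(i * 10, 0), c(i * 10 + 5, 5)))
  obs <- simulate_observations(scn, reaches)
  tr <- attr(obs, "truth")
  expect_equal(sum(tr$dams), sum(obs$kind == "dam"))
  expect_true(all(obs$true_reach %in% reaches$reach_id[tr$is_active]))
  # every active reach contributes at least one feeding sign
  expect_setequal(unique(obs$true_reach), reaches$reach_id[tr$is_active])
  expect_identical(obs$kind, simulate_observations(scn, reaches)$kind)
})
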