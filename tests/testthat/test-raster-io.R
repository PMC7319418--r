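test_that("ASCII grid round-trips exactly", {
  m <- matrix(c(1.5, NA, 3, 4, 5, 6), 2, 3)
  r <- dc_raster(m, xll = 100, yll = 200, cellsize = 5)
  f <- withr::local_tempfile(fileext = ".asc")
  write_asc(r, f)
  r2 <- read_asc(f)
  expect_equal(r2$values, r$values)
  expect_equal(r2$xll, 100)
  expect_equal(r2$cellsize, 5)
})

test_that("raster coordinates, extraction and resampling agree", {
  r <- dc_raster(matrix(1:12, 3, 4), xll = 0, yll = 0, cellsize = 10)
  # top-left cell centre is (5, 25): row 1 is the northern row
  expect_equal(raster_extract(r, 5, 25), 1)
  expect_equal(raster_extract(r, 35, 5), 12)
  expect_true(is.na(raster_extract(r, -5, 5)))
  tmpl <- raster_template(0, 0, 40, 30, cellsize = 5)
  rs <- raster_resample_nn(r, tmpl)
  expect_equal(raster_extract(rs, 6, 26), 1) # nearest neighbour preserved
  expect_equal(dim(rs$values), c(6, 8))
})

test_that("GeoJSON round-trips all three geometry types", {
  f <- withr::local_tempfile(fileext = ".geojson")
  lines <- dc_features(list(rbind(c(0, 0), c(5, 5))), "LineString", id = "a")
  write_geojson(lines, f)
  back <- read_geojson(f)
  expect_equal(back$geometry[[1]], lines$geometry[[1]])
  expect_equal(back$id, "a")
  pts <- dc_features(list(matrix(c(1, 2), 1), matrix(c(3, 4), 1)), "Point",
                     kind = c("dam", "sign"))
  write_geojson(pts, f)
  expect_equal(read_geojson(f)$kind, c("dam", "sign"))
})
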