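test_that("line length, interpolation and splitting are consistent", {
  g <- rbind(c(0, 0), c(3, 4), c(3, 10))
  expect_equal(line_length(g), 11)
  expect_equal(line_interpolate(g, 5), matrix(c(3, 4), 1))
  expect_equal(line_interpolate(g, c(-2, 99))[1, ], c(0, 0)) # clamped
  expect_equal(line_interpolate(g, 99)[1, ], c(3, 10))
  parts <- line_split(g, c(2.5, 5, 8))
  expect_length(parts, 4)
  expect_equal(sum(vapply(parts, line_length, 0)), 11)
  # split points sit on the line
  expect_equal(parts[[1]][nrow(parts[[1]]), ], as.vector(line_interpolate(g, 2.5)))
})

test_that("distance to line and point-in-polygon are exact on known cases", {
  g <- rbind(c(0, 0), c(10, 0))
  expect_equal(dist_to_line(cbind(5, 3), g), 3)
  expect_equal(dist_to_line(cbind(-4, 0), g), 4)
  expect_equal(dist_to_line(cbind(13, 4), g), 5)
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  expect_true(point_in_polygon(5, 5, sq))
  expect_false(point_in_polygon(15, 5, sq))
  # polygon with a hole (second ring)
  hole <- rbind(c(4, 4), c(6, 4), c(6, 6), c(4, 6), c(4, 4))
  expect_false(point_in_polygon(5, 5, list(sq, hole)))
  expect_true(point_in_polygon(2, 2, list(sq, hole)))
})

test_that("ring area and buffering are consistent", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  expect_equal(abs(ring_area(sq)), 100)
  ring <- line_buffer_ring(rbind(c(0, 0), c(100, 0)), 5)
  expect_equal(abs(ring_area(ring)), 1000, tolerance = 0.01)
})

test_that("dist_to_lines returns nearest line index", {
  lines <- list(rbind(c(0, 0), c(10, 0)), rbind(c(0, 20), c(10, 20)))
  r <- dist_to_lines(cbind(c(5, 5), c(3, 18)), lines)
  expect_equal(r$which, c(1L, 2L))
  expect_equal(r$dist, c(3, 2))
})
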