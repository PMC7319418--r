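test_that("segmentation thresholds and conserves length", {
  mk <- function(len) rbind(c(0, 0), c(len, 0))
  net <- dc_features(list(mk(150), mk(200), mk(450), mk(199.99)), "LineString",
                     id = c("a", "b", "c", "d"))
  rch <- segment_network(net)
  expect_equal(as.integer(table(rch$parent_id)[c("a", "b", "c", "d")]),
               c(1L, 2L, 3L, 1L))          # 200 m splits in two; 450 -> 3
  expect_true(all(rch$length_m < 200))
  expect_equal(sum(rch$length_m), 150 + 200 + 450 + 199.99)
  expect_equal(rch$reach_id, sprintf("R%04d", seq_len(nrow(rch))))
  # zero-length feature dropped with warning
  net0 <- dc_features(list(mk(100), rbind(c(5, 5), c(5, 5))), "LineString",
                      id = c("a", "z"))
  expect_warning(r0 <- segment_network(net0), "zero-length")
  expect_equal(nrow(r0), 1)
})

test_that("bankfull width recovers a known rectangular channel", {
  reach <- dc_features(list(rbind(c(50, 100), c(250, 100))), "LineString")
  chan <- dc_features(list(rbind(c(50, 96), c(250, 96), c(250, 104),
                                 c(50, 104), c(50, 96))), "Polygon")
  w <- mean_bankfull_width(reach, chan)
  expect_equal(as.numeric(w), 8, tolerance = 0.15)
  expect_false(attr(w, "capped"))
  # no channel polygon -> declared minimum
  w0 <- mean_bankfull_width(reach, chan[0, , drop = FALSE])
  expect_equal(as.numeric(w0), 0.5)
  # channel wider than the whole buffer is flagged as capped
  big <- dc_features(list(rbind(c(-50, 0), c(350, 0), c(350, 200),
                                c(-50, 200), c(-50, 0))), "Polygon")
  wb <- mean_bankfull_width(reach, big)
  expect_true(attr(wb, "capped"))
})

test_that("snapping assigns nearest reach, drops excluded, breaks ties low", {
  reaches <- dc_features(list(rbind(c(0, 0), c(100, 0)),
                              rbind(c(0, 50), c(100, 50))), "LineString",
                         reach_id = c("R0001", "R0002"))
  pts <- dc_features(list(matrix(c(50, 10), 1), matrix(c(50, 45), 1),
                          matrix(c(50, 25), 1), matrix(c(10, 60), 1)),
                     "Point", kind = c("dam", "feeding_sign", "dam", "dam"))
  mask <- dc_features(list(rbind(c(0, 55), c(20, 55), c(20, 70),
                                 c(0, 70), c(0, 55))), "Polygon")
  expect_message(sn <- snap_observations(pts, reaches, mask), "equidistant")
  expect_equal(attr(sn, "n_excluded"), 1L)
  expect_equal(sn$snapped_reach_id, c("R0001", "R0002", "R0001"))
  expect_equal(sn$snap_distance_m, c(10, 5, 25))
  # distant point warns but still snaps
  far <- dc_features(list(matrix(c(50, 500), 1)), "Point", kind = "dam")
  expect_warning(sf <- snap_observations(far, reaches), "over 100 m")
  expect_equal(sf$snapped_reach_id, "R0002")
})

test_that("activity flag counts standing dams only", {
  reaches <- dc_features(list(rbind(c(0, 0), c(10, 0)),
                              rbind(c(0, 9), c(10, 9))), "LineString",
                         reach_id = c("R0001", "R0002"))
  sn <- data.frame(snapped_reach_id = c("R0001", "R0001", "R0001"),
                   kind = c("dam", "removed_dam", "feeding_sign"))
  out <- flag_activity(reaches, sn)
  expect_equal(out$is_active, c(TRUE, FALSE))
  expect_equal(out$observed_dams, c(1L, 0L))
})
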