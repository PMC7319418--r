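# Working-reach network: segmentation into <200 m reaches, mean bankfull
# width, observation snapping and activity flags.

#' Segment a stream network into working reaches
#'
#' The network (already noded at confluences) is cut so every reach is
#' shorter than 200 m: features under the threshold pass through unchanged;
#' features at or over it are split into the minimum number of equal parts
#' below the threshold (features of exactly 200 m are split in two).
#' Zero-length features are dropped with a warning. Total length is
#' conserved.
#' @param network `dc_features` of LineStrings.
#' @param max_len threshold length in metres (default 200).
#' @return `dc_features` of reach polylines with columns `reach_id`,
#'   `parent_id`, `length_m`.
#' @export
segment_network <- function(network, max_len = 200) {
  geoms <- list(); parent <- character(0)
  ids <- if ("id" %in% names(network)) network$id else as.character(seq_len(nrow(network)))
  for (i in seq_len(nrow(network))) {
    g <- network$geometry[[i]]
    L <- line_length(g)
    if (L <= 1e-9) {
      warning("dropping zero-length feature ", ids[i])
      next
    }
    parts <- if (L < max_len) 1L else max(2L, ceiling(L / max_len))
    segs <- if (parts == 1L) list(g) else
      line_split(g, seq_len(parts - 1L) / parts * L)
    geoms <- c(geoms, segs)
    parent <- c(parent, rep(ids[i], parts))
  }
  if (!length(geoms)) stop("no usable features in network")
  lens <- vapply(geoms, line_length, numeric(1))
  dc_features(geoms, "LineString",
              reach_id = sprintf("R%04d", seq_along(geoms)),
              parent_id = parent, length_m = lens)
}

#' Mean bankfull width per reach
#'
#' The reach is buffered to 20 m, the buffer clipped by the channel-area
#' polygons, and the clipped area divided by reach length. The clip is
#' evaluated on a regular point lattice (default 1 m), which is exact to the
#' lattice resolution. Reaches that intersect no channel polygon get the
#' declared minimum width. Widths limited by the buffer itself (channel
#' wider than 2 x buffer) are flagged in the `capped` attribute.
#' @param reaches `dc_features` of reach polylines.
#' @param channels `dc_features` of channel polygons (may be empty).
#' @param buffer buffer radius in metres (default 20).
#' @param min_width width assigned when no polygon intersects (default 0.5).
#' @param res sampling lattice spacing in metres (default 1).
#' @return numeric widths (m) with logical attribute `capped`.
#' @export
mean_bankfull_width <- function(reaches, channels, buffer = 20,
                                min_width = 0.5, res = 1) {
  n <- nrow(reaches)
  out <- rep(min_width, n)
  capped <- rep(FALSE, n)
  have_chan <- !is.null(channels) && nrow(channels) > 0
  for (i in seq_len(n)) {
    g <- reaches$geometry[[i]]
    if (!have_chan) next
    bb <- bbox_of(list(g))
    xs <- seq(bb[1] - buffer, bb[3] + buffer, by = res)
    ys <- seq(bb[2] - buffer, bb[4] + buffer, by = res)
    px <- rep(xs, each = length(ys)); py <- rep(ys, length(xs))
    inbuf <- dist_to_line(cbind(px, py), g) <= buffer
    if (!any(inbuf)) next
    px <- px[inbuf]; py <- py[inbuf]
    inchan <- rep(FALSE, length(px))
    for (j in seq_len(nrow(channels))) {
      ring <- channels$geometry[[j]]
      rb <- bbox_of(list(ring))
      cand <- which(!inchan & px >= rb[1] & px <= rb[3] & py >= rb[2] & py <= rb[4])
      if (length(cand))
        inchan[cand] <- point_in_polygon(px[cand], py[cand], ring)
    }
    if (!any(inchan)) next
    area <- sum(inchan) * res^2
    out[i] <- area / line_length(g)
    # buffer-limited: nearly the whole buffer lies in channel
    if (mean(inchan) > 0.95) capped[i] <- TRUE
  }
  attr(out, "capped") <- capped
  out
}

#' Snap observation points to the nearest reach
#'
#' Each point outside the exclusion masks is assigned to the nearest reach
#' by perpendicular distance; equidistant points go to the lowest reach_id
#' (logged). Points inside an exclusion polygon are dropped and counted.
#' There is no maximum snap distance; distances over 100 m raise a warning.
#' @param points `dc_features` of Points with a `kind` column
#'   ("feeding_sign", "dam", "removed_dam").
#' @param reaches `dc_features` of reach polylines with `reach_id`.
#' @param exclusion_masks optional `dc_features` of Polygons (e.g. enclosed
#'   sites whose damming may not reflect natural behaviour).
#' @return `dc_features` of the retained points with `snapped_reach_id` and
#'   `snap_distance_m`; attribute `n_excluded` counts dropped points.
#' @export
snap_observations <- function(points, reaches, exclusion_masks = NULL) {
  if (nrow(reaches) == 0L) stop("no reaches to snap to")
  if (nrow(points) == 0L) {
    out <- points
    out$snapped_reach_id <- character(0)
    out$snap_distance_m <- numeric(0)
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  pxy <- do.call(rbind, points$geometry)
  keep <- rep(TRUE, nrow(points))
  if (!is.null(exclusion_masks) && nrow(exclusion_masks) > 0) {
    for (j in seq_len(nrow(exclusion_masks)))
      keep <- keep & !point_in_polygon(pxy[, 1], pxy[, 2],
                                       exclusion_masks$geometry[[j]])
  }
  n_excluded <- sum(!keep)
  pts <- points[keep, , drop = FALSE]
  pxy <- pxy[keep, , drop = FALSE]
  nd <- matrix(Inf, nrow(pts), nrow(reaches))
  for (j in seq_len(nrow(reaches)))
    nd[, j] <- dist_to_line(pxy, reaches$geometry[[j]])
  best <- apply(nd, 1, min)
  # tie-break: lowest reach_id among (numerically) equidistant reaches
  ord <- order(reaches$reach_id)
  idx <- apply(nd[, ord, drop = FALSE] <= best + 1e-9, 1, which.max)
  ties <- rowSums(nd <= best + 1e-9) > 1
  if (any(ties))
    message(sum(ties), " equidistant point(s) assigned to the lowest reach_id")
  if (any(best > 100))
    warning(sum(best > 100), " point(s) snapped over 100 m")
  out <- pts
  out$snapped_reach_id <- reaches$reach_id[ord][idx]
  out$snap_distance_m <- best
  attr(out, "geom_type") <- "Point"
  class(out) <- c("dc_features", "data.frame")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Flag active reaches and count observed dams
#'
#' A reach is active when at least one snapped point of any kind lies on it.
#' Observed dams count only points of kind "dam": removed or collapsed dams
#' mark activity but are not modelled as standing dams.
#' @param reaches `dc_features` with `reach_id`.
#' @param snapped output of [snap_observations()].
#' @return `reaches` with logical `is_active` and integer `observed_dams`.
#' @export
flag_activity <- function(reaches, snapped) {
  act <- unique(snapped$snapped_reach_id)
  reaches$is_active <- reaches$reach_id %in% act
  dam_tab <- table(snapped$snapped_reach_id[snapped$kind == "dam"])
  reaches$observed_dams <- as.integer(dam_tab[reaches$reach_id])
  reaches$observed_dams[is.na(reaches$observed_dams)] <- 0L
  class(reaches) <- c("dc_features", "data.frame")
  reaches
}
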