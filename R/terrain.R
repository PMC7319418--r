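# Terrain analysis: stream burning, hydrological conditioning (priority-flood
# pit filling), D8 routing, flow accumulation, and Strahler stream order with
# the burned-network correction.
#
# Grids are small (catchment fixtures), so routines are plain R working on
# the raster matrix in column-major linear indexing.

#' Rasterise polylines to a cell mask
#'
#' A cell is marked when its centre lies within `tol` of any line (default:
#' half a cell, i.e. the line passes through the cell).
#' @param template raster defining the grid.
#' @param lines list of polyline coordinate matrices (or a `dc_features`).
#' @param tol distance tolerance in metres; default half the cell size.
#' @return logical matrix of the template's shape.
#' @export
rasterize_lines_mask <- function(template, lines, tol = template$cellsize / 2) {
  if (inherits(lines, "dc_features")) lines <- lines$geometry
  nr <- raster_nrow(template); nc <- raster_ncol(template)
  mask <- matrix(FALSE, nr, nc)
  cs <- template$cellsize
  for (ln in lines) {
    pts <- line_densify(ln, cs / 4)
    rc <- raster_rowcol(template, pts[, 1], pts[, 2])
    rc <- rc[!is.na(rc[, 1]), , drop = FALSE]
    # candidate cells: hit cells plus their 8-neighbourhood
    cand <- unique(rbind(rc,
      do.call(rbind, lapply(list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)),
                            function(o) cbind(rc[, 1] + o[1], rc[, 2] + o[2])))))
    cand <- cand[cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 & cand[, 2] <= nc, , drop = FALSE]
    cand <- unique(cand)
    cx <- template$xll + (cand[, 2] - 0.5) * cs
    cy <- template$yll + (nr - cand[, 1] + 0.5) * cs
    d <- dist_to_line(cbind(cx, cy), ln)
    keep <- cand[d <= tol + 1e-9, , drop = FALSE]
    if (nrow(keep)) mask[keep] <- TRUE
  }
  mask
}

#' Stream-burn a terrain model
#'
#' Lowers cells coinciding with the vector stream network by a fixed depth so
#' that subsequent flow routing follows the mapped channels. Not idempotent:
#' call once per pipeline run.
#' @param dtm elevation raster.
#' @param network stream network (`dc_features` of LineStrings or list of
#'   coordinate matrices).
#' @param depth burn depth in metres (default 30).
#' @return burned elevation raster.
#' @export
burn_dtm <- function(dtm, network, depth = 30) {
  mask <- rasterize_lines_mask(dtm, network)
  if (!any(mask)) stop("stream network does not intersect the terrain grid")
  out <- dtm
  out$values[mask] <- out$values[mask] - depth
  out
}

## -- priority-flood fill + D8 -------------------------------------------

.neighbours <- function(nr, nc) {
  # offsets in linear (column-major) indexing plus row guards
  list(
    drow = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
    dcol = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L),
    dist = c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2))
  )
}

#' Condition a terrain grid and derive D8 flow directions and accumulation
#'
#' Applies priority-flood pit filling with a small epsilon gradient (so every
#' cell drains to the grid boundary), derives single-direction (D8) flow to
#' the steepest downslope neighbour of the filled surface, and accumulates
#' cell counts downstream.
#' @param burned elevation raster (typically stream-burned).
#' @return a `dc_flowgrid`: list with `filled` (raster), `dir` (integer
#'   matrix of receiver linear indices, 0 = drains off-grid), `acc` (raster of
#'   upstream cell counts, including the cell itself) and `order` (linear
#'   indices, downstream-last).
#' @export
flow_accumulation <- function(burned) {
  z <- burned$values
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  if (anyNA(z)) stop("elevation grid contains missing cells")
  nb <- .neighbours(nr, nc)
  eps <- 1e-6
  filled <- rep(NA_real_, n)
  seen <- rep(FALSE, n)
  # binary min-heap on (key, id) held in local vectors so element updates
  # stay in place (environment-held vectors would be copied on every write)
  hkey <- numeric(n); hid <- integer(n); hn <- 0L
  zv <- as.vector(z)
  rows <- rep(seq_len(nr), nc); cols <- rep(seq_len(nc), each = nr)
  # seed with boundary cells (already sorted into a valid heap afterwards)
  bcells <- unique(c(seq_len(nr), seq_len(nr) + (nc - 1L) * nr,
                     (seq_len(nc) - 1L) * nr + 1L, (seq_len(nc) - 1L) * nr + nr))
  o <- order(zv[bcells])
  hn <- length(bcells)
  hkey[seq_len(hn)] <- zv[bcells][o]
  hid[seq_len(hn)] <- bcells[o]
  seen[bcells] <- TRUE
  while (hn > 0L) {
    # pop the minimum
    key <- hkey[1L]; i <- hid[1L]
    hkey[1L] <- hkey[hn]; hid[1L] <- hid[hn]
    hn <- hn - 1L
    p <- 1L
    repeat {
      l <- 2L * p; s <- p
      if (l <= hn && hkey[l] < hkey[s]) s <- l
      if (l < hn && hkey[l + 1L] < hkey[s]) s <- l + 1L
      if (s == p) break
      tk <- hkey[s]; hkey[s] <- hkey[p]; hkey[p] <- tk
      ti <- hid[s]; hid[s] <- hid[p]; hid[p] <- ti
      p <- s
    }
    filled[i] <- key
    r0 <- rows[i]; c0 <- cols[i]
    for (k in 1:8) {
      rr <- r0 + nb$drow[k]; cc <- c0 + nb$dcol[k]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      j <- (cc - 1L) * nr + rr
      if (seen[j]) next
      seen[j] <- TRUE
      # push max(z_j, spill level)
      kj <- if (zv[j] > key + eps) zv[j] else key + eps
      hn <- hn + 1L
      if (hn > length(hkey)) { length(hkey) <- 2L * hn; length(hid) <- 2L * hn }
      hkey[hn] <- kj; hid[hn] <- j
      p <- hn
      while (p > 1L) {
        q <- p %/% 2L
        if (hkey[q] <= hkey[p]) break
        tk <- hkey[q]; hkey[q] <- hkey[p]; hkey[p] <- tk
        ti <- hid[q]; hid[q] <- hid[p]; hid[p] <- ti
        p <- q
      }
    }
  }
  if (anyNA(filled)) stop("unresolved pits after priority-flood fill")
  # D8 on the filled surface
  dirv <- integer(n)
  cs <- burned$cellsize
  best <- rep(0, n)
  fz <- filled
  for (k in 1:8) {
    rr <- rows + nb$drow[k]; cc <- cols + nb$dcol[k]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    j <- (cc - 1L) * nr + rr
    grad <- rep(-Inf, n)
    grad[ok] <- (fz[ok] - fz[j[ok]]) / (nb$dist[k] * cs)
    upd <- ok & grad > best + 1e-15
    dirv[upd] <- j[upd]
    best[upd] <- grad[upd]
  }
  # boundary cells without a lower neighbour drain off-grid (dir 0)
  ord <- order(fz, decreasing = TRUE)
  acc <- rep(1, n)
  for (i in ord) {
    j <- dirv[i]
    if (j > 0L) acc[j] <- acc[j] + acc[i]
  }
  structure(list(
    filled = dc_raster(matrix(filled, nr, nc), burned$xll, burned$yll, cs),
    dir = matrix(dirv, nr, nc),
    acc = dc_raster(matrix(acc, nr, nc), burned$xll, burned$yll, cs),
    order = ord
  ), class = "dc_flowgrid")
}

#' @export
print.dc_flowgrid <- function(x, ...) {
  cat(sprintf("<dc_flowgrid %d x %d, max accumulation %g cells>\n",
              raster_nrow(x$acc), raster_ncol(x$acc), max(x$acc$values)))
  invisible(x)
}

# linear indices of cells a reach geometry passes through
.reach_cells <- function(reach_coords, template, fractions = NULL) {
  if (is.null(fractions)) {
    pts <- line_densify(reach_coords, template$cellsize / 2)
  } else {
    pts <- line_interpolate(reach_coords, fractions * line_length(reach_coords))
  }
  rc <- raster_rowcol(template, pts[, 1], pts[, 2])
  rc <- rc[!is.na(rc[, 1]), , drop = FALSE]
  unique((rc[, 2] - 1L) * raster_nrow(template) + rc[, 1])
}

#' Contributing area per reach
#'
#' The maximum flow accumulation among cells the reach passes through, times
#' the cell area, in square kilometres.
#' @param reaches `dc_features` of reach polylines.
#' @param fg a `dc_flowgrid`.
#' @return numeric vector of areas (km^2).
#' @export
contributing_area <- function(reaches, fg) {
  accv <- as.vector(fg$acc$values)
  cellkm2 <- (fg$acc$cellsize^2) / 1e6
  vapply(reaches$geometry, function(g) {
    cells <- .reach_cells(g, fg$acc)
    if (!length(cells)) return(NA_real_)
    max(accv[cells]) * cellkm2
  }, numeric(1))
}

#' Reach slope from the (unburned) terrain model
#'
#' Elevation difference between the reach endpoints divided by reach length;
#' the absolute value is used and the result floored at `floor` so downstream
#' stream-power terms stay positive.
#' @param reaches reach polylines (`dc_features` or list of matrices).
#' @param dtm unburned elevation raster.
#' @param floor minimum slope (default 1e-4).
#' @return numeric slope vector (dimensionless).
#' @export
reach_slope <- function(reaches, dtm, floor = 1e-4) {
  geoms <- if (inherits(reaches, "dc_features")) reaches$geometry else reaches
  vapply(geoms, function(g) {
    z0 <- raster_extract(dtm, g[1, 1], g[1, 2])
    z1 <- raster_extract(dtm, g[nrow(g), 1], g[nrow(g), 2])
    if (is.na(z0) || is.na(z1)) stop("reach endpoint lies outside the terrain grid")
    max(abs(z0 - z1) / line_length(g), floor)
  }, numeric(1))
}

#' Calibrate the raster stream accumulation threshold
#'
#' Picks a flow-accumulation threshold from the accumulation observed at the
#' mapped channel heads: a fraction of the smallest head accumulation. Below
#' every mapped head the raster stream is then guaranteed to exist, while it
#' still extends a little beyond each head into the unmapped headwater flow
#' paths (so the order correction applies), and hillslope flow paths much
#' weaker than the weakest mapped channel are suppressed.
#' @param fg a `dc_flowgrid`.
#' @param network mapped stream network (`dc_features` or list of matrices).
#' @param head_fraction fraction of the minimum head accumulation (default
#'   0.35).
#' @return threshold in cells, with attribute `head_acc` (the per-head
#'   accumulations).
#' @export
pick_accumulation_threshold <- function(fg, network, head_fraction = 0.25) {
  pts <- .head_points(network, fg$acc$cellsize)
  acc <- vapply(seq_len(nrow(pts)), function(i)
    raster_extract(fg$acc, pts[i, 1], pts[i, 2]), numeric(1))
  if (anyNA(acc)) stop("network endpoint lies outside the grid")
  acc <- acc[-which.max(acc)]  # the largest-accumulation endpoint is the outlet
  structure(max(10L, as.integer(round(head_fraction * min(acc)))),
            head_acc = acc)
}

# channel-head coordinates: degree-1 feature endpoints that do not lie on
# another feature's line (which excludes tributary mouths joining mid-stem);
# the outlet is still among them, callers drop the max-accumulation point
.head_points <- function(network, cellsize) {
  geoms <- if (inherits(network, "dc_features")) network$geometry else network
  tol <- cellsize * 1e-6
  ends <- lapply(geoms, function(g) rbind(g[1, ], g[nrow(g), ]))
  allpts <- do.call(rbind, ends)
  feat <- rep(seq_along(geoms), each = 2L)
  deg1 <- vapply(seq_len(nrow(allpts)), function(i) {
    d <- sqrt((allpts[, 1] - allpts[i, 1])^2 + (allpts[, 2] - allpts[i, 2])^2)
    sum(d < tol) == 1L
  }, logical(1))
  on_other <- vapply(seq_len(nrow(allpts)), function(i) {
    others <- geoms[-feat[i]]
    length(others) > 0 &&
      dist_to_lines(allpts[i, , drop = FALSE], others)$dist < tol
  }, logical(1))
  pts <- allpts[deg1 & !on_other, , drop = FALSE]
  if (nrow(pts) < 2L) stop("network has no identifiable channel heads")
  pts
}

#' Strahler stream order with burned-network correction
#'
#' Computes Strahler order on the raster stream (cells with accumulation at
#' or above `threshold_cells`) routed by D8. The raster stream is first
#' pruned to the mapped network plus flow paths that enter it through a
#' channel head, discarding hillslope convergence artifacts that join the
#' network mid-channel. Because the retained stream still extends beyond the
#' mapped network into unmapped headwater flow paths, raw orders along mapped
#' channels come out one order high; orders above 1 are therefore decremented
#' and residual first-order cells that do not coincide with the vector
#' network are discarded. Each reach then takes the maximum corrected order
#' among the stream cells along its interior.
#'
#' @param fg a `dc_flowgrid`.
#' @param reaches reach polylines (`dc_features`).
#' @param network the mapped vector network used for the correction.
#' @param threshold_cells accumulation threshold applied to the retained
#'   headwater paths; `NULL` (the default) calibrates a per-head threshold as
#'   `head_fraction` of each head's own flow accumulation.
#' @param head_fraction fraction used for the per-head calibration (default
#'   0.25); ignored when `threshold_cells` is given.
#' @return list with `reach_order` (integer per reach), `cell_order`
#'   (matrix of corrected orders, NA off-stream) and `threshold_cells` (the
#'   smallest threshold actually applied).
#' @export
strahler_with_correction <- function(fg, reaches, network, threshold_cells = NULL,
                                     head_fraction = 0.25) {
  accv <- as.vector(fg$acc$values)
  n <- length(accv)
  dirv <- as.vector(fg$dir)
  nr <- raster_nrow(fg$acc); ncg <- raster_ncol(fg$acc)
  lines <- if (inherits(network, "dc_features")) network$geometry else network
  # Prune the raster stream to the mapped network plus flow paths that reach
  # it *through a channel head*. Convergence artifacts on the hillslopes join
  # the network mid-channel; excluding them structurally keeps the
  # accumulation threshold uncritical across grid resolutions.
  mask <- as.vector(rasterize_lines_mask(fg$acc, lines))
  hp <- .head_points(network, fg$acc$cellsize)
  hacc <- raster_extract(fg$acc, hp[, 1], hp[, 2])
  out_i <- which.max(hacc)  # the max-accumulation endpoint is the outlet
  hp <- hp[-out_i, , drop = FALSE]; hacc <- hacc[-out_i]
  # each head carries its own threshold: a fixed fraction of the flow
  # accumulation at the head, so hillslope laterals stay below it while the
  # unmapped flow paths feeding the head stay above, at any grid resolution
  thr <- if (is.null(threshold_cells))
    pmax(10, round(head_fraction * hacc)) else rep(threshold_cells, length(hacc))
  status <- ifelse(mask, 2L, 0L)   # 1 head, 2 network, 3 blocked, 0 pending
  headid <- rep(0L, n)
  rc <- raster_rowcol(fg$acc, hp[, 1], hp[, 2])
  for (i in seq_len(nrow(rc))) {  # a head is its cell's 3x3 mask neighbourhood
    if (is.na(rc[i, 1])) next
    rr <- max(1L, rc[i, 1] - 1L):min(nr, rc[i, 1] + 1L)
    cc <- max(1L, rc[i, 2] - 1L):min(ncg, rc[i, 2] + 1L)
    idx <- as.vector(outer(rr, (cc - 1L) * nr, `+`))
    idx <- idx[mask[idx]]
    status[idx] <- 1L; headid[idx] <- i
  }
  # receivers are visited before their donors in reverse topological order,
  # so each off-network cell inherits where its flow path first meets the mask
  for (i in rev(fg$order)) {
    if (mask[i]) next
    j <- dirv[i]
    if (j > 0L && status[j] == 1L) {
      status[i] <- 1L; headid[i] <- headid[j]
    } else status[i] <- 3L
  }
  keep <- !mask & status == 1L
  stream <- mask
  stream[keep] <- accv[keep] >= thr[headid[keep]]
  threshold_cells <- min(thr)
  ord <- rep(NA_integer_, n)
  # donors among stream cells
  donors <- vector("list", 0L)
  # process upstream-first: fg$order is downstream-last (filled decreasing)
  maxord <- rep(0L, n); nmax <- rep(0L, n)
  for (i in fg$order) {
    if (!stream[i]) next
    o <- if (maxord[i] == 0L) 1L else maxord[i] + (nmax[i] >= 2L)
    ord[i] <- o
    j <- dirv[i]
    if (j > 0L && stream[j]) {
      if (o > maxord[j]) { maxord[j] <- o; nmax[j] <- 1L }
      else if (o == maxord[j]) nmax[j] <- nmax[j] + 1L
    }
  }
  # correction: decrement orders > 1; drop stray order-1 cells off the network
  corr <- ord
  corr[!is.na(corr) & corr > 1L] <- corr[!is.na(corr) & corr > 1L] - 1L
  ones <- which(!is.na(corr) & corr == 1L)
  if (length(ones)) {
    cs <- fg$acc$cellsize
    rows <- ((ones - 1L) %% nr) + 1L; cols <- ((ones - 1L) %/% nr) + 1L
    cx <- fg$acc$xll + (cols - 0.5) * cs
    cy <- fg$acc$yll + (nr - rows + 0.5) * cs
    d <- dist_to_lines(cbind(cx, cy), lines)$dist
    corr[ones[d > cs]] <- NA_integer_
  }
  # per reach: interior sampling avoids junction cells shared between reaches
  fr <- seq(0.2, 0.8, by = 0.1)
  reach_order <- vapply(reaches$geometry, function(g) {
    cells <- .reach_cells(g, fg$acc, fractions = fr)
    oo <- corr[cells]
    oo <- oo[!is.na(oo)]
    if (!length(oo)) {
      warning("reach with no corrected stream cells; assigning order 1")
      return(1L)
    }
    max(oo)
  }, integer(1))
  list(reach_order = reach_order,
       cell_order = matrix(corr, raster_nrow(fg$acc), raster_ncol(fg$acc)),
       threshold_cells = as.integer(threshold_cells))
}
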