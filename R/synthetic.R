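# Synthetic catchment generator.
#
# Builds complete, fully deterministic test catchments — terrain, a dendritic
# stream network, channel polygons, four landcover sources, gauge flow
# records and beaver field observations — with known generative parameters,
# so every downstream stage of the pipeline can be validated without
# national GIS datasets.
#
# Terrain is constructed (ridge-and-valley composition around a channel
# skeleton), not simulated: elevations increase with network distance to the
# outlet along channels and with lateral distance to the channel skeleton on
# hillslopes. The skeleton additionally carries two short unmapped headwater
# arms above every mapped channel head, emulating the real-world situation
# in which flow paths on a terrain model extend beyond the mapped network —
# the situation the Strahler-order correction exists for.

# run expr with a private RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Define a synthetic catchment scenario
#'
#' @param grid_shape integer c(rows, cols) of the terrain grid (min 16x16).
#' @param cell_size cell edge in metres (default 5).
#' @param relief total elevation range in metres.
#' @param drainage_style "dendritic_synthetic" (main stem plus tributaries)
#'   or "single_valley" (one channel).
#' @param n_tributaries number of tributaries for the dendritic style.
#' @param landcover_mosaic data.frame with columns `class_label`,
#'   `source_layer` (one of "os_vector", "lcm_raster", "wlff_lines") and
#'   `target_fraction`; fractions per source must sum to <= 1. Controls the
#'   composition of the riparian strip. The percent-cover source is drawn
#'   uniformly and is not part of the mosaic.
#' @param gauge_count number of flow gauges (>= 2).
#' @param flow_law c(a, b) of the discharge scaling Q = a * Area^b
#'   (m^3/s per km^(2b)); both must be positive.
#' @param flow_sigma lognormal spread of daily flows around the scaling law.
#' @param n_days days of flow record per gauge.
#' @param occupancy_model list with `activity_logit` (length-5 logit of reach
#'   activity per BFI category, unsuitable..preferred) and `damming` (list
#'   count_intercept, count_slope, theta, zero_intercept, zero_slope) for the
#'   zero-inflated negative binomial dam process on active reaches.
#' @param seed integer RNG seed; identical seeds give bit-identical outputs.
#' @return a validated `catchment_scenario`.
#' @export
catchment_scenario <- function(grid_shape = c(64, 64),
                               cell_size = 5,
                               relief = 120,
                               drainage_style = c("dendritic_synthetic", "single_valley"),
                               n_tributaries = 3,
                               landcover_mosaic = default_mosaic(),
                               gauge_count = 4,
                               flow_law = c(a = 0.05, b = 0.8),
                               flow_sigma = 0.3,
                               n_days = 365,
                               occupancy_model = default_occupancy(),
                               seed = 1) {
  drainage_style <- match.arg(drainage_style)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 16L))
    stop("degenerate grid: grid_shape must be at least 16 x 16")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (gauge_count < 2L) stop("gauge_count must be at least 2")
  if (any(flow_law <= 0)) stop("flow_law parameters (a, b) must be positive")
  stopifnot(all(c("class_label", "source_layer", "target_fraction") %in%
                  names(landcover_mosaic)))
  fr <- tapply(landcover_mosaic$target_fraction, landcover_mosaic$source_layer, sum)
  if (any(fr > 1 + 1e-9)) stop("landcover_mosaic target_fractions per source must sum to <= 1")
  structure(list(grid_shape = grid_shape, cell_size = cell_size, relief = relief,
                 drainage_style = drainage_style, n_tributaries = n_tributaries,
                 landcover_mosaic = landcover_mosaic, gauge_count = gauge_count,
                 flow_law = flow_law, flow_sigma = flow_sigma, n_days = n_days,
                 occupancy_model = occupancy_model, seed = as.integer(seed)),
            class = "catchment_scenario")
}

#' Default riparian landcover mosaic
#' @return data.frame of (class_label, source_layer, target_fraction).
#' @export
default_mosaic <- function() {
  data.frame(
    class_label = c("Broad-leafed woodland", "Coniferous woodland", "Reeds",
                    "Unimproved grass", "Water",
                    "Improved grassland", "Arable and horticulture",
                    "Broadleaf woodland", "Coniferous woodland", "Heather",
                    "Woody linear feature"),
    source_layer = c(rep("os_vector", 5), rep("lcm_raster", 5), "wlff_lines"),
    target_fraction = c(0.20, 0.10, 0.10, 0.20, 0.05,
                        0.35, 0.25, 0.20, 0.10, 0.10,
                        0.05),
    stringsAsFactors = FALSE
  )
}

#' Default reach occupancy model
#'
#' Activity probabilities rise monotonically with BFI category (with the
#' three middle categories close together), and damming on active reaches
#' follows a zero-inflated negative binomial whose linear predictors use the
#' modelled maximum dams per reach.
#' @return list of truth parameters.
#' @export
default_occupancy <- function() {
  list(
    activity_logit = stats::qlogis(c(0.03, 0.30, 0.35, 0.40, 0.65)),
    damming = list(count_intercept = -0.8, count_slope = 0.5, theta = 1.2,
                   zero_intercept = 1.0, zero_slope = -0.8)
  )
}

## -- terrain + network ----------------------------------------------------

# channel skeleton: list of polylines (cell-centre vertices) with per-vertex
# distance-to-outlet; mapped channels and hidden headwater arms
.build_skeleton <- function(scn) {
  R <- scn$grid_shape[1]; C <- scn$grid_shape[2]; cs <- scn$cell_size
  cx <- function(col) (col - 0.5) * cs
  cy <- function(row) (R - row + 0.5) * cs
  r0 <- floor(R / 2)
  head_col <- floor(0.82 * C)
  stem <- cbind(cx(1:head_col), cy(rep(r0, head_col)))[head_col:1, , drop = FALSE]
  # stem runs head -> outlet in construction; store outlet-last
  channels <- list()
  junctions <- numeric(0)
  if (scn$drainage_style == "dendritic_synthetic" && scn$n_tributaries > 0) {
    nt <- scn$n_tributaries
    jcols <- round(seq(0.30, 0.62, length.out = nt) * C)
    side <- rep(c(-1, 1), length.out = nt)   # alternate north/south
    for (i in seq_len(nt)) {
      jc <- jcols[i]
      hr <- r0 + side[i] * round(0.30 * R)
      hc <- jc + round(0.12 * C)
      steps <- max(abs(hr - r0), abs(hc - jc))
      rows <- round(seq(hr, r0, length.out = steps + 1))
      cols <- round(seq(hc, jc, length.out = steps + 1))
      trib <- cbind(cx(cols), cy(rows))
      channels[[length(channels) + 1L]] <- trib
      junctions <- c(junctions, cx(jc))
    }
  }
  # split stem at junction x positions so the network is noded at confluences
  stem_out_to_head <- stem[nrow(stem):1, , drop = FALSE]  # outlet -> head
  jx <- sort(unique(junctions))
  segs <- list()
  if (length(jx)) {
    brk <- jx - stem_out_to_head[1, 1]  # distances along stem from outlet
    parts <- line_split(stem_out_to_head, brk)
    segs <- lapply(parts, function(p) p[nrow(p):1, , drop = FALSE]) # head->outlet dir
  } else segs <- list(stem)
  network <- c(segs, channels)
  # hidden headwater arms above every mapped head (incl. main stem head)
  heads <- lapply(c(list(stem[1, ]), lapply(channels, function(g) g[1, ])), identity)
  arms <- list()
  arm_len <- max(8L, round(0.12 * min(R, C)))
  for (h in heads) {
    hc0 <- round(h[1] / cs + 0.5); hr0 <- R - round(h[2] / cs - 0.5)
    for (s in c(-1, 1)) {
      rows <- hr0 + s * (0:arm_len)
      cols <- hc0 + (0:arm_len)
      ok <- rows >= 2 & rows <= R - 1 & cols >= 2 & cols <= C - 1
      if (sum(ok) >= 3) arms[[length(arms) + 1L]] <- cbind(cx(cols[ok]), cy(rows[ok]))[sum(ok):1, , drop = FALSE]
    }
  }
  list(network = network, arms = arms, outlet = stem[nrow(stem), ], r0 = r0,
       n_stem = length(segs))
}

# distance to the outlet along the tree, for each vertex of each skeleton line
.skeleton_points <- function(skel, cs) {
  # network distance: outlet at stem end; for each line, accumulate from its
  # downstream end, whose distance is found by matching coordinates
  all_lines <- c(skel$network, skel$arms)
  pts <- list(); dist <- list()
  # compute downstream-end network distance by walking: iterate until stable
  end_d <- rep(NA_real_, length(all_lines))
  starts <- t(vapply(all_lines, function(g) g[1, ], numeric(2)))      # upstream end
  ends <- t(vapply(all_lines, function(g) g[nrow(g), ], numeric(2)))  # downstream end
  lens <- vapply(all_lines, line_length, numeric(1))
  # a line's downstream end either is the outlet or touches another line
  repeat {
    changed <- FALSE
    for (i in seq_along(all_lines)) {
      if (!is.na(end_d[i])) next
      if (all(abs(ends[i, ] - skel$outlet) < 1e-6)) { end_d[i] <- 0; changed <- TRUE; next }
      for (j in seq_along(all_lines)) {
        if (i == j || is.na(end_d[j])) next
        # downstream end of i lies on line j: distance along j
        d <- dist_to_line(ends[i, , drop = FALSE], all_lines[[j]])
        if (d < 1e-6) {
          dj <- .dist_along(all_lines[[j]], ends[i, ])
          end_d[i] <- end_d[j] + lens[j] - dj
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  if (anyNA(end_d)) stop("disconnected skeleton line")  # construction guarantee
  for (i in seq_along(all_lines)) {
    g <- all_lines[[i]]
    p <- line_densify(g, cs / 2)
    # distance from downstream end along the line
    cum <- c(0, cumsum(seg_lengths(p)))
    d_out <- end_d[i] + (lens[i] - cum)
    pts[[i]] <- p; dist[[i]] <- d_out
  }
  list(xy = do.call(rbind, pts), d = unlist(dist), end_d = end_d, lens = lens)
}

# distance along line g (from its first vertex) of a point known to lie on it
.dist_along <- function(g, pt) {
  cum <- c(0, cumsum(seg_lengths(g)))
  best <- Inf; at <- 0
  for (i in seq_len(nrow(g) - 1L)) {
    d2 <- .dist2_seg(pt[1], pt[2], g[i, 1], g[i, 2], g[i + 1, 1], g[i + 1, 2])
    if (d2 < best) {
      best <- d2
      a <- g[i, ]; b <- g[i + 1, ]
      l2 <- sum((b - a)^2)
      t <- if (l2 == 0) 0 else min(max(sum((pt - a) * (b - a)) / l2, 0), 1)
      at <- cum[i] + t * sqrt(l2)
    }
  }
  at
}

#' Generate synthetic terrain, stream network and channel polygons
#'
#' @param scenario a `catchment_scenario`.
#' @return a `dc_catchment`: list with `dtm` (raster), `network`
#'   (`dc_features` of LineStrings, noded at confluences, digitised
#'   upstream-to-downstream), `channels` (`dc_features` of Polygons whose
#'   width grows downstream), `outlet` coordinates, and the generative
#'   skeleton (for tests).
#' @export
generate_terrain <- function(scenario) {
  stopifnot(inherits(scenario, "catchment_scenario"))
  scn <- scenario
  R <- scn$grid_shape[1]; C <- scn$grid_shape[2]; cs <- scn$cell_size
  skel <- .build_skeleton(scn)
  sp <- .skeleton_points(skel, cs)
  dmax <- max(sp$d)
  g_ch <- (0.35 * scn$relief) / dmax          # channel gradient
  # lateral distances from every cell centre to the skeleton
  nrc <- R * C
  X <- matrix((rep(seq_len(C), each = R) - 0.5) * cs, R, C)
  Y <- matrix((R - rep(seq_len(R), C) + 0.5) * cs, R, C)
  xv <- as.vector(X); yv <- as.vector(Y)
  best2 <- rep(Inf, nrc); zch <- rep(0, nrc)
  zpt <- g_ch * sp$d
  for (i in seq_len(nrow(sp$xy))) {
    d2 <- (xv - sp$xy[i, 1])^2 + (yv - sp$xy[i, 2])^2
    upd <- d2 < best2
    best2[upd] <- d2[upd]; zch[upd] <- zpt[i]
  }
  lat <- sqrt(best2)
  g_lat <- (0.65 * scn$relief) / max(lat)
  z <- zch + g_lat * lat
  noise <- with_seed(scn$seed, stats::runif(nrc, -1, 1)) * 0.1 * g_lat * cs
  on_skel <- lat <= cs / 2
  noise[on_skel] <- 0
  z <- z + noise
  # raise a rim on boundary cells (except near the outlet) so the whole grid
  # drains through the outlet
  zm <- matrix(z, R, C)
  rim <- 2 * g_lat * cs
  bmask <- matrix(FALSE, R, C)
  bmask[1, ] <- bmask[R, ] <- TRUE; bmask[, 1] <- bmask[, C] <- TRUE
  orc <- raster_rowcol(dc_raster(zm, 0, 0, cs), skel$outlet[1], skel$outlet[2])
  bmask[orc[1, 1], orc[1, 2]] <- FALSE
  zm[bmask] <- zm[bmask] + rim
  dtm <- dc_raster(zm, xll = 0, yll = 0, cellsize = cs)
  net <- dc_features(skel$network, "LineString",
                     id = sprintf("N%02d", seq_along(skel$network)))
  # channel polygons: width grows downstream (shrinking distance to outlet)
  sp_net <- sp  # includes arms at tail; network lines come first
  w_head <- 1; w_out <- 6
  polys <- vector("list", length(skel$network))
  for (i in seq_along(skel$network)) {
    g <- skel$network[[i]]
    cum <- c(0, cumsum(seg_lengths(g)))
    d_out <- sp$end_d[i] + (sp$lens[i] - cum)
    w <- w_out - (w_out - w_head) * d_out / dmax
    polys[[i]] <- line_buffer_ring(g, w / 2)
  }
  channels <- dc_features(polys, "Polygon", id = net$id)
  structure(list(dtm = dtm, network = net, channels = channels,
                 outlet = skel$outlet, skeleton = skel, scenario = scn),
            class = "dc_catchment")
}

#' @export
print.dc_catchment <- function(x, ...) {
  cat(sprintf("<dc_catchment %dx%d @ %gm, %d network features, %.0f m of channel>\n",
              raster_nrow(x$dtm), raster_ncol(x$dtm), x$dtm$cellsize,
              nrow(x$network), sum(vapply(x$network$geometry, line_length, numeric(1)))))
  invisible(x)
}

## -- landcover ------------------------------------------------------------

# deterministic proportional class allocation with a seeded shuffle
.allocate_classes <- function(n, labels, fractions) {
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_part <- fractions * n - counts
    extra <- order(frac_part, decreasing = TRUE)[seq_len(min(rem, length(labels)))]
    counts[extra] <- counts[extra] + 1
    rem <- n - sum(counts)
  }
  out <- c(rep(labels, counts), rep(NA_character_, max(rem, 0)))
  sample(out)
}

#' Generate the four synthetic landcover sources
#'
#' Emulates a high-resolution categorical vector layer (the priority source),
#' a woody-linear-features vector layer, a categorical landcover raster and a
#' percent tree-cover-density raster. Riparian strips (within 60 m of the
#' network) receive classes in the scenario's mosaic proportions.
#' @param scenario the `catchment_scenario`.
#' @param catchment output of [generate_terrain()].
#' @return named list with elements `os_vector`, `wlff_lines`
#'   (`dc_features`), `lcm_raster`, `tcd_percent` (`dc_raster` at 10 m and
#'   20 m respectively). Categorical rasters carry a `levels` attribute
#'   mapping cell codes to class labels.
#' @export
generate_landcover <- function(scenario, catchment) {
  scn <- scenario
  known <- unlist(lapply(default_suitability(), function(t) names(t$classes)))
  bad <- setdiff(scn$landcover_mosaic$class_label, known)
  if (length(bad)) stop("unknown class label(s) in mosaic: ", paste(bad, collapse = ", "))
  cs <- scn$cell_size
  ext <- c(0, 0, scn$grid_shape[2] * cs, scn$grid_shape[1] * cs)
  lines <- catchment$network$geometry
  mosaic <- function(src) {
    m <- scn$landcover_mosaic[scn$landcover_mosaic$source_layer == src, , drop = FALSE]
    m[m$target_fraction > 0, , drop = FALSE]
  }
  with_seed(scn$seed + 101L, {
    ## priority vector source: 20 m tiles in the riparian strip
    os <- mosaic("os_vector")
    tile <- 20
    txs <- seq(ext[1], ext[3] - tile, by = tile)
    tys <- seq(ext[2], ext[4] - tile, by = tile)
    cent <- cbind(rep(txs, each = length(tys)) + tile / 2, rep(tys, length(txs)) + tile / 2)
    near <- dist_to_lines(cent, lines)$dist <= 60
    cent <- cent[near, , drop = FALSE]
    cls <- if (nrow(os)) .allocate_classes(nrow(cent), os$class_label, os$target_fraction)
           else rep(NA_character_, nrow(cent))
    keep <- !is.na(cls)
    tiles <- lapply(which(keep), function(i) {
      x0 <- cent[i, 1] - tile / 2; y0 <- cent[i, 2] - tile / 2
      cbind(c(x0, x0 + tile, x0 + tile, x0, x0), c(y0, y0, y0 + tile, y0 + tile, y0))
    })
    os_vector <- dc_features(tiles, "Polygon", class = cls[keep])

    ## woody linear features: hedgerow segments near the network
    wl <- mosaic("wlff_lines")
    n_hedge <- if (nrow(wl)) max(1L, round(sum(wl$target_fraction) * nrow(cent) / 2)) else 0L
    wlff_lines <- if (n_hedge > 0L) {
      at <- cent[sample(nrow(cent), min(n_hedge, nrow(cent))), , drop = FALSE]
      segs <- lapply(seq_len(nrow(at)), function(i)
        cbind(c(at[i, 1] - 15, at[i, 1] + 15), c(at[i, 2], at[i, 2])))
      dc_features(segs, "LineString",
                  class = rep(wl$class_label[1], length(segs)))
    } else dc_features(list(), "LineString")

    ## categorical raster at 10 m: blocky classes, riparian strip follows the
    ## mosaic proportions, remainder reshuffled from the same pool
    lc <- mosaic("lcm_raster")
    lcm <- raster_template(ext[1], ext[2], ext[3], ext[4], cellsize = 10)
    xy <- raster_xy(lcm)
    block <- 3L  # 30 m blocks
    brow <- (row(lcm$values) - 1L) %/% block
    bcol <- (col(lcm$values) - 1L) %/% block
    bid <- brow * (max(bcol) + 1L) + bcol + 1L
    ub <- sort(unique(as.vector(bid)))
    # block centres -> riparian or not
    bx <- tapply(as.vector(xy$x), as.vector(bid), mean)
    by <- tapply(as.vector(xy$y), as.vector(bid), mean)
    bnear <- dist_to_lines(cbind(bx, by), lines)$dist <= 60
    labs <- lc$class_label; frs <- lc$target_fraction / max(sum(lc$target_fraction), 1)
    assign_block <- rep(NA_character_, length(ub))
    assign_block[bnear] <- .allocate_classes(sum(bnear), labs, frs)
    assign_block[!bnear] <- .allocate_classes(sum(!bnear), labs, frs)
    assign_block[is.na(assign_block)] <- labs[which.max(frs)]
    lev <- labs
    codes <- match(assign_block, lev)
    lcm$values[] <- codes[match(as.vector(bid), ub)]
    attr(lcm, "levels") <- lev

    ## percent tree-cover raster at 20 m: blockwise uniform(0, 100)
    tcd <- raster_template(ext[1], ext[2], ext[3], ext[4], cellsize = 20)
    tcd$values[] <- stats::runif(length(tcd$values), 0, 100)

    list(os_vector = os_vector, wlff_lines = wlff_lines,
         lcm_raster = lcm, tcd_percent = tcd)
  })
}

## -- gauge flows ----------------------------------------------------------

#' Generate daily gauge flow records
#'
#' Places gauges on the network, takes each gauge's contributing area from
#' the D8 flow-accumulation grid, and draws daily mean flows lognormally
#' around the scenario's scaling law Q = a * Area^b (sigma = 0 gives exact,
#' noiseless records).
#' @param scenario the `catchment_scenario`.
#' @param catchment output of [generate_terrain()].
#' @param fg optional precomputed `dc_flowgrid` (burned + routed); computed
#'   from the catchment when missing.
#' @return list with `flows` (data.frame date, flow_m3s, gauge_id),
#'   `gauges` (data.frame gauge_id, area_km2, x, y).
#' @export
generate_flows <- function(scenario, catchment, fg = NULL) {
  scn <- scenario
  if (scn$gauge_count < 2L) stop("at least two gauges are required")
  if (is.null(fg)) fg <- flow_accumulation(burn_dtm(catchment$dtm, catchment$network))
  # gauges spaced along the main stem (the first skeleton features, each
  # digitised head -> outlet)
  mains <- catchment$skeleton$network[seq_len(catchment$skeleton$n_stem)]
  full <- do.call(rbind, rev(mains))
  L <- line_length(full)
  at <- line_interpolate(full, seq(0.1, 0.9, length.out = scn$gauge_count) * L)
  area <- raster_extract(fg$acc, at[, 1], at[, 2]) * (fg$acc$cellsize^2) / 1e6
  gauges <- data.frame(gauge_id = sprintf("G%02d", seq_len(scn$gauge_count)),
                       area_km2 = area, x = at[, 1], y = at[, 2],
                       stringsAsFactors = FALSE)
  a <- scn$flow_law[[1]]; b <- scn$flow_law[[2]]
  dates <- as.Date("2017-01-01") + seq_len(scn$n_days) - 1L
  flows <- with_seed(scn$seed + 202L, {
    do.call(rbind, lapply(seq_len(nrow(gauges)), function(i) {
      mu <- a * gauges$area_km2[i]^b
      q <- mu * exp(stats::rnorm(scn$n_days, 0, scn$flow_sigma))
      data.frame(date = dates, flow_m3s = q, gauge_id = gauges$gauge_id[i],
                 stringsAsFactors = FALSE)
    }))
  })
  list(flows = flows, gauges = gauges)
}

## -- observations ---------------------------------------------------------

#' Simulate dam counts from a zero-inflated negative binomial truth
#'
#' @param x covariate (modelled maximum dams per reach).
#' @param pars list(count_intercept, count_slope, theta, zero_intercept,
#'   zero_slope).
#' @return integer counts.
#' @export
simulate_dam_counts <- function(x, pars) {
  pi0 <- stats::plogis(pars$zero_intercept + pars$zero_slope * x)
  mu <- exp(pars$count_intercept + pars$count_slope * x)
  zero <- stats::rbinom(length(x), 1, pi0) == 1
  y <- stats::rnbinom(length(x), mu = mu, size = pars$theta)
  y[zero] <- 0L
  y
}

#' Simulate beaver field observations on reaches
#'
#' Activity per reach follows a logistic model on the BFI category; dams on
#' active reaches follow the scenario's zero-inflated negative binomial with
#' the modelled maximum dams per reach as covariate. Points are placed on the
#' reach geometry. The generative truth is attached as an attribute (single
#' source of truth for recovery tests) and can be serialised alongside the
#' points.
#' @param scenario the `catchment_scenario`.
#' @param reaches data.frame with list-column `geometry` and columns
#'   `bfi_category` (factor/character: unsuitable, low, medium, high,
#'   preferred) and `max_dams`.
#' @return `dc_features` point layer with column `kind` ("feeding_sign" or
#'   "dam"); attribute `truth` holds the generative parameters and the
#'   per-reach simulated activity/dam counts.
#' @export
simulate_observations <- function(scenario, reaches) {
  scn <- scenario
  stopifnot(all(c("bfi_category", "max_dams") %in% names(reaches)))
  lev <- c("unsuitable", "low", "medium", "high", "preferred")
  ci <- match(as.character(reaches$bfi_category), lev)
  if (anyNA(ci)) stop("bfi_category must be one of: ", paste(lev, collapse = ", "))
  om <- scn$occupancy_model
  with_seed(scn$seed + 303L, {
    p_act <- stats::plogis(om$activity_logit[ci])
    active <- stats::rbinom(nrow(reaches), 1, p_act) == 1
    dams <- integer(nrow(reaches))
    dams[active] <- simulate_dam_counts(reaches$max_dams[active], om$damming)
    pts <- list(); kind <- character(0); parent <- character(0)
    for (i in which(active)) {
      g <- reaches$geometry[[i]]
      L <- line_length(g)
      nf <- 1L + stats::rpois(1, 1)
      fpos <- line_interpolate(g, stats::runif(nf, 0, L))
      for (k in seq_len(nf)) { pts[[length(pts) + 1L]] <- fpos[k, , drop = FALSE] }
      kind <- c(kind, rep("feeding_sign", nf))
      parent <- c(parent, rep(as.character(reaches$reach_id[i]), nf))
      if (dams[i] > 0) {
        dpos <- line_interpolate(g, stats::runif(dams[i], 0, L))
        for (k in seq_len(dams[i])) pts[[length(pts) + 1L]] <- dpos[k, , drop = FALSE]
        kind <- c(kind, rep("dam", dams[i]))
        parent <- c(parent, rep(as.character(reaches$reach_id[i]), dams[i]))
      }
    }
    obs <- if (length(pts)) dc_features(pts, "Point", kind = kind, true_reach = parent)
           else dc_features(list(), "Point")
    attr(obs, "truth") <- list(occupancy = om,
                               is_active = active, dams = dams,
                               reach_id = reaches$reach_id)
    obs
  })
}

#' Serialise generator truth parameters as JSON
#' @param obs observation layer from [simulate_observations()].
#' @param path output JSON file.
#' @export
write_truth <- function(obs, path) {
  tr <- attr(obs, "truth")
  jsonlite::write_json(list(occupancy = tr$occupancy,
                            n_active = sum(tr$is_active),
                            n_dams = sum(tr$dams)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
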