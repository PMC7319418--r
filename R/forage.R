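# Beaver Forage Index (BFI).
#
# Landcover sources are reclassified to 0-5 foraging suitability, rasterised
# and aligned on a common 5 m grid, and composited: one source is the
# priority layer (used wherever it has data); elsewhere the highest value of
# the coincident remaining sources is used; cells with no data in any source
# score 0 ("no vegetation") so the index is defined catchment-wide.

#' Read suitability tables from YAML
#' @param path YAML file mapping source layers to class suitability values.
#' @return named list of suitability tables. Each table has `source_id`,
#'   `type` ("categorical" or "percent"), and `classes` (named integer
#'   vector) or `bands` (data.frame low, high, value); optional `default`.
#' @export
read_suitability <- function(path) {
  y <- yaml::read_yaml(path)
  out <- lapply(y, function(t) {
    t$type <- match.arg(t$type, c("categorical", "percent"))
    if (t$type == "categorical") {
      t$classes <- unlist(t$classes)
      if (any(!t$classes %in% 0:5)) stop("suitability values must be integers 0-5")
    } else {
      t$bands <- as.data.frame(do.call(rbind, t$bands))
      names(t$bands) <- c("low", "high", "value")
      if (is.unsorted(t$bands$low) || any(t$bands$high[-nrow(t$bands)] > t$bands$low[-1]))
        stop("percent bands must be ordered and non-overlapping")
    }
    t
  })
  names(out) <- vapply(out, `[[`, "", "source_id")
  out
}

.suit_cache <- new.env(parent = emptyenv())

#' Default suitability tables
#'
#' Shipped tables cover the published headline classes for the four emulated
#' sources (high-resolution categorical vector, categorical landcover raster,
#' percent tree-cover raster, woody linear features); the YAML file is
#' user-extensible for fuller national class lists.
#' @return named list of suitability tables.
#' @export
default_suitability <- function() {
  if (is.null(.suit_cache$tables)) {
    path <- system.file("extdata", "bfi_suitability.yaml", package = "damcap",
                        mustWork = TRUE)
    .suit_cache$tables <- read_suitability(path)
  }
  .suit_cache$tables
}

#' Reclassify a landcover source to suitability values
#'
#' Value-for-value substitution; geometry is unchanged. Vector layers gain a
#' `suit` column; categorical rasters are mapped via their `levels`
#' attribute; percent rasters are banded (values outside all bands become
#' nodata).
#' @param layer `dc_features` (with a `class` column) or `dc_raster`.
#' @param table one suitability table (see [read_suitability()]).
#' @return layer of the same geometry type carrying suitability 0-5.
#' @export
reclassify_source <- function(layer, table) {
  if (table$type == "percent") {
    stopifnot(inherits(layer, "dc_raster"))
    v <- layer$values
    out <- matrix(NA_real_, nrow(v), ncol(v))
    for (i in seq_len(nrow(table$bands))) {
      b <- table$bands[i, ]
      sel <- !is.na(v) & v >= b$low & v <= b$high
      out[sel] <- b$value
    }
    r <- layer; r$values <- out; attr(r, "levels") <- NULL
    return(r)
  }
  map <- table$classes
  if (inherits(layer, "dc_raster")) {
    lev <- attr(layer, "levels")
    if (is.null(lev)) stop("categorical raster needs a 'levels' attribute")
    labs <- lev[layer$values]
    miss <- setdiff(unique(labs[!is.na(labs)]), names(map))
    if (length(miss) && is.null(table$default))
      stop("unmapped class(es) without default: ", paste(miss, collapse = ", "))
    suit <- unname(map[labs])
    if (length(miss)) suit[labs %in% miss] <- table$default
    r <- layer
    r$values <- matrix(as.numeric(suit), nrow(layer$values), ncol(layer$values))
    attr(r, "levels") <- NULL
    return(r)
  }
  stopifnot(inherits(layer, "dc_features"), "class" %in% names(layer))
  miss <- setdiff(unique(layer$class), names(map))
  if (length(miss) && is.null(table$default))
    stop("unmapped class(es) without default: ", paste(miss, collapse = ", "))
  suit <- unname(map[layer$class])
  if (length(miss)) suit[layer$class %in% miss] <- table$default
  layer$suit <- as.numeric(suit)
  layer
}

#' Rasterise and align suitability layers on a common 5 m grid
#'
#' Vector polygons burn their value into cells whose centre they cover;
#' lines into cells whose centre lies within half a cell of the line;
#' rasters are resampled by nearest neighbour (classes are preserved, never
#' interpolated). All outputs share one origin, extent and cell size.
#' @param layers list of reclassified layers (`dc_features` with `suit`, or
#'   suitability `dc_raster`s).
#' @param cellsize target cell size (default 5 m).
#' @param extent optional c(xmin, ymin, xmax, ymax); defaults to the union
#'   of layer extents. Layers that do not overlap the union are rejected as
#'   being in a different coordinate frame.
#' @return list of aligned `dc_raster`s (same order as `layers`).
#' @export
rasterize_and_align <- function(layers, cellsize = 5, extent = NULL) {
  if (!length(layers)) stop("empty layer list")
  ext_of <- function(l) {
    if (inherits(l, "dc_raster"))
      c(l$xll, l$yll, l$xll + raster_ncol(l) * l$cellsize,
        l$yll + raster_nrow(l) * l$cellsize)
    else if (nrow(l)) bbox_of(l$geometry) else rep(NA_real_, 4)
  }
  exts <- lapply(layers, ext_of)
  have <- !vapply(exts, anyNA, logical(1))
  if (is.null(extent)) {
    em <- do.call(rbind, exts[have])
    extent <- c(min(em[, 1]), min(em[, 2]), max(em[, 3]), max(em[, 4]))
  }
  for (e in exts[have]) {
    if (e[3] < extent[1] || e[1] > extent[3] || e[4] < extent[2] || e[2] > extent[4])
      stop("layer does not overlap the target extent; mismatched coordinate frames?")
  }
  template <- raster_template(extent[1], extent[2], extent[3], extent[4], cellsize)
  xy <- raster_xy(template)
  lapply(layers, function(l) {
    if (inherits(l, "dc_raster")) return(raster_resample_nn(l, template))
    out <- template
    if (!nrow(l)) return(out)
    if (geom_type(l) == "Polygon") {
      for (i in seq_len(nrow(l))) {
        g <- l$geometry[[i]]
        bb <- bbox_of(list(g))
        cand <- which(xy$x >= bb[1] - cellsize & xy$x <= bb[3] + cellsize &
                        xy$y >= bb[2] - cellsize & xy$y <= bb[4] + cellsize)
        if (!length(cand)) next
        inside <- point_in_polygon(xy$x[cand], xy$y[cand], g)
        out$values[cand[inside]] <- l$suit[i]
      }
    } else if (geom_type(l) == "LineString") {
      for (i in seq_len(nrow(l))) {
        m <- rasterize_lines_mask(template, list(l$geometry[[i]]))
        out$values[m] <- l$suit[i]
      }
    } else stop("point layers cannot be rasterised to suitability")
    out
  })
}

#' Composite aligned suitability grids into the forage index
#'
#' The priority grid's value is used wherever it has data; elsewhere the
#' maximum of the remaining coincident grids; cells with no data anywhere
#' score 0.
#' @param grids list of aligned suitability `dc_raster`s.
#' @param priority index of the priority grid within `grids` (default 1).
#' @return the composite BFI `dc_raster` (integer values 0-5).
#' @export
composite_bfi <- function(grids, priority = 1) {
  if (!length(grids)) stop("empty grid list")
  for (g in grids[-1]) if (!same_grid(g, grids[[1]]))
    stop("grids are not aligned; run rasterize_and_align() first")
  base <- grids[[priority]]$values
  rest <- grids[-priority]
  if (length(rest)) {
    mx <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE),
                 lapply(rest, `[[`, "values"))
    base[is.na(base)] <- mx[is.na(base)]
  }
  base[is.na(base)] <- 0
  out <- grids[[1]]
  out$values <- base
  attr(out, "levels") <- NULL
  out
}

## -- reach extraction -------------------------------------------------------

# extend a reach path `dist` metres along the network beyond each end;
# truncated at headwaters/outlet; at confluences the continuation with the
# lowest feature index is taken (deterministic tie-break)
.extend_path <- function(i, geoms, dist, tol = 1e-6) {
  g <- geoms[[i]]
  match_pt <- function(pt, ends) which(abs(ends[, 1] - pt[1]) < tol &
                                         abs(ends[, 2] - pt[2]) < tol)
  starts <- t(vapply(geoms, function(x) x[1, ], numeric(2)))
  ends <- t(vapply(geoms, function(x) x[nrow(x), ], numeric(2)))
  # upstream: other reaches whose END meets our START
  up <- g
  need <- dist; cur <- i
  repeat {
    cand <- setdiff(match_pt(up[1, ], ends), cur)
    if (!length(cand) || need <= 0) break
    j <- min(cand)
    gj <- geoms[[j]]
    L <- line_length(gj)
    take <- min(need, L)
    part <- line_split(gj, if (take < L) L - take else numeric(0))
    seg <- part[[length(part)]]
    up <- rbind(seg[-nrow(seg), , drop = FALSE], up)
    need <- need - take
    cur <- c(cur, j)
    if (take < L) break
  }
  # downstream: other reaches whose START meets our END
  need <- dist
  repeat {
    cand <- setdiff(match_pt(up[nrow(up), ], starts), cur)
    if (!length(cand) || need <= 0) break
    j <- min(cand)
    gj <- geoms[[j]]
    L <- line_length(gj)
    take <- min(need, L)
    part <- line_split(gj, if (take < L) take else numeric(0))
    seg <- part[[1]]
    up <- rbind(up, seg[-1, , drop = FALSE])
    need <- need - take
    cur <- c(cur, j)
    if (take < L) break
  }
  up
}

#' Reach-scale forage statistics
#'
#' For each reach the search area is the reach path extended 100 m up- and
#' downstream along the network (truncated at headwaters and the outlet),
#' buffered by the channel half-width plus the search distance. The
#' statistic is the mean of the top 50% of BFI cell values whose centres
#' fall inside (ceiling(k/2) cells of k, so single-cell samples are
#' defined); an empty sample scores 0 with a warning.
#' @param reaches `dc_features` of reach polylines (digitised upstream to
#'   downstream).
#' @param bfi the composite BFI `dc_raster`.
#' @param distance search distance from the bank: 10 (streamside) or 40
#'   (riparian) metres.
#' @param width_m per-reach channel width (metres); defaults to 0.
#' @param extend along-network extension (default 100 m).
#' @return numeric vector: per-reach mean of the top half of sampled values.
#' @export
extract_reach_forage <- function(reaches, bfi, distance, width_m = 0,
                                 extend = 100) {
  geoms <- reaches$geometry
  width_m <- rep_len(width_m, length(geoms))
  xy <- raster_xy(bfi)
  xv <- as.vector(xy$x); yv <- as.vector(xy$y); vals <- as.vector(bfi$values)
  out <- numeric(length(geoms))
  for (i in seq_along(geoms)) {
    path <- .extend_path(i, geoms, extend)
    r <- width_m[i] / 2 + distance
    bb <- bbox_of(list(path))
    cand <- which(xv >= bb[1] - r & xv <= bb[3] + r &
                    yv >= bb[2] - r & yv <= bb[4] + r & !is.na(vals))
    if (length(cand)) {
      d <- dist_to_line(cbind(xv[cand], yv[cand]), path)
      s <- vals[cand[d <= r]]
    } else s <- numeric(0)
    if (!length(s)) {
      warning("empty forage sample for reach ", i, "; scoring 0")
      out[i] <- 0
    } else {
      out[i] <- top_half_mean(s)
    }
  }
  out
}

#' Mean of the top half of a sample
#'
#' With k values the top ceiling(k/2) are averaged.
#' @param x numeric sample.
#' @return mean of the top half.
#' @export
top_half_mean <- function(x) {
  k <- ceiling(length(x) / 2)
  mean(sort(x, decreasing = TRUE)[seq_len(k)])
}

#' BFI category of a riparian forage value
#'
#' unsuitable (<= 1), low (<= 2), medium (<= 3), high (<= 4),
#' preferred (<= 5).
#' @param riparian_bfi value in [0, 5].
#' @return ordered factor of categories.
#' @export
classify_bfi_category <- function(riparian_bfi) {
  if (any(riparian_bfi < 0 | riparian_bfi > 5, na.rm = TRUE))
    stop("BFI values out of range [0, 5]")
  cut(riparian_bfi, breaks = c(-Inf, 1, 2, 3, 4, 5),
      labels = c("unsuitable", "low", "medium", "high", "preferred"),
      right = TRUE, ordered_result = TRUE)
}
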