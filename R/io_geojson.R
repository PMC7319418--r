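# GeoJSON persistence for feature layers (RFC 7946, planar coordinates).

#' Write a feature layer to GeoJSON
#' @param feats a `dc_features` layer.
#' @param path output file.
#' @export
write_geojson <- function(feats, path) {
  type <- geom_type(feats)
  props <- feats[setdiff(names(feats), "geometry")]
  features <- lapply(seq_len(nrow(feats)), function(i) {
    g <- feats$geometry[[i]]
    coords <- switch(type,
      Point = as.numeric(g[1, ]),
      LineString = unname(apply(g, 1, as.numeric, simplify = FALSE)),
      Polygon = list(unname(apply(close_ring(g), 1, as.numeric, simplify = FALSE)))
    )
    p <- lapply(props, function(col) col[i])
    list(type = "Feature",
         properties = if (length(p)) p else structure(list(), names = character()),
         geometry = list(type = type, coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

close_ring <- function(g) {
  if (!all(g[1, ] == g[nrow(g), ])) g <- rbind(g, g[1, ])
  g
}

#' Read a GeoJSON feature collection
#' @param path file path.
#' @return a `dc_features` layer (single geometry type per file).
#' @export
read_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  feats <- j$features
  if (!length(feats)) stop("empty feature collection: ", path)
  type <- feats[[1]]$geometry$type
  geometry <- lapply(feats, function(f) {
    cc <- f$geometry$coordinates
    switch(f$geometry$type,
      Point = matrix(unlist(cc), ncol = 2),
      LineString = do.call(rbind, lapply(cc, unlist)),
      Polygon = do.call(rbind, lapply(cc[[1]], unlist)),
      stop("unsupported geometry type: ", f$geometry$type))
  })
  keys <- unique(unlist(lapply(feats, function(f) names(f$properties))))
  args <- list(geometry = geometry, geom_type = type)
  for (k in keys) {
    args[[k]] <- unlist(lapply(feats, function(f) {
      v <- f$properties[[k]]
      if (is.null(v)) NA else v
    }))
  }
  do.call(dc_features, args)
}
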