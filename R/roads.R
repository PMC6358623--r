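#' Classed road network
#'
#' A set of polyline features, each tagged with a road class
#' (`"national"` or `"provincial"`). Coordinates are meters in a projected
#' CRS shared with all rasters and sign points.
#'
#' @param features list of features; each a list with `coords` (two-column
#'   numeric matrix of vertices, in meters) and `road_class`.
#' @param crs free-text identifier of the metric CRS (bookkeeping only).
#' @return an object of class `rz_roads`.
#' @export
rz_roads <- function(features, crs = "local-metric") {
  stopifnot(length(features) > 0)
  for (f in features) {
    if (!is.matrix(f$coords) || ncol(f$coords) != 2 || nrow(f$coords) < 2)
      stop("each road feature needs a >= 2 vertex two-column coordinate matrix")
    if (!f$road_class %in% c("national", "provincial"))
      stop("road_class must be 'national' or 'provincial', got: ", f$road_class)
  }
  structure(list(features = features, crs = crs), class = "rz_roads")
}

#' @export
print.rz_roads <- function(x, ...) {
  cls <- vapply(x$features, function(f) f$road_class, character(1))
  cat(sprintf("<rz_roads> %d features (%d national, %d provincial), crs=%s\n",
              length(cls), sum(cls == "national"), sum(cls == "provincial"),
              x$crs))
  invisible(x)
}

#' Segments of all roads of one class
#'
#' @param roads an `rz_roads`.
#' @param road_class `"national"` or `"provincial"`.
#' @return four-column matrix (x1, y1, x2, y2), one row per segment; errors
#'   if the class has no features.
#' @export
road_segments <- function(roads, road_class) {
  keep <- Filter(function(f) f$road_class == road_class, roads$features)
  if (length(keep) == 0)
    stop("no roads of class '", road_class, "' in the network")
  segs <- lapply(keep, function(f) {
    v <- f$coords
    cbind(v[-nrow(v), 1], v[-nrow(v), 2], v[-1, 1], v[-1, 2])
  })
  do.call(rbind, segs)
}

#' Planar distance from points to a set of line segments
#'
#' Exact point-to-segment distance, minimized over all segments. Vectorized
#' over points; loops over segments (segment counts are small).
#'
#' @param x,y point coordinates (m).
#' @param segs four-column segment matrix as from [road_segments()].
#' @return numeric vector of distances (m).
#' @export
dist_to_segments <- function(x, y, segs) {
  d2 <- rep(Inf, length(x))
  for (k in seq_len(nrow(segs))) {
    x1 <- segs[k, 1]; y1 <- segs[k, 2]
    dx <- segs[k, 3] - x1; dy <- segs[k, 4] - y1
    L2 <- dx * dx + dy * dy
    if (L2 == 0) {
      px <- x - x1; py <- y - y1
    } else {
      t <- ((x - x1) * dx + (y - y1) * dy) / L2
      t <- pmin(pmax(t, 0), 1)
      px <- x - (x1 + t * dx); py <- y - (y1 + t * dy)
    }
    d2 <- pmin(d2, px * px + py * py)
  }
  sqrt(d2)
}

#' Distance-to-road raster for one road class
#'
#' @param roads an `rz_roads`.
#' @param road_class road class to measure distance to.
#' @param template an `rz_raster` supplying the grid.
#' @return an `rz_raster` of distances (m) on the template grid.
#' @export
distance_raster <- function(roads, road_class, template) {
  segs <- road_segments(roads, road_class)
  xy <- raster_coords(template)
  d <- dist_to_segments(xy[, 1], xy[, 2], segs)
  rz_raster(matrix(d, nrow = template$nrow), xmin = template$xmin,
            ymin = template$ymin, cellsize = template$cellsize)
}

#' Axis-aligned rectangular study area
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds (m).
#' @return object of class `rz_study_area`.
#' @export
study_area_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  structure(list(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax),
            class = "rz_study_area")
}

#' Test whether points fall inside the study area
#'
#' @param area an `rz_study_area`.
#' @param x,y point coordinates (m).
#' @param inset shrink the rectangle inward by this many meters before
#'   testing (used to guarantee whole cells fit inside).
#' @return logical vector.
#' @export
area_contains <- function(area, x, y, inset = 0) {
  x >= area$xmin + inset & x <= area$xmax - inset &
    y >= area$ymin + inset & y <= area$ymax - inset
}

#' Write roads (and optionally the study area) as GeoJSON
#'
#' @param roads an `rz_roads`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roads_geojson <- function(roads, path) {
  feats <- lapply(roads$features, function(f) {
    list(type = "Feature",
         properties = list(road_class = f$road_class),
         geometry = list(type = "LineString",
                         coordinates = unname(apply(f$coords, 1, as.list,
                                                    simplify = FALSE))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roads_geojson
#' @export
read_roads_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  feats <- lapply(fc$features, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(p) c(p[[1]], p[[2]])))
    list(coords = coords, road_class = f$properties$road_class)
  })
  rz_roads(feats)
}
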