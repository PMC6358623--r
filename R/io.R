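#' Write a landscape bundle to plain-text files
#'
#' Rasters go to ESRI ASCII grids, roads and the study area to GeoJSON,
#' signs to CSV (x, y, id) and GeoJSON points, and the ground-truth
#' generator parameters to a JSON sidecar. [read_landscape()] restores a
#' bundle written this way (distance rasters are recomputed on demand).
#'
#' @param bundle an `rz_landscape`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("elevation", "forest", "construction", "water",
               "population")) {
    write_ascii_grid(bundle[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  if (!is.null(bundle$roads))
    write_roads_geojson(bundle$roads, file.path(dir, "roads.geojson"))
  utils::write.csv(bundle$signs, file.path(dir, "signs.csv"),
                   row.names = FALSE)
  write_signs_geojson(bundle$signs, file.path(dir, "signs.geojson"))
  sa <- bundle$study_area
  jsonlite::write_json(
    list(type = "Feature", properties = list(role = "study_area"),
         geometry = list(type = "Polygon", coordinates = list(list(
           c(sa$xmin, sa$ymin), c(sa$xmax, sa$ymin), c(sa$xmax, sa$ymax),
           c(sa$xmin, sa$ymax), c(sa$xmin, sa$ymin))))),
    file.path(dir, "study_area.geojson"), auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$truth))
    jsonlite::write_json(unclass(bundle$truth),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  rasters <- lapply(stats::setNames(nm = c("elevation", "forest",
                                           "construction", "water",
                                           "population")),
                    function(nm) read_ascii_grid(
                      file.path(dir, paste0(nm, ".asc"))))
  tmpl <- rasters$elevation
  roads_path <- file.path(dir, "roads.geojson")
  roads <- if (file.exists(roads_path)) read_roads_geojson(roads_path) else
    NULL
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    class(tr) <- "rz_landscape_params"
    tr
  } else NULL
  structure(c(
    list(study_area = study_area_rect(
      tmpl$xmin, tmpl$ymin,
      tmpl$xmin + tmpl$ncol * tmpl$cellsize,
      tmpl$ymin + tmpl$nrow * tmpl$cellsize),
      roads = roads),
    rasters,
    list(dist = list(national = NULL, provincial = NULL),
         signs = utils::read.csv(file.path(dir, "signs.csv")),
         truth = truth)
  ), class = "rz_landscape")
}

#' Write sign points as GeoJSON
#'
#' @param signs data.frame with `x`, `y`, `id`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signs_geojson <- function(signs, path) {
  feats <- lapply(seq_len(nrow(signs)), function(i) {
    list(type = "Feature", properties = list(id = signs$id[i]),
         geometry = list(type = "Point",
                         coordinates = c(signs$x[i], signs$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
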