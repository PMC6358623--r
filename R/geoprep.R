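#' Ring-buffer distance schedule
#'
#' Contiguous half-open distance rings `(inner, outer]` covering
#' `(0, max_m]`: a fine step up to `fine_limit_m`, a coarse step beyond.
#' The default reproduces the 25-ring schedule used for major-road analyses
#' (every 500 m to 5000 m, every 1000 m to 20000 m); rings are labeled by
#' their outer edge.
#'
#' @param max_m outermost ring edge (m).
#' @param fine_step_m,fine_limit_m fine step size and the distance it
#'   applies up to (m).
#' @param coarse_step_m step size beyond `fine_limit_m` (m).
#' @return data.frame with columns `inner_m`, `outer_m`.
#' @export
ring_schedule <- function(max_m = 20000, fine_step_m = 500,
                          fine_limit_m = 5000, coarse_step_m = 1000) {
  stopifnot(max_m > 0, fine_step_m > 0, coarse_step_m > 0)
  fine_top <- min(fine_limit_m, max_m)
  if (fine_top %% fine_step_m != 0)
    stop("fine_step_m must divide the fine range evenly")
  edges <- seq(0, fine_top, by = fine_step_m)
  if (max_m > fine_top) {
    if ((max_m - fine_top) %% coarse_step_m != 0)
      stop("coarse_step_m must divide the coarse range evenly")
    edges <- c(edges, seq(fine_top + coarse_step_m, max_m, by = coarse_step_m))
  }
  data.frame(inner_m = edges[-length(edges)], outer_m = edges[-1])
}

#' Ring buffers around roads of one class, as raster cell sets
#'
#' Each ring holds the template cells whose centers lie at a road distance in
#' `(inner_m, outer_m]`. By construction the rings are pairwise disjoint and
#' their union equals the full `max` buffer, so the partition property holds
#' exactly.
#'
#' @param roads an `rz_roads`.
#' @param road_class class to buffer around.
#' @param schedule data.frame from [ring_schedule()].
#' @param template `rz_raster` supplying the analysis grid (assumed to cover
#'   the study area).
#' @param dist optional precomputed distance `rz_raster` for this class (to
#'   avoid recomputation); must be on the template grid.
#' @return list of ring buffers; each a list with `inner_m`, `outer_m`,
#'   `cells` (linear cell indices), `area_km2`, and `template`.
#' @export
build_ring_buffers <- function(roads, road_class, schedule, template,
                               dist = NULL) {
  if (is.null(dist)) dist <- distance_raster(roads, road_class, template)
  d <- as.vector(dist$values)
  breaks <- c(schedule$inner_m[1], schedule$outer_m)
  ring_idx <- findInterval(d, breaks, left.open = TRUE)
  ring_idx[d <= breaks[1] | d > breaks[length(breaks)]] <- 0L
  cell_km2 <- (template$cellsize / 1000)^2
  lapply(seq_len(nrow(schedule)), function(k) {
    cells <- which(ring_idx == k)
    list(inner_m = schedule$inner_m[k], outer_m = schedule$outer_m[k],
         cells = cells, area_km2 = length(cells) * cell_km2,
         template = template)
  })
}

#' Segment one ring buffer by a square grid
#'
#' Splits a ring's cell set by the 15 x 15 km (default) analysis grid. Cells
#' partition exactly, so the summed section area equals the ring area.
#'
#' @param ring one element of [build_ring_buffers()] output.
#' @param grid_origin numeric length-2 (x, y) of the grid anchor (m);
#'   conventionally the study-area lower-left corner.
#' @param cell_m grid cell edge (m), default 15000.
#' @return list of sections; each a list with `inner_m`, `outer_m`,
#'   `grid_row`, `grid_col`, `cells`, `area_km2`, `template`.
#' @export
segment_by_grid <- function(ring, grid_origin = c(0, 0), cell_m = 15000) {
  if (length(ring$cells) == 0) return(list())
  xy <- raster_coords(ring$template, ring$cells)
  gr <- floor((xy[, 2] - grid_origin[2]) / cell_m)
  gc <- floor((xy[, 1] - grid_origin[1]) / cell_m)
  key <- paste(gr, gc, sep = ":")
  cell_km2 <- (ring$template$cellsize / 1000)^2
  idx_split <- split(seq_along(ring$cells), key)
  lapply(idx_split, function(ii) {
    list(inner_m = ring$inner_m, outer_m = ring$outer_m,
         grid_row = gr[ii[1]], grid_col = gc[ii[1]],
         cells = ring$cells[ii], area_km2 = length(ii) * cell_km2,
         template = ring$template)
  })
}

#' Clip a section to an elevation band
#'
#' Retains only cells whose elevation lies within the habitat band
#' (1600-3800 m by default) and recomputes the section area. The operation
#' is idempotent. Sections whose clipped area falls below `min_area_km2`
#' are flagged unusable (density on slivers is unstable).
#'
#' @param section a section from [segment_by_grid()].
#' @param elevation `rz_raster` of elevation on the section's template grid.
#' @param band numeric length-2 inclusive elevation band (m).
#' @param min_area_km2 usability floor on the clipped area.
#' @return the section with added fields `kept_cells`, `area_km2` (clipped),
#'   `raw_area_km2`, and `usable`.
#' @export
clip_by_elevation <- function(section, elevation, band = c(1600, 3800),
                              min_area_km2 = 0.25) {
  cells <- if (!is.null(section$kept_cells)) section$kept_cells else
    section$cells
  ev <- elevation$values[cells]
  if (anyNA(ev))
    stop("elevation raster does not cover the section (NA cells found)")
  keep <- ev >= band[1] & ev <= band[2]
  cell_km2 <- (section$template$cellsize / 1000)^2
  section$raw_area_km2 <- length(section$cells) * cell_km2
  section$kept_cells <- cells[keep]
  section$area_km2 <- length(section$kept_cells) * cell_km2
  section$usable <- section$area_km2 >= min_area_km2
  section
}

#' Area-weighted covariate means over a clipped section
#'
#' @param section a clipped section (from [clip_by_elevation()]).
#' @param rasters named list of `rz_raster`s on the section's template grid
#'   (conventionally `elevation`, `forest`, `construction`, `water`,
#'   `population`).
#' @return named numeric vector of means over the clipped cells.
#' @export
extract_covariates <- function(section, rasters) {
  cells <- section$kept_cells
  if (is.null(cells) || length(cells) == 0)
    stop("section has zero clipped area; filter unusable sections upstream")
  vapply(rasters, function(r) mean(r$values[cells]), numeric(1))
}

#' Build, segment, clip and summarize all buffer sections for one road class
#'
#' Composes [build_ring_buffers()], [segment_by_grid()],
#' [clip_by_elevation()] and [extract_covariates()] over a full ring
#' schedule.
#'
#' @param bundle an `rz_landscape` (or a compatible list with `roads`,
#'   `study_area`, rasters, and optionally precomputed `dist` rasters).
#' @param road_class `"national"` or `"provincial"`.
#' @param schedule data.frame from [ring_schedule()].
#' @param band elevation band passed to [clip_by_elevation()].
#' @param grid_origin grid anchor; defaults to the study-area lower-left.
#' @param grid_cell_m analysis grid size (m).
#' @param min_area_km2 usability floor for clipped sections.
#' @return object of class `rz_sections`: list with `sections` (list of
#'   clipped, covariate-summarized sections), `table` (one-row-per-section
#'   summary data.frame) and bookkeeping (`schedule`, `road_class`, `band`,
#'   `grid_origin`).
#' @export
build_sections <- function(bundle, road_class, schedule = ring_schedule(),
                           band = c(1600, 3800), grid_origin = NULL,
                           grid_cell_m = 15000, min_area_km2 = 0.25) {
  if (is.null(grid_origin))
    grid_origin <- c(bundle$study_area$xmin, bundle$study_area$ymin)
  template <- bundle$elevation
  dist <- if (!is.null(bundle$dist)) bundle$dist[[road_class]] else NULL
  rings <- build_ring_buffers(bundle$roads, road_class, schedule, template,
                              dist = dist)
  rasters <- bundle[c("elevation", "forest", "construction", "water",
                      "population")]
  sections <- list()
  for (ring in rings) {
    for (sec in segment_by_grid(ring, grid_origin, grid_cell_m)) {
      sec <- clip_by_elevation(sec, bundle$elevation, band, min_area_km2)
      if (sec$usable) sec$covariates <- extract_covariates(sec, rasters)
      sections[[length(sections) + 1L]] <- sec
    }
  }
  tab <- do.call(rbind, lapply(sections, function(s) {
    cov <- if (!is.null(s$covariates)) s$covariates else
      stats::setNames(rep(NA_real_, length(rasters)), names(rasters))
    data.frame(inner_m = s$inner_m, outer_m = s$outer_m,
               grid_row = s$grid_row, grid_col = s$grid_col,
               area_km2 = s$area_km2, raw_area_km2 = s$raw_area_km2,
               usable = s$usable, t(cov))
  }))
  structure(list(sections = sections, table = tab, schedule = schedule,
                 road_class = road_class, band = band,
                 grid_origin = grid_origin, min_area_km2 = min_area_km2),
            class = "rz_sections")
}

#' @export
print.rz_sections <- function(x, ...) {
  cat(sprintf("<rz_sections> %d sections (%d usable) over %d rings, class=%s\n",
              length(x$sections), sum(x$table$usable), nrow(x$schedule),
              x$road_class))
  invisible(x)
}
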