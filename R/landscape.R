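#' Parameters for the synthetic landscape generator
#'
#' The generator emulates a mountain-range study system: classed major roads
#' crossing the extent, a smooth elevation field, forest cover depressed (and
#' construction/population elevated) near roads, and wildlife sign points
#' drawn from an inhomogeneous Poisson process whose intensity is suppressed
#' within a known distance of roads — the ground-truth road-effect zone that
#' downstream estimation must recover.
#'
#' @param width_km,height_km study-area extent in km; both must exceed 30 so
#'   that at least one 15-km grid cell lies beyond the widest buffers.
#' @param n_national,n_provincial number of roads per class.
#' @param elev_range numeric length-2, min/max elevation (m) of the smooth
#'   field.
#' @param suppression_distance_m named numeric (`national`, `provincial`):
#'   the true road-effect-zone distance per class (m).
#' @param suppression_strength fraction in \[0, 1\] by which sign intensity
#'   is reduced inside the suppression zone (1 = complete avoidance).
#' @param base_intensity baseline sign intensity (signs per km^2) before
#'   suppression, forest weighting and elevation restriction.
#' @param forest_decay_distance_m distance scale (m) over which forest cover
#'   rises from its near-road to its far-from-road level (logistic ramp with
#'   midpoint at half this distance).
#' @param forest_range numeric length-2: forest fraction adjacent to roads
#'   and far from roads. Equal values give a road-independent forest field
#'   (the null landscape used for calibration).
#' @param construction_max,population_max,water_max peak near-road levels of
#'   the construction fraction, population density (persons per km^2) and
#'   water fraction fields.
#' @param cell_m raster cell size (m); the default 90 m mirrors a coarsened
#'   30-m DEM at desk scale.
#' @param seed integer RNG seed; mandatory, all randomness is derived from
#'   it.
#' @return a validated list of class `rz_landscape_params`.
#' @export
landscape_params <- function(width_km = 160, height_km = 160,
                             n_national = 3, n_provincial = 4,
                             elev_range = c(1000, 4500),
                             suppression_distance_m = c(national = 5000,
                                                        provincial = 1500),
                             suppression_strength = 0.8,
                             base_intensity = 2,
                             forest_decay_distance_m = 3000,
                             forest_range = c(0.15, 0.8),
                             construction_max = 0.35,
                             population_max = 300,
                             water_max = 0.08,
                             cell_m = 90,
                             seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("seed is required: all randomness must be seeded")
  if (width_km <= 30 || height_km <= 30)
    stop("degenerate extent: width_km and height_km must exceed 30 km")
  if (suppression_strength < 0 || suppression_strength > 1)
    stop("suppression_strength must lie in [0, 1]")
  if (base_intensity <= 0) stop("base_intensity must be positive")
  stopifnot(length(elev_range) == 2, elev_range[1] < elev_range[2],
            all(c("national", "provincial") %in%
                  names(suppression_distance_m)),
            length(forest_range) == 2, all(forest_range >= 0),
            all(forest_range <= 1), cell_m > 0)
  structure(list(
    width_km = width_km, height_km = height_km,
    n_national = n_national, n_provincial = n_provincial,
    elev_range = elev_range,
    suppression_distance_m = suppression_distance_m,
    suppression_strength = suppression_strength,
    base_intensity = base_intensity,
    forest_decay_distance_m = forest_decay_distance_m,
    forest_range = forest_range,
    construction_max = construction_max,
    population_max = population_max,
    water_max = water_max,
    cell_m = cell_m,
    seed = as.integer(seed)
  ), class = "rz_landscape_params")
}

# Smooth random field as a sum of Gaussian bumps; returns values at (x, y).
# Consumes the current RNG stream.
gaussian_bump_field <- function(x, y, xmax, ymax, n_bumps = 8) {
  cx <- stats::runif(n_bumps, 0, xmax)
  cy <- stats::runif(n_bumps, 0, ymax)
  sd <- stats::runif(n_bumps, 0.10, 0.30) * max(xmax, ymax)
  amp <- stats::runif(n_bumps, -1, 1)
  z <- numeric(length(x))
  for (b in seq_len(n_bumps)) {
    z <- z + amp[b] * exp(-((x - cx[b])^2 + (y - cy[b])^2) / (2 * sd[b]^2))
  }
  z
}

# Random mildly-bent polyline crossing the full extent; horizontal or
# vertical trend with jittered interior vertices.
random_crossing_road <- function(xmax, ymax, road_class, horizontal) {
  n_mid <- 3L
  if (horizontal) {
    xs <- c(0, sort(stats::runif(n_mid, 0.15, 0.85)) * xmax, xmax)
    y0 <- stats::runif(1, 0.15, 0.85) * ymax
    ys <- y0 + c(0, stats::runif(n_mid, -0.08, 0.08) * ymax, 0)
    ys <- pmin(pmax(ys, 0), ymax)
    coords <- cbind(xs, ys)
  } else {
    ys <- c(0, sort(stats::runif(n_mid, 0.15, 0.85)) * ymax, ymax)
    x0 <- stats::runif(1, 0.15, 0.85) * xmax
    xs <- x0 + c(0, stats::runif(n_mid, -0.08, 0.08) * xmax, 0)
    xs <- pmin(pmax(xs, 0), xmax)
    coords <- cbind(xs, ys)
  }
  dimnames(coords) <- NULL
  list(coords = coords, road_class = road_class)
}

#' Generate a synthetic landscape bundle
#'
#' Builds the study-area rectangle, the classed road network, and rasters of
#' elevation, forest, construction, water and population on a shared grid,
#' then draws sign points via [generate_signs()]. Forest rises with distance
#' from roads along a logistic ramp; construction and population decay with
#' distance; elevation is a road-independent smooth field rescaled to
#' `elev_range`. Identical `params` (including `seed`) give bit-identical
#' bundles.
#'
#' @param params an [landscape_params()] object.
#' @return a list of class `rz_landscape` with elements `study_area`,
#'   `roads`, `elevation`, `forest`, `construction`, `water`, `population`
#'   (all `rz_raster` on one grid), `dist` (per-class distance rasters),
#'   `signs` (data.frame x, y, id) and `truth` (the params).
#' @export
generate_landscape <- function(params) {
  stopifnot(inherits(params, "rz_landscape_params"))
  set.seed(params$seed)
  xmax <- params$width_km * 1000
  ymax <- params$height_km * 1000
  h <- params$cell_m
  nc <- as.integer(ceiling(xmax / h))
  nr <- as.integer(ceiling(ymax / h))
  template <- rz_raster(matrix(0, nr, nc), xmin = 0, ymin = 0, cellsize = h)
  xy <- raster_coords(template)
  x <- xy[, 1]; y <- xy[, 2]

  # roads: alternate horizontal/vertical so all rings have area everywhere
  feats <- list()
  n_tot <- params$n_national + params$n_provincial
  cls <- c(rep("national", params$n_national),
           rep("provincial", params$n_provincial))
  for (k in seq_len(n_tot)) {
    feats[[k]] <- random_crossing_road(xmax, ymax, cls[k],
                                       horizontal = (k %% 2 == 1))
  }
  roads <- if (n_tot > 0) rz_roads(feats) else NULL

  mkr <- function(v) rz_raster(matrix(v, nr, nc), 0, 0, h)

  # elevation: smooth bump field rescaled to the declared range
  z <- gaussian_bump_field(x, y, xmax, ymax)
  z <- (z - min(z)) / (max(z) - min(z))
  elev <- params$elev_range[1] + z * diff(params$elev_range)

  # per-class and combined distance to roads
  dist <- list(national = NULL, provincial = NULL)
  d_all <- rep(Inf, length(x))
  for (cl in c("national", "provincial")) {
    if (sum(cls == cl) > 0) {
      segs <- road_segments(roads, cl)
      d <- dist_to_segments(x, y, segs)
      dist[[cl]] <- mkr(d)
      d_all <- pmin(d_all, d)
    }
  }

  # forest: logistic rise with distance from any road, plus smooth noise
  fr <- params$forest_range
  ramp <- if (is.finite(params$forest_decay_distance_m) &&
              params$forest_decay_distance_m > 0) {
    stats::plogis((d_all - params$forest_decay_distance_m / 2) /
                    (params$forest_decay_distance_m / 5))
  } else rep(1, length(x))
  ramp[is.infinite(d_all)] <- 1
  forest <- fr[1] + (fr[2] - fr[1]) * ramp +
    0.05 * gaussian_bump_field(x, y, xmax, ymax, n_bumps = 6)
  forest <- pmin(pmax(forest, 0), 1)

  # construction and population: decay away from roads
  dk <- ifelse(is.infinite(d_all), 1e9, d_all)
  constr <- params$construction_max * exp(-dk / 1500) +
    0.01 * abs(gaussian_bump_field(x, y, xmax, ymax, n_bumps = 5))
  constr <- pmin(pmax(constr, 0), 1)
  pop <- params$population_max * exp(-dk / 2500) *
    (1 + 0.2 * gaussian_bump_field(x, y, xmax, ymax, n_bumps = 5))
  pop <- pmax(pop, 0)
  water <- params$water_max *
    (0.5 + 0.5 * abs(gaussian_bump_field(x, y, xmax, ymax, n_bumps = 5))) *
    exp(-dk / 8000)
  water <- pmin(pmax(water, 0), 1)

  bundle <- structure(list(
    study_area = study_area_rect(0, 0, xmax, ymax),
    roads = roads,
    elevation = mkr(elev),
    forest = mkr(forest),
    construction = mkr(constr),
    water = mkr(water),
    population = mkr(pop),
    dist = dist,
    signs = NULL,
    truth = params
  ), class = "rz_landscape")
  bundle$signs <- generate_signs(bundle, params)
  bundle
}

#' @export
print.rz_landscape <- function(x, ...) {
  cat(sprintf("<rz_landscape> %g x %g km @ %g m cells, %d signs\n",
              x$truth$width_km, x$truth$height_km, x$truth$cell_m,
              if (is.null(x$signs)) 0L else nrow(x$signs)))
  invisible(x)
}

#' Draw sign points from the landscape's inhomogeneous Poisson intensity
#'
#' The intensity at location x is
#' `base_intensity * (1 - s * 1(d_road(x) < D_class)) * forest(x) *
#' 1(1600 <= elev(x) <= 3800)` where the suppression indicator fires when x
#' lies within the class-specific true effect distance of any road of that
#' class. Simulation is by thinning: a homogeneous process at the maximal
#' intensity is sampled over the study area and each point is retained with
#' probability `lambda(x) / lambda_max` (intensity looked up at its raster
#' cell). The RNG stream is derived from `seed` (default offsets the
#' landscape seed so the field-generation draws are not reused).
#'
#' @param bundle an `rz_landscape` (rasters present; `signs` may be NULL).
#' @param params the [landscape_params()] used for the bundle.
#' @param seed integer seed for the point process.
#' @param elevation_band numeric length-2 habitat elevation band (m).
#' @return data.frame with columns `x`, `y`, `id`.
#' @export
generate_signs <- function(bundle, params, seed = params$seed + 1000003L,
                           elevation_band = c(1600, 3800)) {
  stopifnot(inherits(bundle, "rz_landscape"))
  set.seed(as.integer(seed))
  area <- bundle$study_area
  a_km2 <- (area$xmax - area$xmin) * (area$ymax - area$ymin) / 1e6

  elev <- bundle$elevation$values
  forest <- bundle$forest$values
  supp <- matrix(FALSE, nrow(elev), ncol(elev))
  for (cl in c("national", "provincial")) {
    if (!is.null(bundle$dist[[cl]])) {
      supp <- supp |
        (bundle$dist[[cl]]$values < params$suppression_distance_m[[cl]])
    }
  }
  lam <- params$base_intensity *
    (1 - params$suppression_strength * supp) * forest *
    (elev >= elevation_band[1] & elev <= elevation_band[2])
  if (all(lam <= 0)) {
    warning("sign intensity is zero everywhere; returning an empty sign set")
    return(data.frame(x = numeric(0), y = numeric(0), id = integer(0)))
  }
  lam_max <- params$base_intensity  # all modifiers are <= 1

  n <- stats::rpois(1, lam_max * a_km2)
  px <- stats::runif(n, area$xmin, area$xmax)
  py <- stats::runif(n, area$ymin, area$ymax)
  cell <- raster_cell_at(bundle$elevation, px, py)
  keep <- stats::runif(n) < lam[cell] / lam_max
  out <- data.frame(x = px[keep], y = py[keep])
  out$id <- seq_len(nrow(out))
  out
}
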