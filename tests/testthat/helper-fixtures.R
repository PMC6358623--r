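# Shared fixtures, all built in code.

# Small generated landscape reused across tests (memoised per session).
tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- landscape_params(width_km = 60, height_km = 60, n_national = 1,
                            n_provincial = 1, base_intensity = 2,
                            cell_m = 300, seed = 1234)
      cache <<- generate_landscape(p)
    }
    cache
  }
})

# Hand-built flat landscape: constant rasters, one straight horizontal road,
# exact geometry known in closed form.
flat_bundle <- function(width_m = 50000, height_m = 50000, cell_m = 50,
                        elev = 2500, road_y = NULL, forest = 0.6) {
  nc <- as.integer(width_m / cell_m)
  nr <- as.integer(height_m / cell_m)
  mk <- function(v) rz_raster(matrix(v, nr, nc), 0, 0, cell_m)
  if (is.null(road_y)) road_y <- height_m / 2
  roads <- rz_roads(list(list(
    coords = cbind(c(0, width_m), c(road_y, road_y)),
    road_class = "national")))
  structure(list(
    study_area = study_area_rect(0, 0, width_m, height_m),
    roads = roads,
    elevation = mk(elev), forest = mk(forest), construction = mk(0.1),
    water = mk(0.02), population = mk(50),
    dist = list(national = NULL, provincial = NULL),
    signs = data.frame(x = numeric(0), y = numeric(0), id = integer(0)),
    truth = NULL
  ), class = "rz_landscape")
}

# A small square section in the lower-left of a raster template, for
# placement tests.
square_section <- function(template, n_side = 5) {
  cells <- as.vector(outer(seq_len(n_side),
                           (seq_len(n_side) - 1) * template$nrow, "+"))
  cell_km2 <- (template$cellsize / 1000)^2
  list(inner_m = 0, outer_m = 500, grid_row = 0, grid_col = 0,
       cells = cells, kept_cells = cells,
       area_km2 = length(cells) * cell_km2,
       raw_area_km2 = length(cells) * cell_km2,
       usable = TRUE, template = template)
}

# Plausible true parameter vector for the national-structure model, named
# by parameter label.
national_true_theta <- function() {
  c("landcover=~d_constr" = -0.7,
    "landcover~sqrt_dist" = -0.30, "landcover~d_elev" = 0.30,
    "landcover~d_pop" = -0.20,
    "d_density~landcover" = 0.70, "d_density~sqrt_dist" = -0.05,
    "d_density~d_elev" = -0.40, "d_density~d_pop" = 0.10,
    "sqrt_dist~~sqrt_dist" = 1, "d_elev~~d_elev" = 1, "d_pop~~d_pop" = 1,
    "d_forest~~d_forest" = 0.30, "d_constr~~d_constr" = 0.50,
    "d_density~~d_density" = 0.60, "landcover~~landcover" = 0.50,
    "sqrt_dist~~d_elev" = 0.30, "sqrt_dist~~d_pop" = 0.20,
    "d_elev~~d_pop" = 0.10)
}

# Exhaustive signed-rank null distribution for a vector of nonzero
# differences: enumerate all 2^n sign assignments of the ranked |d|.
enumerate_signed_rank_p <- function(d, alternative = "less") {
  stopifnot(all(d != 0))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  switch(alternative,
         less = mean(v_all <= v_obs),
         greater = mean(v_all >= v_obs),
         stop("unsupported alternative"))
}
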