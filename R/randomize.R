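#' Rigid-motion transforms for section copies
#'
#' A copy is produced by rotating a section's cell centers about the section
#' centroid and translating the result: `p' = R(angle) (p - c) + c + (dx, dy)`.
#' Rigid motions preserve the (pre-clipping) cell-count area exactly.
#'
#' @param coords two-column matrix of points (rows).
#' @param transform list with `dx`, `dy`, `angle` (radians) and `center`
#'   (length-2 rotation center).
#' @return transformed two-column matrix.
#' @export
apply_rigid_transform <- function(coords, transform) {
  R <- matrix(c(cos(transform$angle), sin(transform$angle),
                -sin(transform$angle), cos(transform$angle)), 2, 2)
  sweep(sweep(coords, 2, transform$center) %*% t(R), 2,
        transform$center + c(transform$dx, transform$dy), "+")
}

#' @rdname apply_rigid_transform
#' @export
invert_rigid_transform <- function(coords, transform) {
  R <- matrix(c(cos(transform$angle), sin(transform$angle),
                -sin(transform$angle), cos(transform$angle)), 2, 2)
  sweep(sweep(coords, 2, transform$center + c(transform$dx, transform$dy))
        %*% R, 2, transform$center, "+")
}

#' Place a random rigid-motion copy of a section within the study area
#'
#' Rejection sampling: each attempt draws a rotation angle uniform on
#' (0, 2*pi) about the section centroid and a translation placing the
#' centroid uniformly in the study area; the attempt is accepted only if
#' every transformed cell (inset by half the cell diagonal, so whole rotated
#' cells fit) lies inside the study area and, when `exclusion_m > 0`, at
#' least that far from any road of the analyzed class. Uses the current RNG
#' stream; seed at the caller.
#'
#' @param section a clipped section (its full, pre-clipping cell set is
#'   copied; the copy is re-clipped at its destination).
#' @param study_area an `rz_study_area`.
#' @param max_attempts attempts before giving up (the pair is then flagged
#'   unusable, never silently dropped).
#' @param exclusion_m optional minimum distance of the copy from roads of
#'   the analyzed class (0 disables the check).
#' @param road_segs segment matrix for the exclusion check (required when
#'   `exclusion_m > 0`).
#' @return list with `ok` (logical), `transform` (dx, dy, angle, center) and
#'   `attempts`.
#' @export
random_rigid_placement <- function(section, study_area, max_attempts = 1000,
                                   exclusion_m = 0, road_segs = NULL) {
  coords <- raster_coords(section$template, section$cells)
  ctr <- colMeans(coords)
  inset <- section$template$cellsize * sqrt(2) / 2
  if (exclusion_m > 0 && is.null(road_segs))
    stop("exclusion_m > 0 requires road_segs")
  for (att in seq_len(max_attempts)) {
    angle <- stats::runif(1, 0, 2 * pi)
    tx <- stats::runif(1, study_area$xmin, study_area$xmax)
    ty <- stats::runif(1, study_area$ymin, study_area$ymax)
    tr <- list(dx = tx - ctr[1], dy = ty - ctr[2], angle = angle,
               center = ctr)
    pc <- apply_rigid_transform(coords, tr)
    if (!all(area_contains(study_area, pc[, 1], pc[, 2], inset = inset)))
      next
    if (exclusion_m > 0 &&
        min(dist_to_segments(pc[, 1], pc[, 2], road_segs)) < exclusion_m)
      next
    return(list(ok = TRUE, transform = tr, attempts = att))
  }
  list(ok = FALSE, transform = NULL, attempts = max_attempts)
}

#' Create one elevation-clipped, covariate-summarized random copy per section
#'
#' Copies start from each section's full (pre-clipping) geometry, are placed
#' by [random_rigid_placement()], then clipped to the same elevation band
#' and summarized with the same covariate operation as the actual sections —
#' covariates are resampled from the rasters at the copy's location, never
#' copied from the actual member. Pairs whose actual member is unusable,
#' whose placement failed, or whose copy has clipped area below the floor
#' are flagged unusable.
#'
#' @param secs an `rz_sections` from [build_sections()].
#' @param bundle the landscape bundle supplying `study_area` and rasters.
#' @param seed integer seed for the placement RNG.
#' @param exclusion_m,max_attempts passed to [random_rigid_placement()].
#' @return object of class `rz_pairs`: list with `pairs` (per-section list
#'   of placement records) and the originating `secs`.
#' @export
make_paired_copies <- function(secs, bundle, seed, exclusion_m = 0,
                               max_attempts = 1000) {
  stopifnot(inherits(secs, "rz_sections"))
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  band <- secs$band
  rasters <- bundle[c("elevation", "forest", "construction", "water",
                      "population")]
  road_segs <- if (exclusion_m > 0)
    road_segments(bundle$roads, secs$road_class) else NULL
  cell_km2 <- (bundle$elevation$cellsize / 1000)^2

  pairs <- vector("list", length(secs$sections))
  for (k in seq_along(secs$sections)) {
    sec <- secs$sections[[k]]
    if (!isTRUE(sec$usable)) {
      pairs[[k]] <- list(usable = FALSE, reason = "actual_unusable")
      next
    }
    pl <- random_rigid_placement(sec, bundle$study_area, max_attempts,
                                 exclusion_m, road_segs)
    if (!pl$ok) {
      pairs[[k]] <- list(usable = FALSE, reason = "placement_failed",
                         attempts = pl$attempts)
      next
    }
    coords <- raster_coords(sec$template, sec$cells)
    pc <- apply_rigid_transform(coords, pl$transform)
    ev <- raster_sample(bundle$elevation, pc[, 1], pc[, 2])
    keep <- !is.na(ev) & ev >= band[1] & ev <= band[2]
    copy_area <- sum(keep) * cell_km2
    raw_area <- nrow(coords) * cell_km2  # rigid motion: equals actual exactly
    usable <- copy_area >= secs$min_area_km2
    cov <- if (usable) {
      vapply(rasters, function(r)
        mean(raster_sample(r, pc[keep, 1], pc[keep, 2])), numeric(1))
    } else NULL
    ctr <- pl$transform$center
    radius <- sqrt(max((coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2)) +
      bundle$elevation$cellsize
    pairs[[k]] <- list(usable = usable,
                       reason = if (usable) NA_character_ else
                         "copy_below_area_floor",
                       transform = pl$transform, attempts = pl$attempts,
                       center_dst = ctr + c(pl$transform$dx, pl$transform$dy),
                       radius = radius,
                       copy_kept_src = sec$cells[keep],
                       copy_area_km2 = copy_area,
                       copy_raw_area_km2 = raw_area,
                       copy_covariates = cov)
  }
  structure(list(pairs = pairs, secs = secs), class = "rz_pairs")
}

#' @export
print.rz_pairs <- function(x, ...) {
  us <- vapply(x$pairs, function(p) isTRUE(p$usable), logical(1))
  cat(sprintf("<rz_pairs> %d pairs, %d usable, class=%s\n",
              length(x$pairs), sum(us), x$secs$road_class))
  invisible(x)
}
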