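#' Deduplicate sign points by a minimum pairwise distance
#'
#' Greedy single pass in `id` order: a sign is kept iff no previously kept
#' sign lies strictly within `min_dist_m` of it. The pass is deterministic,
#' idempotent, its output is a subset of its input, and every pair of kept
#' signs is at least `min_dist_m` apart. A 100-m rule reduces clustered
#' field records to single observations.
#'
#' Implementation detail: kept points are hashed into `min_dist_m`-sized
#' grid buckets so each candidate checks only its 3 x 3 neighborhood,
#' keeping the pass O(n) for realistic densities.
#'
#' @param signs data.frame with columns `x`, `y`, `id`.
#' @param min_dist_m minimum allowed pairwise distance (m).
#' @return the kept subset of `signs`, in id order.
#' @export
deduplicate_signs <- function(signs, min_dist_m = 100) {
  if (nrow(signs) == 0) return(signs)
  ord <- order(signs$id)
  x <- signs$x[ord]; y <- signs$y[ord]
  n <- length(x)
  bx <- floor(x / min_dist_m); by <- floor(y / min_dist_m)
  # integer bucket keys and a precomputed 3 x 3 neighbor-bucket index
  nby <- max(by) - min(by) + 3
  key <- (bx - min(bx) + 1) * nby + (by - min(by) + 1)
  bucket_ids <- sort(unique(key))
  offs <- as.vector(outer(c(-1, 0, 1) * nby, c(-1, 0, 1), "+"))
  neigh <- matrix(match(rep(key, 9) + rep(offs, each = n), bucket_ids),
                  nrow = n)
  own <- match(key, bucket_ids)
  kept_in <- vector("list", length(bucket_ids))
  keep <- logical(n)
  d2min <- min_dist_m^2
  for (i in seq_len(n)) {
    ok <- TRUE
    for (nb in neigh[i, ]) {
      if (is.na(nb)) next
      js <- kept_in[[nb]]
      if (!is.null(js) &&
          any((x[js] - x[i])^2 + (y[js] - y[i])^2 < d2min)) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      keep[i] <- TRUE
      kept_in[[own[i]]] <- c(kept_in[[own[i]]], i)
    }
  }
  signs[ord[keep], , drop = FALSE]
}

#' Sign density of a single clipped section
#'
#' Signs are assigned to raster cells (half-open cells, so a point on a cell
#' edge is counted exactly once) and counted over the section's clipped cell
#' set; density is count per km^2 of clipped area.
#'
#' @param section a clipped section with nonzero area.
#' @param signs deduplicated sign data.frame.
#' @return signs per km^2.
#' @export
section_sign_density <- function(section, signs) {
  if (is.null(section$kept_cells) || section$area_km2 <= 0)
    stop("section has zero clipped area; unusable sections must be filtered")
  idx <- raster_cell_at(section$template, signs$x, signs$y)
  sum(idx %in% section$kept_cells, na.rm = TRUE) / section$area_km2
}

# Per-pair densities for all usable pairs: one vectorized pass for actual
# sections (which are pairwise disjoint, so a cell->section map works), a
# radius-prefiltered inverse-transform pass per copy.
pair_densities <- function(pairs, signs) {
  stopifnot(inherits(pairs, "rz_pairs"))
  secs <- pairs$secs
  template <- secs$sections[[1]]$template
  ncell <- template$nrow * template$ncol
  sec_of_cell <- integer(ncell)
  for (k in seq_along(secs$sections)) {
    s <- secs$sections[[k]]
    if (isTRUE(s$usable)) sec_of_cell[s$kept_cells] <- k
  }
  sidx <- raster_cell_at(template, signs$x, signs$y)
  sidx <- sidx[!is.na(sidx)]
  counts <- tabulate(sec_of_cell[sidx], nbins = length(secs$sections))

  rows <- lapply(seq_along(pairs$pairs), function(k) {
    p <- pairs$pairs[[k]]
    s <- secs$sections[[k]]
    if (!isTRUE(p$usable))
      return(data.frame(pair = k, inner_m = s$inner_m, outer_m = s$outer_m,
                        usable = FALSE, actual_density = NA_real_,
                        copy_density = NA_real_))
    near <- (signs$x - p$center_dst[1])^2 + (signs$y - p$center_dst[2])^2 <=
      p$radius^2
    cnt_c <- 0L
    if (any(near)) {
      p0 <- invert_rigid_transform(cbind(signs$x[near], signs$y[near]),
                                   p$transform)
      cidx <- raster_cell_at(template, p0[, 1], p0[, 2])
      cnt_c <- sum(cidx %in% p$copy_kept_src, na.rm = TRUE)
    }
    data.frame(pair = k, inner_m = s$inner_m, outer_m = s$outer_m,
               usable = TRUE,
               actual_density = counts[k] / s$area_km2,
               copy_density = cnt_c / p$copy_area_km2)
  })
  do.call(rbind, rows)
}

#' Paired rank test on section-vs-copy sign densities for one ring
#'
#' Wilcoxon signed-rank test on the per-pair density differences
#' (actual - copy). Zero differences are dropped; the exact null
#' distribution is used when at most `exact_max` nonzero differences remain
#' and there are no ties in their absolute values, otherwise the normal
#' approximation with tie correction. The default one-sided alternative
#' `"less"` tests for depressed density near roads. The statistic is
#' reported under the name `U` for compatibility with conventional result
#' tables.
#'
#' @param actual,copy numeric vectors of paired densities (signs/km^2).
#' @param alternative passed to [stats::wilcox.test()].
#' @param alpha significance level.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `diff` (mean difference), `U` (signed-rank statistic),
#'   `n` (usable pairs), `n_nonzero`, `p`, `significant`, `degenerate`.
#' @export
ring_paired_test <- function(actual, copy, alternative = "less",
                             alpha = 0.05, exact_max = 25) {
  stopifnot(length(actual) == length(copy), length(actual) >= 1)
  d <- actual - copy
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(list(diff = 0, U = 0, n = length(d), n_nonzero = 0L, p = 1,
                significant = FALSE, degenerate = TRUE))
  }
  ties <- anyDuplicated(abs(nz)) > 0
  exact <- length(nz) <= exact_max && !ties
  # one-sample signed-rank on the nonzero differences: identical to the
  # paired test and composes cleanly with the explicit zero-drop policy
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  p <- unname(wt$p.value)
  list(diff = mean(d), U = unname(wt$statistic), n = length(d),
       n_nonzero = length(nz), p = p, significant = p < alpha,
       degenerate = FALSE)
}

#' Per-ring paired tests over a full schedule
#'
#' Deduplicates signs, computes paired densities and runs
#' [ring_paired_test()] for every ring, producing the conventional
#' per-distance result table (difference of sign density, U, n, p).
#'
#' @param pairs an `rz_pairs` from [make_paired_copies()].
#' @param signs sign data.frame (deduplicated internally unless
#'   `dedup = FALSE`).
#' @param alpha significance level.
#' @param alternative one-sided alternative for the rank test.
#' @param dedup logical; apply [deduplicate_signs()] first.
#' @param dedup_dist_m minimum pairwise sign distance (m).
#' @param p_adjust optional multiple-testing correction across rings
#'   (`"none"` matches the conventional analysis; `"BH"` available).
#' @return data.frame with one row per ring: `distance_m` (outer edge),
#'   `diff`, `U`, `n`, `p`, `significant`, `degenerate`.
#' @export
ring_test_table <- function(pairs, signs, alpha = 0.05,
                            alternative = "less", dedup = TRUE,
                            dedup_dist_m = 100, p_adjust = "none") {
  if (dedup) signs <- deduplicate_signs(signs, dedup_dist_m)
  pd <- pair_densities(pairs, signs)
  sched <- pairs$secs$schedule
  rows <- lapply(seq_len(nrow(sched)), function(k) {
    sub <- pd[pd$usable & pd$outer_m == sched$outer_m[k], ]
    if (nrow(sub) == 0)
      return(data.frame(distance_m = sched$outer_m[k], diff = NA_real_,
                        U = NA_real_, n = 0L, p = NA_real_,
                        significant = FALSE, degenerate = TRUE))
    r <- ring_paired_test(sub$actual_density, sub$copy_density,
                          alternative = alternative, alpha = alpha)
    data.frame(distance_m = sched$outer_m[k], diff = r$diff, U = r$U,
               n = r$n, p = r$p, significant = r$significant,
               degenerate = r$degenerate)
  })
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    out$p <- stats::p.adjust(out$p, method = p_adjust)
    out$significant <- !is.na(out$p) & out$p < alpha
  }
  out
}

#' Road-effect-zone decision rule over per-ring test results
#'
#' Two rules are exposed. `"last_significant"` sets the zone at the outer
#' edge of the furthest significant ring (tolerating interior
#' non-significant gaps). `"contiguous"` sets it at the outer edge of the
#' initial unbroken run of significant rings, which is robust to isolated
#' chance rejections far from the road. Significant rings lying beyond the
#' chosen zone are reported in `isolated_m`, never silently absorbed. With
#' no significant ring the zone is 0.
#'
#' @param results data.frame from [ring_test_table()] (sorted by ring).
#' @param rule `"last_significant"` or `"contiguous"`.
#' @param alpha significance level re-applied to the `p` column.
#' @return list with `zone_m`, `rule`, `alpha`, `isolated_m` (outer edges of
#'   significant rings beyond the zone) and `n_significant`.
#' @export
effect_zone <- function(results, rule = c("last_significant", "contiguous"),
                        alpha = 0.05) {
  rule <- match.arg(rule)
  if (nrow(results) == 0) stop("empty results table")
  stopifnot(!is.unsorted(results$distance_m))
  sig <- !is.na(results$p) & results$p < alpha
  zone <- if (!any(sig)) {
    0
  } else if (rule == "last_significant") {
    max(results$distance_m[sig])
  } else {
    run <- cumprod(as.numeric(sig))  # 1 while the initial run is unbroken
    if (run[1] == 0) 0 else max(results$distance_m[run == 1])
  }
  isolated <- results$distance_m[sig & results$distance_m > zone]
  list(zone_m = zone, rule = rule, alpha = alpha, isolated_m = isolated,
       n_significant = sum(sig))
}

#' Observation table for the structural equation model
#'
#' One row per usable section pair: the square root of the ring midpoint
#' distance (sqrt-transformed road distance), the actual-minus-copy
#' differences of mean elevation, population density, forest, construction
#' and water fractions, and the difference of sign densities.
#'
#' @param pairs an `rz_pairs` (with covariates on both members).
#' @param signs sign data.frame (deduplicated internally unless
#'   `dedup = FALSE`).
#' @param dedup,dedup_dist_m as in [ring_test_table()].
#' @return data.frame with columns `sqrt_dist`, `d_elev`, `d_pop`,
#'   `d_forest`, `d_constr`, `d_water`, `d_density`.
#' @export
prepare_sem_table <- function(pairs, signs, dedup = TRUE,
                              dedup_dist_m = 100) {
  if (dedup) signs <- deduplicate_signs(signs, dedup_dist_m)
  pd <- pair_densities(pairs, signs)
  rows <- lapply(seq_along(pairs$pairs), function(k) {
    p <- pairs$pairs[[k]]
    if (!isTRUE(p$usable)) return(NULL)
    s <- pairs$secs$sections[[k]]
    if (is.null(s$covariates) || is.null(p$copy_covariates)) return(NULL)
    a <- s$covariates; b <- p$copy_covariates
    data.frame(
      sqrt_dist = sqrt((s$inner_m + s$outer_m) / 2),
      d_elev = a[["elevation"]] - b[["elevation"]],
      d_pop = a[["population"]] - b[["population"]],
      d_forest = a[["forest"]] - b[["forest"]],
      d_constr = a[["construction"]] - b[["construction"]],
      d_water = a[["water"]] - b[["water"]],
      d_density = pd$actual_density[k] - pd$copy_density[k]
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sqrt_dist = numeric(0), d_elev = numeric(0),
                      d_pop = numeric(0), d_forest = numeric(0),
                      d_constr = numeric(0), d_water = numeric(0),
                      d_density = numeric(0))
  rownames(out) <- NULL
  out
}
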