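test_that("deduplication follows the greedy 100-m rule", {
  empty <- data.frame(x = numeric(0), y = numeric(0), id = integer(0))
  expect_equal(nrow(deduplicate_signs(empty)), 0)

  two <- data.frame(x = c(0, 50), y = c(0, 0), id = 1:2)
  expect_equal(deduplicate_signs(two)$id, 1L)

  chain <- data.frame(x = c(0, 80, 160), y = 0, id = 1:3)
  expect_equal(deduplicate_signs(chain)$id, c(1L, 3L))
})

test_that("deduplication matches a brute-force greedy oracle", {
  brute <- function(signs, dmin = 100) {
    o <- order(signs$id)
    keep <- integer(0)
    for (i in o) {
      if (length(keep) == 0 ||
          all((signs$x[keep] - signs$x[i])^2 +
                (signs$y[keep] - signs$y[i])^2 >= dmin^2))
        keep <- c(keep, i)
    }
    signs[keep, ]
  }
  set.seed(10)
  for (rep in 1:5) {
    s <- data.frame(x = runif(300, 0, 2000), y = runif(300, 0, 2000),
                    id = sample(300))
    got <- deduplicate_signs(s)
    want <- brute(s)
    expect_equal(got$id, want$id)
    # postcondition: all kept pairs at least 100 m apart
    expect_true(min(dist(cbind(got$x, got$y))) >= 100)
    # idempotence and subset
    expect_equal(deduplicate_signs(got), got)
    expect_true(all(got$id %in% s$id))
  }
})

test_that("section density is count over clipped area", {
  tmpl <- rz_raster(matrix(0, 10, 10), 0, 0, 500)
  sec <- list(kept_cells = raster_cell_at(tmpl, rep(250, 14),
                                          seq(250, 250 + 13 * 500, 500)),
              area_km2 = 3.5, template = tmpl)
  none <- data.frame(x = numeric(0), y = numeric(0), id = integer(0))
  expect_equal(section_sign_density(sec, none), 0)
  seven <- data.frame(x = rep(250, 7), y = seq(250, 3250, 500), id = 1:7)
  expect_equal(section_sign_density(sec, seven), 2.0)
  bad <- sec; bad$area_km2 <- 0; bad$kept_cells <- integer(0)
  expect_error(section_sign_density(bad, seven), "zero")
})

test_that("a sign on a cell edge is assigned to exactly one cell", {
  tmpl <- rz_raster(matrix(0, 10, 10), 0, 0, 500)
  idx <- raster_cell_at(tmpl, 500, 250)  # exactly on the vertical edge
  expect_length(idx, 1)
  expect_false(is.na(idx))
  # half-open convention: the edge point belongs to the right-hand cell
  expect_equal(unname(raster_coords(tmpl, idx)[1, "x"]), 750)
})

test_that("paired rank test matches exhaustive enumeration", {
  d <- c(-3, -2, -1, -0.5, 0.2)
  res <- ring_paired_test(d, rep(0, 5), alternative = "less")
  expect_equal(res$p, enumerate_signed_rank_p(d, "less"))
  expect_equal(res$n, 5)
  expect_false(res$degenerate)
  # statistic is the positive-rank sum
  expect_equal(res$U, sum(rank(abs(d))[d > 0]))
})

test_that("degenerate rings are flagged with p = 1", {
  res <- ring_paired_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  expect_equal(res$U, 0)
  expect_false(res$significant)
})

test_that("large-n rings switch to the tie-corrected normal approximation", {
  set.seed(3)
  a <- rnorm(40); b <- rnorm(40, 0.8)
  res <- ring_paired_test(a, b, alternative = "less")
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             alternative = "less",
                                             exact = FALSE))
  expect_equal(res$p, unname(ref$p.value))
  expect_lt(res$p, 0.05)
})

test_that("effect zone rules reproduce the published significance patterns", {
  sched <- ring_schedule(20000, 500, 5000, 1000)
  mk <- function(sig_at) {
    data.frame(distance_m = sched$outer_m,
               p = ifelse(sched$outer_m %in% sig_at, 0.01, 0.5))
  }
  # national-style pattern: significant at 6 of the first 10 rings
  nat <- mk(c(500, 1500, 2000, 3000, 4000, 5000))
  expect_equal(effect_zone(nat, "last_significant")$zone_m, 5000)
  # provincial-style pattern: only the first three rings significant
  prov <- mk(c(500, 1000, 1500))
  expect_equal(effect_zone(prov, "last_significant")$zone_m, 1500)
  expect_equal(effect_zone(prov, "contiguous")$zone_m, 1500)
  # no significant ring
  expect_equal(effect_zone(mk(numeric(0)), "last_significant")$zone_m, 0)
  # isolated ring beyond the contiguous run is flagged, not absorbed
  iso <- mk(c(500, 1000, 2500))
  ez <- effect_zone(iso, "contiguous")
  expect_equal(ez$zone_m, 1000)
  expect_equal(ez$isolated_m, 2500)
  expect_error(effect_zone(nat[0, ], "contiguous"), "empty")
})

test_that("SEM table rows carry sqrt distance and pair differences", {
  b <- tiny_bundle()
  secs <- build_sections(b, "national", ring_schedule(3000, 500, 2000, 1000))
  pairs <- make_paired_copies(secs, b, seed = 17)
  tab <- prepare_sem_table(pairs, b$signs)
  n_usable <- sum(vapply(pairs$pairs, function(p) isTRUE(p$usable),
                         logical(1)))
  expect_equal(nrow(tab), n_usable)
  expect_named(tab, c("sqrt_dist", "d_elev", "d_pop", "d_forest",
                      "d_constr", "d_water", "d_density"))
  # ring (2000, 3000] has midpoint 2500 -> sqrt = 50
  usable <- which(vapply(pairs$pairs, function(p) isTRUE(p$usable),
                         logical(1)))
  inner <- vapply(usable, function(k) secs$sections[[k]]$inner_m,
                  numeric(1))
  expect_true(all(tab$sqrt_dist[inner == 2000] == 50))
  expect_true(all(is.finite(tab$d_density)))
})
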