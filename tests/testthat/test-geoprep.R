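test_that("ring schedule reproduces the 25-ring major-road layout", {
  s <- ring_schedule(20000, 500, 5000, 1000)
  expect_equal(nrow(s), 25)
  expect_equal(s$outer_m, c(seq(500, 5000, 500), seq(6000, 20000, 1000)))
  expect_equal(s$inner_m[1], 0)
  expect_equal(s$inner_m[-1], s$outer_m[-25])
})

test_that("ring schedule handles single-step and mixed cases", {
  expect_equal(nrow(ring_schedule(500, 500, 500, 1000)), 1)
  expect_equal(nrow(ring_schedule(6000, 500, 5000, 1000)), 11)
  expect_error(ring_schedule(20000, 300, 5000, 1000), "divide")
  expect_error(ring_schedule(20500, 500, 5000, 1000), "divide")
})

test_that("straight-road ring buffer area matches the analytic value", {
  # full-width horizontal road: the (0, 500] ring is a 1-km band of length
  # 50 km with no end caps inside the domain -> exactly 50 km^2
  b <- flat_bundle(width_m = 50000, height_m = 50000, cell_m = 50)
  rings <- build_ring_buffers(b$roads, "national",
                              ring_schedule(500, 500, 500, 1000),
                              b$elevation)
  expect_equal(rings[[1]]$area_km2, 50, tolerance = 0.005)
})

test_that("rings partition the maximal buffer exactly", {
  b <- tiny_bundle()
  sched <- ring_schedule(5000, 500, 5000, 1000)
  rings <- build_ring_buffers(b$roads, "national", sched, b$elevation,
                              dist = b$dist$national)
  cells <- lapply(rings, `[[`, "cells")
  all_cells <- unlist(cells)
  expect_equal(anyDuplicated(all_cells), 0)  # pairwise disjoint
  single <- which(b$dist$national$values > 0 &
                    b$dist$national$values <= 5000)
  expect_setequal(all_cells, single)          # union = max buffer
})

test_that("empty road class is rejected by name", {
  b <- flat_bundle()
  expect_error(
    build_ring_buffers(b$roads, "provincial", ring_schedule(500, 500, 500),
                       b$elevation),
    "provincial")
})

test_that("grid segmentation conserves area and splits known cases", {
  b <- tiny_bundle()
  sched <- ring_schedule(3000, 500, 3000, 1000)
  rings <- build_ring_buffers(b$roads, "national", sched, b$elevation,
                              dist = b$dist$national)
  for (ring in rings) {
    secs <- segment_by_grid(ring, c(0, 0), 15000)
    expect_equal(sum(vapply(secs, `[[`, numeric(1), "area_km2")),
                 ring$area_km2, tolerance = 1e-9)
    expect_setequal(unlist(lapply(secs, `[[`, "cells")), ring$cells)
  }
})

test_that("a ring inside one grid cell yields exactly one section", {
  tmpl <- rz_raster(matrix(0, 100, 100), 0, 0, 100)  # 10 x 10 km
  ring <- list(inner_m = 0, outer_m = 500, cells = c(1L, 5L, 300L),
               area_km2 = 3 * 0.01, template = tmpl)
  secs <- segment_by_grid(ring, c(0, 0), 15000)
  expect_length(secs, 1)
  expect_equal(secs[[1]]$area_km2, ring$area_km2)
})

test_that("a ring crossing a 2x2 grid block splits by hand-checked cells", {
  tmpl <- rz_raster(matrix(0, 40, 40), 0, 0, 1000)  # 40 x 40 km, 1-km cells
  # four cells at the corners of the 15-km grid intersection near (15, 15) km
  xy <- rbind(c(14500, 14500), c(15500, 14500), c(14500, 15500),
              c(15500, 15500))
  cells <- raster_cell_at(tmpl, xy[, 1], xy[, 2])
  ring <- list(inner_m = 0, outer_m = 500, cells = cells,
               area_km2 = 4, template = tmpl)
  secs <- segment_by_grid(ring, c(0, 0), 15000)
  expect_length(secs, 4)
  keys <- sort(unname(vapply(secs, function(s)
    paste(s$grid_row, s$grid_col), character(1))))
  expect_equal(keys, c("0 0", "0 1", "1 0", "1 1"))
  expect_true(all(vapply(secs, `[[`, numeric(1), "area_km2") == 1))
})

test_that("elevation clipping keeps in-band cells and is idempotent", {
  tmpl <- rz_raster(matrix(0, 20, 20), 0, 0, 500)
  sec <- list(inner_m = 0, outer_m = 500, grid_row = 0, grid_col = 0,
              cells = 1:400, area_km2 = 100, template = tmpl)
  const <- function(v) rz_raster(matrix(v, 20, 20), 0, 0, 500)
  s1 <- clip_by_elevation(sec, const(2500))
  expect_equal(s1$area_km2, s1$raw_area_km2)
  expect_true(s1$usable)
  s2 <- clip_by_elevation(sec, const(4000))
  expect_equal(s2$area_km2, 0)
  expect_false(s2$usable)
  # left half 1500 m (out of band), right half 2000 m (in band)
  half <- rz_raster(cbind(matrix(1500, 20, 10), matrix(2000, 20, 10)),
                    0, 0, 500)
  s3 <- clip_by_elevation(sec, half)
  expect_equal(s3$area_km2, 50)
  s3b <- clip_by_elevation(s3, half)
  expect_identical(s3b$kept_cells, s3$kept_cells)
  expect_identical(s3b$area_km2, s3$area_km2)
})

test_that("covariate extraction averages exactly over clipped cells", {
  tmpl <- rz_raster(matrix(0, 10, 10), 0, 0, 500)
  sec <- list(cells = 1:100, kept_cells = 1:100, area_km2 = 25,
              template = tmpl)
  const <- rz_raster(matrix(3.5, 10, 10), 0, 0, 500)
  checker <- rz_raster(matrix(rep(c(0, 1), 50), 10, 10), 0, 0, 500)
  cov <- extract_covariates(sec, list(a = const, b = checker))
  expect_equal(cov[["a"]], 3.5)
  expect_equal(cov[["b"]], 0.5)
  sec0 <- sec; sec0$kept_cells <- integer(0)
  expect_error(extract_covariates(sec0, list(a = const)), "zero")
})

test_that("build_sections produces a consistent summary table", {
  b <- tiny_bundle()
  secs <- build_sections(b, "national", ring_schedule(2000, 500, 2000, 1000))
  expect_s3_class(secs$table, "data.frame")
  expect_equal(nrow(secs$table), length(secs$sections))
  usable <- secs$table[secs$table$usable, ]
  expect_true(all(usable$elevation >= 1600 & usable$elevation <= 3800))
  expect_true(all(usable$area_km2 >= 0.25))
  expect_true(all(secs$table$area_km2 <= secs$table$raw_area_km2))
})
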