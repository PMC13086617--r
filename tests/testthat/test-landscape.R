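test_that("pair enumeration honors the separation floor", {
  tab <- list(id = c("a", "b", "c"), x = c(0, 2000, 5000), y = c(0, 0, 0))
  expect_equal(nrow(build_pairs(tab)), 3L)
  p <- build_pairs(tab, min_separation = 3000)
  expect_equal(nrow(p), 2L) # 0-5 km and 2-5 km survive; 0-2 km dropped
  expect_setequal(p$geo_m, c(5000, 3000))
  tab2 <- list(id = sprintf("s%03d", 1:30), x = runif(30, 0, 1e4),
               y = runif(30, 0, 1e4))
  expect_equal(nrow(build_pairs(tab2)), 30 * 29 / 2)
})

test_that("transect means: constant fields, half-planes, thin strips", {
  m <- matrix(2.5, 40, 40)
  st <- raster_stack(list(a = m), pixel = 100)
  tm <- extract_transect_means(st, rbind(c(500, 700), c(3300, 2900)),
                               buffer = 300)
  expect_equal(unname(tm["a"]), 2.5)
  # exact coverage: weights sum to the corridor area to machine precision
  L <- sqrt(2800^2 + 2200^2)
  expect_equal(attr(tm, "area"), L * 600, tolerance = 1e-9)
  # binary half-plane covering half the transect
  half <- matrix(0, 40, 40); half[, 21:40] <- 1 # x > 2000
  st2 <- raster_stack(list(h = half), pixel = 100, binary = "h")
  tm2 <- extract_transect_means(st2, rbind(c(1000, 2000), c(3000, 2000)),
                                buffer = 300)
  expect_equal(unname(tm2["h"]), 0.5, tolerance = 0.02)
  # one-pixel strip crossed perpendicularly: mean = strip width / length
  strip <- matrix(0, 40, 40); strip[, 20] <- 1
  st3 <- raster_stack(list(s = strip), pixel = 100, binary = "s")
  tm3 <- extract_transect_means(st3, rbind(c(500, 2050), c(3500, 2050)),
                                buffer = 250)
  expect_equal(unname(tm3["s"]), 100 / 3000, tolerance = 0.02 * 100 / 3000 +
                 0.002)
  # subgrid mode approximates the exact weights closely
  tm4 <- extract_transect_means(st2, rbind(c(1000, 2000), c(3000, 2000)),
                                buffer = 300, method = "subgrid", subdiv = 8)
  expect_equal(unname(tm4["h"]), unname(tm2["h"]), tolerance = 0.01)
  expect_error(extract_transect_means(st, rbind(c(-5e4, 0), c(-4e4, 0)),
                                      buffer = 100), "extent")
})

test_that("transect means are invariant under scene translation", {
  set.seed(12)
  vals <- matrix(runif(1600), 40, 40)
  st <- raster_stack(list(v = vals), xll = 0, yll = 0, pixel = 100)
  stT <- raster_stack(list(v = vals), xll = 7000, yll = -3000, pixel = 100)
  line <- rbind(c(600, 500), c(3500, 3100))
  a <- extract_transect_means(st, line, buffer = 400)
  b <- extract_transect_means(stT, sweep(line, 2, c(7000, -3000), "+"),
                              buffer = 400)
  expect_equal(a["v"], b["v"], tolerance = 1e-12)
  expect_equal(attr(a, "area"), attr(b, "area"), tolerance = 1e-9)
})

test_that("least-cost paths: uniform surfaces, gaps, degenerate cases", {
  s <- resistance_surface(matrix(4, 50, 50), pixel = 100)
  g <- cost_graph(s)
  lcp <- least_cost_path(s, c(250, 250), c(4750, 4250), graph = g)
  straight <- sqrt(4500^2 + 4000^2)
  expect_gte(lcp$cost, 4 * straight - 1e-9)
  # 8-connected discretization bound: path length within ~8.3% of straight
  expect_lte(lcp$cost, 4 * straight * sqrt(2) * cos(pi / 8) + 1e-9)
  # symmetry
  rev <- least_cost_path(s, c(4750, 4250), c(250, 250), graph = g)
  expect_equal(lcp$cost, rev$cost)
  # src = dst
  z <- least_cost_path(s, c(1050, 1050), c(1050, 1050), graph = g)
  expect_equal(z$cost, 0)
  # wall with a single gap: path must route through the gap
  wall <- matrix(1, 30, 30)
  wall[, 15] <- 1000
  wall[4, 15] <- 1 # gap near the top (row 4)
  sw <- resistance_surface(wall, pixel = 100)
  lp <- least_cost_path(sw, c(250, 250), c(2750, 250))
  gap_xy <- lp$path[which.min(abs(lp$path[, 1] - 1450)), ]
  expect_equal(unname(gap_xy[2]), 2650) # y of row 4 on a 30-row grid
  # accumulated cost <= straight-line pixel chain cost on a random surface
  set.seed(3)
  r <- matrix(runif(900, 1, 10), 30, 30)
  sr <- resistance_surface(r, pixel = 100)
  gr <- cost_graph(sr)
  src <- c(150, 150); dst <- c(2850, 2350)
  lcp2 <- least_cost_path(sr, src, dst, graph = gr)
  # chain along the straight segment, visiting each intersected cell once
  tt <- seq(0, 1, length.out = 400)
  pts <- cbind(src[1] + tt * (dst[1] - src[1]), src[2] + tt * (dst[2] - src[2]))
  cells <- unique(rescape:::point_cells(rescape:::surface_geometry(sr), pts))
  chain <- 0
  for (k in 2:length(cells)) {
    r1 <- (cells[k - 1] - 1) %% 30 + 1; c1 <- (cells[k - 1] - 1) %/% 30 + 1
    r2 <- (cells[k] - 1) %% 30 + 1; c2 <- (cells[k] - 1) %/% 30 + 1
    d <- 100 * sqrt((r1 - r2)^2 + (c1 - c2)^2)
    chain <- chain + (r[cells[k - 1]] + r[cells[k]]) / 2 * d
  }
  expect_lte(lcp2$cost, chain + 1e-9)
})

test_that("nodata barriers make destinations unreachable", {
  m <- matrix(1, 20, 20)
  m[, 10] <- NA
  s <- resistance_surface(m, pixel = 100)
  expect_error(least_cost_path(s, c(150, 150), c(1850, 150)), "unreachable")
  expect_error(least_cost_path(s, c(950, 150), c(150, 150)), "nodata")
})

test_that("ASCII grid and stack I/O round-trip", {
  set.seed(2)
  m <- matrix(runif(300), 15, 20)
  m[3, 5] <- NA
  s <- resistance_surface(m, xll = 1000, yll = 2000, pixel = 180)
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(s, path)
  s2 <- read_asc(path)
  expect_equal(s2$grid, m)
  expect_equal(s2$xll, 1000)
  expect_equal(s2$pixel, 180)
  dir <- withr::local_tempdir()
  st <- raster_stack(list(a = m, b = matrix(0:1, 15, 20)), xll = 1000,
                     yll = 2000, pixel = 180, binary = "b")
  write_raster_stack(st, dir)
  st2 <- read_raster_stack(c(a = file.path(dir, "a.asc"),
                             b = file.path(dir, "b.asc")), binary = "b")
  expect_equal(st2$layers$a, m)
  expect_true(all(st2$layers$b %in% 0:1))
  # mismatched geometry refuses to stack
  bad <- resistance_surface(matrix(1, 10, 10), xll = 0, yll = 0, pixel = 90)
  write_asc(bad, file.path(dir, "c.asc"))
  expect_error(read_raster_stack(c(a = file.path(dir, "a.asc"),
                                   c = file.path(dir, "c.asc"))),
               "co-registered")
  # YAML stack config
  cfg <- file.path(dir, "stack.yml")
  writeLines(c("layers:", "  a: a.asc", "  b: b.asc", "binary: [b]"), cfg)
  st3 <- read_raster_stack(cfg)
  expect_equal(names(st3$layers), c("a", "b"))
})

test_that("GeoJSON polygons round-trip and support point tests", {
  ring <- rbind(c(0, 0), c(1000, 0), c(1000, 800), c(0, 800), c(0, 0))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson_polygon(list(ring), path)
  polys <- read_geojson_polygons(path)
  expect_length(polys, 1L)
  expect_equal(polys[[1L]][[1L]], ring)
  inside <- rescape:::points_in_polygon(polys[[1L]],
                                        rbind(c(500, 400), c(1500, 400)))
  expect_equal(inside, c(TRUE, FALSE))
})
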