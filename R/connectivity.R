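#' Resistant-kernel configuration
#'
#' @param n_sources number of random source locations (default 2000).
#' @param threshold cost-distance threshold in resistance-times-meters units
#'   (default 1,100,000: at a low resistance of 10 this corresponds to a
#'   maximum kernel reach of 110 km).
#' @param normalize_to range the input resistance is rescaled to before
#'   kernels are spread (default c(1, 100)).
#' @param water_resistance resistance assigned to large water bodies
#'   (default 100).
#' @param water_min_area minimum water-body area for the override, m^2
#'   (default 3 km^2).
#' @param seed integer seed for source-point draws.
#' @return object of class `kernel_config`.
#' @export
kernel_config <- function(n_sources = 2000L, threshold = 1100000,
                          normalize_to = c(1, 100), water_resistance = 100,
                          water_min_area = 3e6, seed = 1L) {
  if (threshold <= 0) stop("threshold must be positive")
  if (!(normalize_to[1L] >= 1 && normalize_to[1L] < normalize_to[2L]))
    stop("normalize_to must satisfy 1 <= lo < hi")
  structure(list(n_sources = as.integer(n_sources), threshold = threshold,
                 normalize_to = normalize_to,
                 water_resistance = water_resistance,
                 water_min_area = water_min_area, seed = as.integer(seed)),
            class = "kernel_config")
}

#' Prepare a resistance surface for resistant kernels
#'
#' Linearly rescales the surface to the configured range (default
#' \[1, 100\]) and then overrides pixels covered by water polygons larger
#' than the configured minimum area (default 3 km^2) with the water
#' resistance (default 100). Smaller ponds are left unchanged.
#'
#' @param surface a [resistance_surface()].
#' @param water_polygons list of polygons (each a list of ring matrices),
#'   e.g. from [read_geojson_polygons()]; `NULL` for none.
#' @param cfg a [kernel_config()].
#' @return the prepared [resistance_surface()].
#' @export
prepare_resistance <- function(surface, water_polygons = NULL,
                               cfg = kernel_config()) {
  out <- rescale_surface(surface, cfg$normalize_to[1L], cfg$normalize_to[2L])
  if (length(water_polygons)) {
    geom <- surface_geometry(out)
    idx <- which(!is.na(out$grid))
    rowi <- (idx - 1L) %% geom$nr + 1L
    coli <- (idx - 1L) %/% geom$nr + 1L
    ctr <- cell_xy(geom, rowi, coli)
    for (poly in water_polygons) {
      if (polygon_area(poly[[1L]]) <= cfg$water_min_area) next
      inside <- points_in_polygon(poly, ctr)
      out$grid[idx[inside]] <- cfg$water_resistance
    }
  }
  out$provenance <- paste0(out$provenance, " +water")
  out
}

#' Draw uniform random source points inside a polygon
#'
#' Rejection sampling over the polygon's bounding box.
#'
#' @param polygon a polygon (list of ring matrices, first ring outer).
#' @param n number of points.
#' @param seed integer seed.
#' @return n x 2 matrix of coordinates.
#' @export
draw_source_points <- function(polygon, n, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  ring <- polygon[[1L]]
  if (polygon_area(ring) <= 0) stop("degenerate polygon")
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  xr <- range(ring[, 1L]); yr <- range(ring[, 2L])
  pts <- matrix(NA_real_, 0L, 2L)
  while (nrow(pts) < n) {
    m <- max(2L * (n - nrow(pts)), 64L)
    cand <- cbind(stats::runif(m, xr[1L], xr[2L]),
                  stats::runif(m, yr[1L], yr[2L]))
    keep <- points_in_polygon(polygon, cand)
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Resistant-kernel genetic connectivity map
#'
#' For each source point, accumulated cost distance (Dijkstra on the
#' 8-connected lattice, edge cost = mean resistance of the two cells times
#' center-to-center distance) is computed to every cell; the kernel value
#' is the linear transform `max(0, 1 - cost / threshold)` — 1 at the
#' source, declining to 0 at the cost-distance threshold. Kernels are
#' summed pixel-wise over sources. Wider kernel spread occurs where
#' resistance is low.
#'
#' @param surface a prepared [resistance_surface()] (values >= 1; see
#'   [prepare_resistance()]).
#' @param sources n x 2 matrix of source coordinates (e.g. from
#'   [draw_source_points()]); sources on nodata cells are skipped with a
#'   warning.
#' @param cfg a [kernel_config()].
#' @param graph optional prebuilt [cost_graph()].
#' @return object of class `connectivity_map`: list with `grid` (summed
#'   kernel values, >= 0), geometry fields, `n_sources_used`, and `config`.
#' @export
resistant_kernel_map <- function(surface, sources, cfg = kernel_config(),
                                 graph = NULL) {
  if (any(surface$grid[!is.na(surface$grid)] < 1))
    stop("surface must be prepared (resistance >= 1)")
  cg <- graph %||% cost_graph(surface)
  geom <- cg$geom
  sources <- matrix(as.numeric(sources), ncol = 2L)
  cells <- point_cells(geom, sources)
  on_data <- !is.na(surface$grid[cells])
  if (any(!on_data))
    warning(sum(!on_data), " source(s) on nodata cells skipped")
  cells <- cells[on_data]
  acc <- matrix(0, geom$nr, geom$nc)
  chunk <- 64L
  for (i in if (length(cells)) seq(1L, length(cells), by = chunk) else
       integer(0)) {
    v <- cells[i:min(i + chunk - 1L, length(cells))]
    d <- igraph::distances(cg$graph, v = v)
    k <- 1 - d / cfg$threshold
    k[k < 0] <- 0
    acc <- acc + matrix(colSums(k), geom$nr, geom$nc)
  }
  acc[is.na(surface$grid)] <- NA_real_
  structure(list(grid = acc, xll = surface$xll, yll = surface$yll,
                 pixel = surface$pixel, n_sources_used = length(cells),
                 config = cfg,
                 provenance = paste0("kernels:", surface$provenance)),
            class = c("connectivity_map", "resistance_surface"))
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("connectivity_map: %d x %d @ %g m, %d sources, max %.3g\n",
              nrow(x$grid), ncol(x$grid), x$pixel, x$n_sources_used,
              max(x$grid, na.rm = TRUE)))
  invisible(x)
}

#' Geographic reach of a single-source kernel
#'
#' Helper for calibration checks: the maximum planar distance from the
#' source at which the kernel is still positive.
#'
#' @param surface prepared [resistance_surface()].
#' @param source length-2 coordinate.
#' @param cfg a [kernel_config()].
#' @param graph optional prebuilt [cost_graph()].
#' @return list with `reach_m` (overall) and `reach_axis_m` (along the four
#'   grid axes through the source).
#' @export
kernel_reach <- function(surface, source, cfg = kernel_config(),
                         graph = NULL) {
  cg <- graph %||% cost_graph(surface)
  geom <- cg$geom
  acc <- accumulated_cost(surface, source, graph = cg)
  pos <- which(acc <= cfg$threshold & !is.na(acc), arr.ind = TRUE)
  ctr <- cell_xy(geom, pos[, 1L], pos[, 2L])
  src_rc <- xy_cell(geom, source[1L], source[2L])
  src_ctr <- cell_xy(geom, src_rc[1L, "row"], src_rc[1L, "col"])
  dd <- sqrt((ctr[, 1L] - src_ctr[1L, 1L])^2 + (ctr[, 2L] - src_ctr[1L, 2L])^2)
  on_axis <- pos[, 1L] == src_rc[1L, "row"] | pos[, 2L] == src_rc[1L, "col"]
  list(reach_m = max(dd), reach_axis_m = max(dd[on_axis]))
}
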