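#' Co-registered landscape raster stack
#'
#' A minimal in-memory raster container: named layers as numeric matrices
#' sharing one planar grid. Matrix row 1 is the northernmost row (as in the
#' ASCII-grid on-disk layout); `NA` encodes nodata. Coordinates are meters
#' in an arbitrary projected CRS.
#'
#' @param layers named list of equal-dimension numeric matrices.
#' @param xll,yll coordinates of the lower-left corner of the grid (m).
#' @param pixel pixel size in meters (default 180).
#' @param binary optional character vector naming layers constrained to
#'   values in \{0, 1\}.
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(layers, xll = 0, yll = 0, pixel = 180,
                         binary = NULL) {
  if (!length(layers) || is.null(names(layers)) || any(names(layers) == ""))
    stop("layers must be a non-empty named list")
  dims <- lapply(layers, dim)
  if (length(unique(dims)) != 1L)
    stop("all layers must share the same dimensions")
  for (nm in binary) {
    v <- layers[[nm]]
    if (!all(v %in% c(0, 1, NA)))
      stop("binary layer ", nm, " has values outside {0,1}")
  }
  structure(list(layers = lapply(layers, function(m) {
    storage.mode(m) <- "double"; m
  }), xll = xll, yll = yll, pixel = pixel,
  binary = binary %||% character(0)),
  class = "raster_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$layers[[1L]])
  cat("raster_stack:", length(x$layers), "layers,", d[1L], "x", d[2L],
      "pixels @", x$pixel, "m\n")
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.raster_stack <- function(x) dim(x$layers[[1L]])

#' Single-band resistance (or connectivity) surface
#'
#' @param grid numeric matrix (row 1 = north); `NA` = nodata.
#' @param xll,yll,pixel grid geometry as in [raster_stack()].
#' @param provenance free-form label (model id, iteration, config).
#' @return an object of class `resistance_surface`.
#' @export
resistance_surface <- function(grid, xll = 0, yll = 0, pixel = 180,
                               provenance = "") {
  storage.mode(grid) <- "double"
  structure(list(grid = grid, xll = xll, yll = yll, pixel = pixel,
                 provenance = provenance),
            class = "resistance_surface")
}

#' @export
print.resistance_surface <- function(x, ...) {
  d <- dim(x$grid)
  rng <- range(x$grid, na.rm = TRUE)
  cat(sprintf("resistance_surface: %d x %d @ %g m, range %.3g-%.3g\n",
              d[1L], d[2L], x$pixel, rng[1L], rng[2L]))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

surface_geometry <- function(s) {
  m <- s[["grid"]] %||% s$layers[[1L]]
  list(xll = s$xll, yll = s$yll, pixel = s$pixel,
       nr = nrow(m), nc = ncol(m))
}

# cell (row, col) centers -> x/y and back; row 1 is the top (north) row
cell_xy <- function(geom, row, col) {
  cbind(x = geom$xll + (col - 0.5) * geom$pixel,
        y = geom$yll + (geom$nr - row + 0.5) * geom$pixel)
}

xy_cell <- function(geom, x, y) {
  col <- pmin(pmax(ceiling((x - geom$xll) / geom$pixel), 1L), geom$nc)
  row <- pmin(pmax(geom$nr - ceiling((y - geom$yll) / geom$pixel) + 1L, 1L),
              geom$nr)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read / write a single-band raster as ESRI ASCII grid
#'
#' Plain-text georeferenced raster format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south).
#'
#' @param path file path (conventionally `.asc`).
#' @return `read_asc`: a [resistance_surface()].
#' @export
read_asc <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  for (i in 1:6) {
    ln <- strsplit(trimws(readLines(con, 1L)), "\\s+")[[1L]]
    hdr[[tolower(ln[1L])]] <- as.numeric(ln[2L])
  }
  vals <- scan(con, what = double(), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("ASCII grid size mismatch in ", path)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  resistance_surface(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
                     pixel = hdr$cellsize, provenance = path)
}

#' @rdname read_asc
#' @param surface a [resistance_surface()] (or matrix-bearing layer).
#' @param nodata value written for `NA` cells.
#' @export
write_asc <- function(surface, path, nodata = -9999) {
  m <- surface$grid
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", format(surface$xll, scientific = FALSE)),
           paste("yllcorner", format(surface$yll, scientific = FALSE)),
           paste("cellsize", format(surface$pixel, scientific = FALSE)),
           paste("NODATA_value", nodata))
  m[is.na(m)] <- nodata
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a raster stack from a set of ASCII grids
#'
#' `paths` may be a named character vector of `.asc` files or a YAML config
#' with fields `layers: {name: path}` and optional `binary: [names]`.
#' All grids must share geometry exactly (no implicit resampling); binary
#' layers are validated to contain only \{0, 1\}.
#'
#' @param paths named character vector, or path to a YAML config.
#' @param binary names of binary layers (when `paths` is a vector).
#' @return a [raster_stack()].
#' @export
read_raster_stack <- function(paths, binary = NULL) {
  if (length(paths) == 1L && grepl("\\.ya?ml$", paths)) {
    cfg <- yaml::read_yaml(paths)
    rel <- function(p) if (file.exists(p)) p else file.path(dirname(paths), p)
    binary <- cfg$binary
    paths <- vapply(cfg$layers, rel, character(1))
  }
  if (is.null(names(paths))) stop("layer paths must be named")
  surfs <- lapply(paths, read_asc)
  geo <- lapply(surfs, function(s) c(s$xll, s$yll, s$pixel, dim(s$grid)))
  if (length(unique(geo)) != 1L)
    stop("layer grids are not co-registered; resample before stacking")
  s1 <- surfs[[1L]]
  raster_stack(lapply(surfs, `[[`, "grid"), xll = s1$xll, yll = s1$yll,
               pixel = s1$pixel, binary = binary)
}

#' Write every layer of a stack as ASCII grids
#' @param stack a [raster_stack()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_raster_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- vapply(names(stack$layers), function(nm) {
    write_asc(resistance_surface(stack$layers[[nm]], stack$xll, stack$yll,
                                 stack$pixel),
              file.path(dir, paste0(nm, ".asc")))
  }, character(1))
  invisible(out)
}

#' Read polygons from a GeoJSON file
#'
#' Supports `Polygon` and `MultiPolygon` geometries (in Features,
#' FeatureCollections, or bare geometries). Returns each ring as a closed
#' two-column coordinate matrix; ring orientation is not interpreted, and
#' holes are returned as additional rings.
#'
#' @param path GeoJSON file path.
#' @return list of polygons; each polygon is a list of ring matrices.
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  geoms <- collect_geometries(g)
  out <- list()
  for (gm in geoms) {
    ring_mat <- function(r) do.call(rbind, lapply(r, function(pt)
      c(pt[[1L]], pt[[2L]])))
    if (gm$type == "Polygon") {
      out[[length(out) + 1L]] <- lapply(gm$coordinates, ring_mat)
    } else if (gm$type == "MultiPolygon") {
      for (poly in gm$coordinates)
        out[[length(out) + 1L]] <- lapply(poly, ring_mat)
    }
  }
  out
}

collect_geometries <- function(g) {
  if (is.null(g$type)) return(list())
  switch(g$type,
         FeatureCollection = do.call(c, lapply(g$features, collect_geometries)),
         Feature = collect_geometries(g$geometry),
         list(g))
}

#' Write one polygon (list of rings) as GeoJSON
#' @param rings list of two-column coordinate matrices (first ring = outer).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geojson_polygon <- function(rings, path) {
  coords <- lapply(rings, function(r) lapply(seq_len(nrow(r)), function(i)
    c(r[i, 1L], r[i, 2L])))
  obj <- list(type = "Feature", properties = NULL,
              geometry = list(type = "Polygon", coordinates = coords))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# TRUE for points inside a polygon (list of rings; even-odd rule via mgcv)
points_in_polygon <- function(rings, pts) {
  bnd <- do.call(rbind, lapply(rings, function(r)
    rbind(r, c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  mgcv::in.out(bnd, pts)
}

polygon_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- nrow(ring)
  if (x[1L] != x[n] || y[1L] != y[n]) { x <- c(x, x[1L]); y <- c(y, y[1L]) }
  abs(sum(x[-length(x)] * y[-1L] - x[-1L] * y[-length(y)])) / 2
}
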