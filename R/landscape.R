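#' Enumerate unordered sample pairs with a minimum separation
#'
#' All unordered pairs of samples whose planar distance is at least
#' `min_separation` meters; pairs of highly clustered samples can thereby be
#' excluded (e.g., a 3-km floor to damp noise from near-duplicate locations).
#'
#' @param table a [genotype_table()] (anything with `id`, `x`, `y`).
#' @param min_separation minimum pair distance in meters (default 0).
#' @return data.frame with `id1`, `id2`, `geo_m` (one row per unordered pair).
#' @export
build_pairs <- function(table, min_separation = 0) {
  n <- length(table$id)
  d <- as.matrix(stats::dist(cbind(table$x, table$y)))
  ij <- which(lower.tri(d), arr.ind = TRUE)
  out <- data.frame(id1 = table$id[ij[, 2L]], id2 = table$id[ij[, 1L]],
                    geo_m = d[ij], stringsAsFactors = FALSE)
  out[out$geo_m >= min_separation, , drop = FALSE]
}

# membership test for the buffered transect of a polyline, with a signed
# margin m: flat caps extend the segment rectangles, round joins cover
# interior vertices; round_caps additionally covers the two end vertices.
transect_membership <- function(pts, poly, buffer, m = 0, round_caps = FALSE) {
  inside <- rep(FALSE, nrow(pts))
  nseg <- nrow(poly) - 1L
  for (s in seq_len(nseg)) {
    p1 <- poly[s, ]; p2 <- poly[s + 1L, ]
    dx <- p2[1L] - p1[1L]; dy <- p2[2L] - p1[2L]
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) next
    ux <- dx / len; uy <- dy / len
    rx <- pts[, 1L] - p1[1L]; ry <- pts[, 2L] - p1[2L]
    tt <- rx * ux + ry * uy
    dd <- abs(rx * uy - ry * ux)
    inside <- inside | (tt >= -m & tt <= len + m & dd <= buffer + m)
  }
  verts <- if (round_caps) seq_len(nrow(poly)) else
    seq_len(nrow(poly))[-c(1L, nrow(poly))]
  for (v in verts) {
    dv <- sqrt((pts[, 1L] - poly[v, 1L])^2 + (pts[, 2L] - poly[v, 2L])^2)
    inside <- inside | dv <= buffer + m
  }
  inside
}

# Sutherland-Hodgman clip of a polygon by the half-plane nx*x + ny*y <= cc
clip_halfplane <- function(xs, ys, nx, ny, cc) {
  n <- length(xs)
  if (!n) return(list(x = xs, y = ys))
  d <- nx * xs + ny * ys - cc
  ox <- numeric(2L * n); oy <- numeric(2L * n); k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (d[i] <= 0) { k <- k + 1L; ox[k] <- xs[i]; oy[k] <- ys[i] }
    if ((d[i] <= 0) != (d[j] <= 0)) {
      t <- d[i] / (d[i] - d[j])
      k <- k + 1L
      ox[k] <- xs[i] + t * (xs[j] - xs[i])
      oy[k] <- ys[i] + t * (ys[j] - ys[i])
    }
  }
  list(x = ox[seq_len(k)], y = oy[seq_len(k)])
}

# exact fraction of a pixel square covered by the corridor rectangle of a
# single segment (flat caps)
rect_pixel_fraction <- function(cx, cy, half, p1, ux, uy, len, buffer) {
  planes <- rbind(c(-ux, -uy, -(ux * p1[1L] + uy * p1[2L])),
                  c(ux, uy, ux * p1[1L] + uy * p1[2L] + len),
                  c(-uy, ux, -uy * p1[1L] + ux * p1[2L] + buffer),
                  c(uy, -ux, uy * p1[1L] - ux * p1[2L] + buffer))
  xs <- c(cx - half, cx + half, cx + half, cx - half)
  ys <- c(cy - half, cy - half, cy + half, cy + half)
  for (p in seq_len(4L)) {
    cl <- clip_halfplane(xs, ys, planes[p, 1L], planes[p, 2L], planes[p, 3L])
    xs <- cl$x; ys <- cl$y
    if (length(xs) < 3L) return(0)
  }
  n <- length(xs)
  j <- c(2:n, 1L)
  abs(sum(xs * ys[j] - xs[j] * ys)) / 2 / (2 * half)^2
}

#' Coverage-weighted landscape means along a buffered transect
#'
#' Buffers a straight line or polyline by `buffer` meters into a corridor
#' polygon (flat end caps by default: the corridor covers only the area
#' between the endpoints) and returns, for every layer of the stack, the
#' coverage-weighted mean of the pixels it intersects. Partial pixels are
#' weighted by intersected area, estimated on a `subdiv` x `subdiv` subgrid
#' of each boundary pixel; interior pixels get full weight. For binary
#' layers the mean is the proportion of the corridor covered by the class.
#' Nodata pixels are excluded from a layer's weights.
#'
#' @param stack a [raster_stack()].
#' @param geometry two-column coordinate matrix: 2 rows for a straight line,
#'   more for a least-cost-path polyline.
#' @param buffer half-width of the corridor in meters (default 500).
#' @param subdiv boundary-pixel subdivision factor (default 8).
#' @param round_caps use round end caps instead of flat (default FALSE).
#' @param method `"exact"` (polygon clipping of boundary pixels; straight
#'   lines with flat caps only), `"subgrid"`, or `"auto"` (default: exact
#'   where available).
#' @return named numeric vector of per-layer means, with attributes `area`
#'   (sum of coverage weights, in m^2) and `cells` (data.frame of `row`,
#'   `col`, `w`).
#' @export
extract_transect_means <- function(stack, geometry, buffer = 500, subdiv = 8L,
                                   round_caps = FALSE,
                                   method = c("auto", "exact", "subgrid")) {
  if (buffer <= 0) stop("buffer must be positive")
  method <- match.arg(method)
  poly <- as.matrix(geometry)
  if (ncol(poly) != 2L || nrow(poly) < 2L)
    stop("geometry must be a 2-column matrix with at least 2 points")
  exact_ok <- nrow(poly) == 2L && !round_caps
  if (method == "exact" && !exact_ok)
    stop("exact coverage is available only for straight lines with flat caps")
  use_exact <- exact_ok && method != "subgrid"
  geom <- surface_geometry(stack)
  px <- geom$pixel
  half_diag <- px * sqrt(2) / 2
  pad <- buffer + px
  rc_min <- xy_cell(geom, max(min(poly[, 1L]) - pad, geom$xll + px / 2),
                    max(min(poly[, 2L]) - pad, geom$yll + px / 2))
  rc_max <- xy_cell(geom, min(max(poly[, 1L]) + pad,
                              geom$xll + (geom$nc - 0.5) * px),
                    min(max(poly[, 2L]) + pad,
                        geom$yll + (geom$nr - 0.5) * px))
  rows <- rc_max[1L, "row"]:rc_min[1L, "row"]
  cols <- rc_min[1L, "col"]:rc_max[1L, "col"]
  grid <- expand.grid(row = rows, col = cols)
  centers <- cell_xy(geom, grid$row, grid$col)
  outer_in <- transect_membership(centers, poly, buffer, m = half_diag,
                                  round_caps = round_caps)
  if (!any(outer_in))
    stop("transect does not intersect the raster extent")
  grid <- grid[outer_in, , drop = FALSE]
  centers <- centers[outer_in, , drop = FALSE]
  inner_in <- transect_membership(centers, poly, buffer, m = -half_diag,
                                  round_caps = round_caps)
  w <- as.numeric(inner_in)
  bnd <- which(!inner_in)
  if (length(bnd)) {
    if (use_exact) {
      dxy <- poly[2L, ] - poly[1L, ]
      len <- sqrt(sum(dxy^2))
      ux <- dxy[1L] / len; uy <- dxy[2L] / len
      w[bnd] <- vapply(bnd, function(i)
        rect_pixel_fraction(centers[i, 1L], centers[i, 2L], px / 2,
                            poly[1L, ], ux, uy, len, buffer),
        numeric(1))
    } else {
      s <- subdiv
      off <- (seq_len(s) - 0.5) / s - 0.5
      sub_off <- as.matrix(expand.grid(dx = off * px, dy = off * px))
      sub_pts <- cbind(rep(centers[bnd, 1L], each = s * s) + sub_off[, 1L],
                       rep(centers[bnd, 2L], each = s * s) + sub_off[, 2L])
      sub_in <- transect_membership(sub_pts, poly, buffer, m = 0,
                                    round_caps = round_caps)
      frac <- colMeans(matrix(sub_in, s * s, length(bnd)))
      w[bnd] <- frac
    }
  }
  keep <- w > 0
  grid <- grid[keep, , drop = FALSE]
  w <- w[keep]
  idx <- cbind(grid$row, grid$col)
  means <- vapply(stack$layers, function(mlay) {
    v <- mlay[idx]
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * v[ok]) / sum(w[ok])
  }, numeric(1))
  attr(means, "area") <- sum(w) * px^2
  attr(means, "cells") <- data.frame(row = grid$row, col = grid$col, w = w)
  means
}

#' Build the weighted 8-connected lattice graph of a resistance surface
#'
#' Cells are graph vertices; each cell is connected to its 8 neighbors with
#' edge cost `mean(resistance of the two cells) * center-to-center distance`
#' (diagonal distance is `pixel * sqrt(2)`). Nodata cells carry no edges.
#' Build once and reuse across [least_cost_path()] / [cost_distances()]
#' calls on the same surface.
#'
#' @param surface a [resistance_surface()] with positive resistance values.
#' @return an object of class `cost_graph`.
#' @export
cost_graph <- function(surface) {
  r <- surface$grid
  if (any(r[!is.na(r)] <= 0)) stop("resistance must be positive everywhere")
  nr <- nrow(r); nc <- ncol(r)
  px <- surface$pixel
  id <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list(); weights <- list(); k <- 0L
  add <- function(fr, to, dist) {
    ok <- !is.na(r[fr]) & !is.na(r[to])
    k <<- k + 1L
    edges[[k]] <<- rbind(fr[ok], to[ok])
    weights[[k]] <<- (r[fr][ok] + r[to][ok]) / 2 * dist
  }
  if (nc > 1L) add(as.vector(id[, -nc]), as.vector(id[, -1L]), px)
  if (nr > 1L) add(as.vector(id[-nr, ]), as.vector(id[-1L, ]), px)
  if (nr > 1L && nc > 1L) {
    add(as.vector(id[-nr, -nc]), as.vector(id[-1L, -1L]), px * sqrt(2))
    add(as.vector(id[-1L, -nc]), as.vector(id[-nr, -1L]), px * sqrt(2))
  }
  g <- igraph::make_graph(as.vector(do.call(cbind, edges)), n = nr * nc,
                          directed = FALSE)
  igraph::E(g)$weight <- unlist(weights)
  structure(list(graph = g, geom = surface_geometry(surface)),
            class = "cost_graph")
}

point_cells <- function(geom, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  rc <- xy_cell(geom, pts[, 1L], pts[, 2L])
  (rc[, "col"] - 1L) * geom$nr + rc[, "row"]
}

#' Least-cost path between two points
#'
#' Minimum accumulated-cost route on the 8-connected pixel graph of a
#' resistance surface. Points are snapped to their containing pixel centers.
#'
#' @param surface a [resistance_surface()] (ignored if `graph` is given
#'   except for geometry checks).
#' @param src,dst length-2 numeric coordinates (meters).
#' @param graph optional prebuilt [cost_graph()] for the surface.
#' @return list with `path` (polyline of cell centers, two-column matrix),
#'   `cost` (accumulated cost), `n_cells`.
#' @export
least_cost_path <- function(surface, src, dst, graph = NULL) {
  cg <- graph %||% cost_graph(surface)
  geom <- cg$geom
  v <- point_cells(geom, rbind(src, dst))
  if (anyNA(cg_value(surface, v)))
    stop("src/dst fall on nodata cells")
  if (v[1L] == v[2L]) {
    ctr <- cell_xy(geom, (v[1L] - 1L) %% geom$nr + 1L,
                   (v[1L] - 1L) %/% geom$nr + 1L)
    return(list(path = rbind(ctr, ctr), cost = 0, n_cells = 1L))
  }
  sp <- igraph::shortest_paths(cg$graph, from = v[1L], to = v[2L],
                               output = "vpath")
  vp <- as.integer(sp$vpath[[1L]])
  if (length(vp) < 2L) stop("destination unreachable (nodata barrier)")
  cost <- igraph::distances(cg$graph, v = v[1L], to = v[2L])[1L, 1L]
  rowi <- (vp - 1L) %% geom$nr + 1L
  coli <- (vp - 1L) %/% geom$nr + 1L
  list(path = cell_xy(geom, rowi, coli), cost = cost, n_cells = length(vp))
}

cg_value <- function(surface, cells) {
  if (is.null(surface)) return(rep(1, length(cells)))
  surface$grid[cells]
}

#' Pairwise accumulated cost distances between points
#'
#' @param surface a [resistance_surface()].
#' @param pts two-column coordinate matrix.
#' @param graph optional prebuilt [cost_graph()].
#' @return symmetric matrix of accumulated costs (`Inf` if unreachable).
#' @export
cost_distances <- function(surface, pts, graph = NULL) {
  cg <- graph %||% cost_graph(surface)
  v <- point_cells(cg$geom, pts)
  uv <- unique(v)
  du <- igraph::distances(cg$graph, v = uv, to = uv)
  d <- du[match(v, uv), match(v, uv), drop = FALSE]
  dimnames(d) <- list(rownames(pts), rownames(pts))
  d
}

#' Accumulated cost from one source cell to every cell
#'
#' @param surface a [resistance_surface()].
#' @param src length-2 numeric coordinate.
#' @param graph optional prebuilt [cost_graph()].
#' @return matrix of accumulated cost with the surface's geometry
#'   (`Inf` where unreachable, `NA` on nodata cells).
#' @export
accumulated_cost <- function(surface, src, graph = NULL) {
  cg <- graph %||% cost_graph(surface)
  v <- point_cells(cg$geom, matrix(src, ncol = 2L))
  d <- igraph::distances(cg$graph, v = v)[1L, ]
  m <- matrix(d, cg$geom$nr, cg$geom$nc)
  m[is.na(surface$grid)] <- NA_real_
  m
}

#' Assemble a pair table of transect means
#'
#' For each pair, extracts coverage-weighted layer means along either the
#' straight line between the two sample locations or a supplied least-cost
#' polyline, and binds them to the pair's geographic distance.
#'
#' @param stack a [raster_stack()].
#' @param table sample table with `id`, `x`, `y`.
#' @param pairs data.frame from [build_pairs()].
#' @param buffer corridor half-width in meters (default 500).
#' @param paths optional list (one per pair row) of polyline matrices; when
#'   `NULL`, straight lines are used.
#' @param subdiv boundary-pixel subdivision passed to
#'   [extract_transect_means()].
#' @param method coverage method for boundary pixels (default `"subgrid"`:
#'   fast approximate partial-pixel weights, adequate for bulk model
#'   inputs; `"auto"`/`"exact"` as in [extract_transect_means()]).
#' @return the `pairs` data.frame with one added numeric column per layer.
#' @export
pair_transect_table <- function(stack, table, pairs, buffer = 500,
                                paths = NULL, subdiv = 4L,
                                method = "subgrid") {
  i1 <- match(pairs$id1, table$id)
  i2 <- match(pairs$id2, table$id)
  if (anyNA(i1) || anyNA(i2)) stop("pair ids not found in sample table")
  vals <- matrix(NA_real_, nrow(pairs), length(stack$layers),
                 dimnames = list(NULL, names(stack$layers)))
  for (k in seq_len(nrow(pairs))) {
    geometry <- if (is.null(paths)) {
      rbind(c(table$x[i1[k]], table$y[i1[k]]),
            c(table$x[i2[k]], table$y[i2[k]]))
    } else paths[[k]]
    vals[k, ] <- extract_transect_means(stack, geometry, buffer,
                                        subdiv = subdiv, method = method)
  }
  cbind(pairs, as.data.frame(vals))
}
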