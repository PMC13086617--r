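#' Scenario truth for synthetic landscape-genetics data
#'
#' Fully serializable description of a synthetic study: landscape geometry,
#' the true resistance function (named layer coefficients on 0-1 scaled
#' layers, applied inside an exponential), the spatial genetic neighborhood
#' scale, locus spec, sampling design, and nuisance rates. Regenerating any
#' artifact from the same truth and seed is byte-identical.
#'
#' Defaults mirror the study conditions the package is designed around:
#' 116 individuals at 14 microsatellite loci with 4-11 alleles and 1%
#' missing genotypes, samples clustered along road corridors (85% within
#' 500 m of a major road), a 0.87 colluvial-slope correlation target, and a
#' landscape of 300 x 300 pixels at 180 m.
#'
#' @param n_individuals number of sampled individuals (default 116).
#' @param n_loci number of microsatellite loci (default 14).
#' @param allele_range per-locus allele count range (default 4:11).
#' @param nr,nc,pixel landscape grid size and pixel size in meters.
#' @param resistance_coefs named non-negative coefficients of the true
#'   resistance function `R = 1 + sum(coef * layer01)`; names must be
#'   generated layers.
#' @param colluvial_slope_cor target colluvial-slope correlation.
#' @param neighborhood_scale true spatial genetic neighborhood scale (m):
#'   the distance over which allele-frequency fields turn over.
#' @param cline_strength standard deviation of the per-allele log-frequency
#'   fields (default 2.4); 0 gives panmixia.
#' @param n_decoys number of pure-noise decoy layers (default 8).
#' @param n_clusters number of sampling clusters along roads (default 4).
#' @param road_bias fraction of samples placed on road corridors
#'   (default 0.85).
#' @param missing_rate per-genotype missing probability (default 0.01).
#' @param seed integer seed stored with the truth.
#' @return object of class `scenario_truth`.
#' @export
scenario_truth <- function(n_individuals = 116L, n_loci = 14L,
                           allele_range = c(4L, 11L),
                           nr = 300L, nc = 300L, pixel = 180,
                           resistance_coefs = c(colluvial = 3,
                                                slope = 10, roads = 4),
                           colluvial_slope_cor = 0.87,
                           neighborhood_scale = 15000,
                           cline_strength = 2.4,
                           n_decoys = 8L, n_clusters = 4L,
                           road_bias = 0.85, missing_rate = 0.01,
                           seed = 1L) {
  structure(list(n_individuals = as.integer(n_individuals),
                 n_loci = as.integer(n_loci),
                 allele_range = as.integer(allele_range),
                 nr = as.integer(nr), nc = as.integer(nc), pixel = pixel,
                 resistance_coefs = resistance_coefs,
                 colluvial_slope_cor = colluvial_slope_cor,
                 neighborhood_scale = neighborhood_scale,
                 cline_strength = cline_strength,
                 n_decoys = as.integer(n_decoys),
                 n_clusters = as.integer(n_clusters),
                 road_bias = road_bias, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "scenario_truth")
}

#' Serialize / deserialize a scenario truth as JSON
#' @param truth a [scenario_truth()].
#' @param path JSON file path.
#' @return `write_scenario_truth`: `path` invisibly;
#'   `read_scenario_truth`: the truth object.
#' @export
write_scenario_truth <- function(truth, path) {
  x <- unclass(truth)
  x$resistance_coefs <- as.list(x$resistance_coefs) # keep layer names
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_truth
#' @export
read_scenario_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$resistance_coefs <- unlist(x$resistance_coefs)
  do.call(scenario_truth, x)
}

# smooth standardized Gaussian random field via FFT (periodic boundary)
gaussian_field <- function(nr, nc, range_px) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  dr <- pmin(0:(nr - 1L), nr - 0:(nr - 1L))
  dc <- pmin(0:(nc - 1L), nc - 0:(nc - 1L))
  K <- exp(-outer(dr^2, dc^2, "+") / (2 * range_px^2))
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(K), inverse = TRUE))
  f <- f / (nr * nc)
  (f - mean(f)) / stats::sd(f)
}

scale01 <- function(m) {
  rng <- range(m, na.rm = TRUE)
  if (rng[1L] == rng[2L]) return(m * 0)
  (m - rng[1L]) / (rng[2L] - rng[1L])
}

# greedy valley-following road: from one edge to the other, stepping to the
# lowest-terrain neighbor ahead
road_path <- function(z, start, horizontal = TRUE, wobble = 0.05) {
  nr <- nrow(z); nc <- ncol(z)
  len <- if (horizontal) nc else nr
  cells <- matrix(0L, len, 2L)
  r <- start
  for (j in seq_len(len)) {
    cells[j, ] <- if (horizontal) c(r, j) else c(j, r)
    if (j < len) {
      lim <- if (horizontal) nr else nc
      rs <- unique(pmin(pmax(r + (-1:1), 1L), lim))
      vals <- if (horizontal) z[rs, j + 1L] else z[j + 1L, rs]
      r <- rs[which.min(vals + stats::rnorm(length(rs), 0, wobble))]
    }
  }
  cells
}

#' Generate a synthetic landscape raster stack
#'
#' Builds a co-registered stack emulating the structure of real covariates:
#' a smooth terrain field drives slope (sigmoid of terrain, in degrees),
#' colluvial parent material (high-terrain indicator, correlation with
#' slope tuned toward the truth's target), organic / fluvial / lacustrine
#' materials (valley-bottom indicators, anti-correlated with slope), water
#' bodies (blobs of an independent field), major roads (valley-following
#' polylines, 1 pixel wide), annual snowfall (latitudinal gradient plus
#' terrain), and pure-noise decoy layers. If the achieved colluvial-slope
#' correlation misses the target by more than 0.1 a warning reports the
#' achieved value.
#'
#' @param truth a [scenario_truth()].
#' @param seed integer seed (default: the truth's seed).
#' @return a [raster_stack()] with attribute `road_cells` (row/col matrix).
#' @export
generate_landscape <- function(truth, seed = truth$seed) {
  if (truth$nr < 100L || truth$nc < 100L)
    stop("landscape extent must be at least 100 x 100 pixels")
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  nr <- truth$nr; nc <- truth$nc
  z <- gaussian_field(nr, nc, range_px = 12)
  eps <- lapply(1:4, function(i) gaussian_field(nr, nc, range_px = 6))
  cthr <- stats::quantile(z, 0.70)
  # slope follows the terrain but carries its own component: real slope is
  # correlated with, not determined by, the soil parent-material map
  zs <- 0.95 * z + 0.312 * gaussian_field(nr, nc, range_px = 9)
  slope <- 35 * stats::pnorm((zs - stats::quantile(zs, 0.70)) / 0.45)
  colluvial <- (z + 0.10 * eps[[1L]] > cthr) * 1
  organic <- (z + 0.30 * eps[[2L]] < stats::quantile(z, 0.25)) * 1
  fluvial <- (z + 0.30 * eps[[3L]] < stats::quantile(z, 0.15)) * 1
  lacustrine <- (z + 0.30 * eps[[4L]] < stats::quantile(z, 0.06)) * 1
  w <- gaussian_field(nr, nc, range_px = 8)
  water <- (w > stats::quantile(w, 0.97)) * 1
  roads <- matrix(0, nr, nc)
  starts_h <- round(nr * c(0.3, 0.7))
  starts_v <- round(nc * 0.5)
  road_cells <- rbind(
    do.call(rbind, lapply(starts_h, function(s) road_path(z, s, TRUE))),
    do.call(rbind, lapply(starts_v, function(s) road_path(z, s, FALSE))))
  # three pixels wide (~540 m corridor)
  road_cells <- rbind(road_cells,
                      cbind(pmin(road_cells[, 1L] + 1L, nr), road_cells[, 2L]),
                      cbind(pmax(road_cells[, 1L] - 1L, 1L), road_cells[, 2L]))
  roads[road_cells] <- 1
  snow <- 40 * scale01(1.2 * matrix((nr:1) / nr, nr, nc) +
                         0.8 * scale01(z) +
                         0.5 * scale01(gaussian_field(nr, nc, 15))) + 5
  layers <- list(slope = slope, colluvial = colluvial, organic = organic,
                 fluvial = fluvial, lacustrine = lacustrine, water = water,
                 roads = roads, snow = snow)
  for (i in seq_len(truth$n_decoys)) # decoys: pure per-pixel noise
    layers[[paste0("decoy", i)]] <- matrix(stats::runif(nr * nc), nr, nc)
  achieved <- stats::cor(as.vector(colluvial), as.vector(slope))
  if (abs(achieved - truth$colluvial_slope_cor) > 0.1)
    warning(sprintf("colluvial-slope correlation target %.2f not reached; achieved %.2f",
                    truth$colluvial_slope_cor, achieved))
  out <- raster_stack(layers, xll = 0, yll = 0, pixel = truth$pixel,
                      binary = c("colluvial", "organic", "fluvial",
                                 "lacustrine", "water", "roads"))
  attr(out, "road_cells") <- road_cells
  attr(out, "colluvial_slope_cor") <- achieved
  out
}

#' True resistance surface of a synthetic scenario
#'
#' Deterministic map `R = 1 + sum_v coef_v * layer01_v` over the truth's
#' named coefficients, with continuous layers scaled to 0-1 first (binary
#' layers are unchanged by the scaling). The linear form keeps resistance
#' on the conventional 1-to-low-tens scale used for cost-distance
#' calibration. Positive everywhere (coefficients must be >= 0); all-zero
#' coefficients give a uniform surface.
#'
#' @param stack a [raster_stack()] from [generate_landscape()].
#' @param truth a [scenario_truth()].
#' @return a [resistance_surface()].
#' @export
true_resistance <- function(stack, truth) {
  coefs <- truth$resistance_coefs
  if (any(coefs < 0)) stop("resistance coefficients must be non-negative")
  miss <- setdiff(names(coefs), names(stack$layers))
  if (length(miss)) stop("truth names absent from stack: ",
                         paste(miss, collapse = ", "))
  geom <- surface_geometry(stack)
  lin <- matrix(1, geom$nr, geom$nc)
  for (v in names(coefs)) lin <- lin + coefs[[v]] * scale01(stack$layers[[v]])
  resistance_surface(lin, xll = stack$xll, yll = stack$yll,
                     pixel = stack$pixel, provenance = "true_resistance")
}

# planar distance from points to the nearest road cell center
distance_to_roads <- function(stack, pts) {
  rc <- attr(stack, "road_cells")
  if (is.null(rc)) rc <- which(stack$layers$roads == 1, arr.ind = TRUE)
  geom <- surface_geometry(stack)
  ctr <- cell_xy(geom, rc[, 1L], rc[, 2L])
  apply(pts, 1L, function(p)
    sqrt(min((ctr[, 1L] - p[1L])^2 + (ctr[, 2L] - p[2L])^2)))
}

#' Simulate sample locations
#'
#' Roadside-biased mode emulates opportunistic (road-mortality) sampling:
#' a fixed fraction of samples sits on road pixels, clustered around
#' well-separated cluster centers on the road network with uneven cluster
#' sizes; the rest scatter around the same centers on non-water pixels.
#' Uniform mode draws uniformly over non-water pixels. Coordinates are
#' jittered uniformly within their pixel.
#'
#' @param stack a [raster_stack()] from [generate_landscape()].
#' @param truth a [scenario_truth()].
#' @param mode `"roadside"` (default) or `"uniform"`.
#' @param cluster_sd within-cluster spread in meters (default 6000).
#' @param seed integer seed.
#' @return data.frame with `id`, `x`, `y`, `cluster`.
#' @export
simulate_sample_locations <- function(stack, truth, mode = c("roadside",
                                                             "uniform"),
                                      cluster_sd = 6000, seed = truth$seed) {
  mode <- match.arg(mode)
  old <- .Random.seed_guard(seed + 1L)
  on.exit(old(), add = TRUE)
  geom <- surface_geometry(stack)
  n <- truth$n_individuals
  px <- geom$pixel
  water <- stack$layers$water
  elig <- which(water == 0, arr.ind = TRUE)
  if (n > nrow(elig)) stop("more samples than eligible pixels")
  jitter_xy <- function(rc) {
    ctr <- cell_xy(geom, rc[, 1L], rc[, 2L])
    ctr + matrix(stats::runif(2L * nrow(rc), -px / 2, px / 2), ncol = 2L)
  }
  if (mode == "uniform") {
    rc <- elig[sample.int(nrow(elig), n), , drop = FALSE]
    xy <- jitter_xy(rc)
    return(data.frame(id = sprintf("S%03d", seq_len(n)), x = xy[, 1L],
                      y = xy[, 2L], cluster = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  rc_road <- attr(stack, "road_cells")
  if (is.null(rc_road)) rc_road <- which(stack$layers$roads == 1,
                                         arr.ind = TRUE)
  rc_road <- rc_road[water[rc_road] == 0, , drop = FALSE]
  road_ctr <- cell_xy(geom, rc_road[, 1L], rc_road[, 2L])
  # well-separated cluster centers on the road network (farthest-point)
  k <- truth$n_clusters
  centers <- sample.int(nrow(road_ctr), 1L)
  while (length(centers) < k) {
    dmin <- rep(Inf, nrow(road_ctr))
    for (cc in centers) {
      dmin <- pmin(dmin, (road_ctr[, 1L] - road_ctr[cc, 1L])^2 +
                     (road_ctr[, 2L] - road_ctr[cc, 2L])^2)
    }
    centers <- c(centers, which.max(dmin))
  }
  sizes <- as.vector(stats::rmultinom(1L, n,
                                      prob = stats::runif(k, 0.4, 1.6)))
  while (any(sizes < 2L)) {
    i <- which.min(sizes); j <- which.max(sizes)
    sizes[i] <- sizes[i] + 1L; sizes[j] <- sizes[j] - 1L
  }
  n_on_road <- round(truth$road_bias * n)
  on_road <- rep(FALSE, n)
  on_road[sample.int(n, n_on_road)] <- TRUE
  elig_ctr <- cell_xy(geom, elig[, 1L], elig[, 2L])
  rows <- list()
  idx <- 0L
  for (ci in seq_len(k)) {
    ctr <- road_ctr[centers[ci], ]
    w_road <- exp(-((road_ctr[, 1L] - ctr[1L])^2 +
                      (road_ctr[, 2L] - ctr[2L])^2) / (2 * cluster_sd^2))
    w_any <- exp(-((elig_ctr[, 1L] - ctr[1L])^2 +
                     (elig_ctr[, 2L] - ctr[2L])^2) / (2 * cluster_sd^2))
    for (s in seq_len(sizes[ci])) {
      idx <- idx + 1L
      if (on_road[idx]) {
        pick <- sample.int(nrow(rc_road), 1L, prob = w_road)
        # scatter road-associated samples a cell or two off the road line
        # (collected near, not on, the carriageway)
        rc1 <- rc_road[pick, ] + c(sample(-2:2, 1L), sample(-2:2, 1L))
        rc1 <- pmin(pmax(rc1, 1L), c(geom$nr, geom$nc))
        if (water[rc1[1L], rc1[2L]] == 1) rc1 <- rc_road[pick, ]
        rows[[idx]] <- c(rc1, ci)
      } else {
        pick <- sample.int(nrow(elig), 1L, prob = w_any)
        rows[[idx]] <- c(elig[pick, ], ci)
      }
    }
  }
  rc <- do.call(rbind, rows)
  xy <- jitter_xy(rc[, 1:2, drop = FALSE])
  data.frame(id = sprintf("S%03d", seq_len(n)), x = xy[, 1L], y = xy[, 2L],
             cluster = rc[, 3L], stringsAsFactors = FALSE)
}

#' Simulate genotypes with isolation-by-resistance structure
#'
#' Phenomenological cline-on-cost-distance construction: pairwise
#' accumulated cost distances through the *true* resistance surface are
#' embedded by metric multidimensional scaling into two latent axes; each
#' allele's log-frequency is a smooth stationary random field over those
#' axes (a random-Fourier-feature Gaussian process) whose correlation
#' length is the true neighborhood scale expressed in cost units (the
#' geographic scale times the median resistance, i.e. movement through
#' typical valley terrain). Allele frequencies therefore turn over across
#' one neighborhood scale: individuals closer in cost distance than the
#' scale share allele pools, individuals beyond it are decorrelated.
#' Genotypes are two independent draws from the local frequencies (local
#' Hardy-Weinberg equilibrium). With `cline_strength = 0` all individuals
#' share one allele pool (panmixia).
#'
#' @param locations data.frame from [simulate_sample_locations()].
#' @param surface the true [resistance_surface()].
#' @param truth a [scenario_truth()].
#' @param seed integer seed.
#' @param graph optional prebuilt [cost_graph()] of `surface`.
#' @return a [genotype_table()] (with `region` = cluster label).
#' @export
simulate_genotypes <- function(locations, surface, truth,
                               seed = truth$seed, graph = NULL) {
  D <- cost_distances(surface, cbind(locations$x, locations$y),
                      graph = graph)
  if (any(!is.finite(D))) stop("non-finite cost distance: unreachable sample")
  old <- .Random.seed_guard(seed + 2L)
  on.exit(old(), add = TRUE)
  n <- nrow(D)
  u <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = 2L))
  if (ncol(u) < 2L) u <- cbind(u, 0)
  # correlation length of the allele fields, in cost units; the 0.55 factor
  # calibrates the declared neighborhood scale to the distance where the
  # genetic correlogram of generated data crosses zero
  s_cost <- 0.55 * truth$neighborhood_scale *
    stats::median(surface$grid, na.rm = TRUE)
  arange <- truth$allele_range
  n_rff <- 8L # random Fourier features per allele field
  genotypes <- vector("list", truth$n_loci)
  for (l in seq_len(truth$n_loci)) {
    A <- sample(seq(arange[1L], arange[2L]), 1L)
    alpha <- stats::rnorm(A, 0, 0.3)
    eta <- matrix(alpha, n, A, byrow = TRUE)
    if (truth$cline_strength > 0) {
      for (i in seq_len(A)) {
        W <- matrix(stats::rnorm(2L * n_rff, 0, 1 / s_cost), n_rff, 2L)
        phi <- stats::runif(n_rff, 0, 2 * pi)
        proj <- u %*% t(W) + matrix(phi, n, n_rff, byrow = TRUE)
        eta[, i] <- eta[, i] +
          truth$cline_strength * sqrt(2 / n_rff) * rowSums(cos(proj))
      }
    }
    p <- exp(eta - apply(eta, 1L, max))
    p <- p / rowSums(p)
    lab <- sprintf("%02d", seq_len(A) * 2 + 100) # length-polymorphism style
    draw <- function() lab[apply(p, 1L, function(pr)
      sample.int(A, 1L, prob = pr))]
    gm <- cbind(draw(), draw())
    if (truth$missing_rate > 0) {
      gone <- stats::runif(n) < truth$missing_rate
      gm[gone, ] <- NA_character_
    }
    genotypes[[l]] <- gm
  }
  names(genotypes) <- sprintf("loc%02d", seq_len(truth$n_loci))
  genotype_table(id = locations$id, x = locations$x, y = locations$y,
                 genotypes = genotypes,
                 region = as.character(locations$cluster))
}

#' Generate a complete synthetic scenario
#'
#' Landscape, true resistance, sample locations, and genotypes in one call.
#'
#' @param truth a [scenario_truth()].
#' @param seed integer seed (default: the truth's seed).
#' @return list with `stack`, `surface` (true resistance), `locations`,
#'   `table` (genotype table), `truth`, `graph` (cost graph of the true
#'   surface).
#' @export
simulate_scenario <- function(truth = scenario_truth(), seed = truth$seed) {
  truth$seed <- as.integer(seed)
  stack <- generate_landscape(truth, seed)
  surface <- true_resistance(stack, truth)
  locations <- simulate_sample_locations(stack, truth, seed = seed)
  graph <- cost_graph(surface)
  table <- simulate_genotypes(locations, surface, truth, seed = seed,
                              graph = graph)
  list(stack = stack, surface = surface, locations = locations,
       table = table, truth = truth, graph = graph)
}
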