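# Shared fixtures and independent oracles used across the suite.

# small genotype table built by hand; alleles are arbitrary labels
toy_table <- function() {
  genotype_table(
    id = c("a", "b", "c"), x = c(0, 1000, 2000), y = c(0, 0, 0),
    genotypes = list(
      L1 = rbind(c("A", "A"), c("A", "B"), c("B", "B")),
      L2 = rbind(c("A", "B"), c("A", "B"), c("A", "A"))))
}

# random diploid table under global Hardy-Weinberg (panmixia), no missing
random_hwe_table <- function(n, n_loci = 5L, n_alleles = 4L, seed = 1L) {
  set.seed(seed)
  genotypes <- lapply(seq_len(n_loci), function(l) {
    p <- as.numeric(stats::rgamma(n_alleles, 2))
    p <- p / sum(p)
    lab <- LETTERS[seq_len(n_alleles)]
    cbind(sample(lab, n, TRUE, p), sample(lab, n, TRUE, p))
  })
  names(genotypes) <- paste0("L", seq_len(n_loci))
  genotype_table(id = sprintf("i%03d", seq_len(n)),
                 x = stats::runif(n, 0, 1e5), y = stats::runif(n, 0, 1e5),
                 genotypes = genotypes)
}

# brute-force standardized index of association: explicit double loops
bf_rd <- function(table) {
  n <- n_samples(table)
  L <- n_loci(table)
  P <- n * (n - 1) / 2
  D <- matrix(NA_real_, P, L)
  k <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k <- k + 1L
    for (l in seq_len(L)) {
      ga <- c(table$a1[i, l], table$a2[i, l])
      gb <- c(table$a1[j, l], table$a2[j, l])
      if (anyNA(ga) || anyNA(gb)) next
      shared <- 0L
      used <- rep(FALSE, 2L)
      for (x in ga) {
        hit <- which(!used & gb == x)
        if (length(hit)) { used[hit[1L]] <- TRUE; shared <- shared + 1L }
      }
      D[k, l] <- 1 - shared / 2
    }
  }
  for (l in seq_len(L)) D[is.na(D[, l]), l] <- mean(D[, l], na.rm = TRUE)
  vj <- apply(D, 2, stats::var)
  VO <- stats::var(rowSums(D))
  num <- VO - sum(vj)
  den <- 0
  for (a in 1:(L - 1)) for (b in (a + 1):L) den <- den + 2 * sqrt(vj[a] * vj[b])
  num / den
}

# reference Dijkstra with an explicit relaxation loop (O(V^2)), on the same
# 8-connected edge-cost rule as the package
bf_dijkstra <- function(grid, pixel, src, dst = NULL) {
  nr <- nrow(grid); nc <- ncol(grid)
  nv <- nr * nc
  dist <- rep(Inf, nv)
  done <- rep(FALSE, nv)
  dist[src] <- 0
  moves <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    if (!is.null(dst) && u == dst) break
    done[u] <- TRUE
    ur <- (u - 1) %% nr + 1; uc <- (u - 1) %/% nr + 1
    for (m in 1:8) {
      vr <- ur + moves[m, 1]; vc <- uc + moves[m, 2]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      v <- (vc - 1) * nr + vr
      if (done[v] || is.na(grid[v]) || is.na(grid[u])) next
      step <- pixel * sqrt(sum(moves[m, ]^2))
      w <- (grid[u] + grid[v]) / 2 * step
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
    if (all(done | !is.finite(dist))) break
  }
  dist
}

# reduced-size recovery scenario shared by the end-to-end checks: the same
# structure as the full default (14 loci, 4-11 alleles, roadside-clustered
# samples, 8 noise decoys) at a grid and sample size that runs in seconds
recovery_truth <- function(seed) {
  scenario_truth(n_individuals = 110L, nr = 140L, nc = 140L,
                 neighborhood_scale = 8000, n_clusters = 5L, seed = seed)
}

# lean but honest fit budget for the end-to-end models
recovery_spec <- function(candidates, response = "gd") {
  model_spec(candidates, response, eta = 0.08, max_depth = 2L,
             min_child_weight = 20L, checkpoints = c(120L, 250L))
}

recovery_candidates <- c("colluvial", "slope", "roads", paste0("decoy", 1:8))

# run the straight-line pipeline on one recovery scenario; returns the
# pieces the acceptance checks need (memoized: several blocks share runs)
.recovery_cache <- new.env(parent = emptyenv())

run_recovery <- function(seed, correlogram = TRUE) {
  key <- as.character(seed)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  tr <- recovery_truth(seed)
  sc <- simulate_scenario(tr)
  gd <- pairwise_genetic_distance(sc$table, "dps")
  pairs <- build_pairs(sc$table, min_separation = 4000)
  pairs$gd <- gd$values[cbind(match(pairs$id1, gd$ids),
                              match(pairs$id2, gd$ids))]
  folds <- assign_spatial_folds(sc$locations, k = 6L, seed = seed)
  sub <- sc$stack
  sub$layers <- sub$layers[recovery_candidates]
  pt <- pair_transect_table(sub, sc$table, pairs, buffer = 500)
  pt$geo_m <- pairs$geo_m
  spec <- recovery_spec(c(recovery_candidates, "geo_m"))
  fs <- forward_feature_selection(pt, spec, folds)
  surf <- predict_resistance(fs$model, sub, median_pair_distance(pt))
  ok <- !is.na(surf$grid)
  out <- list(
    scenario = sc, pairs = pt, folds = folds, selection = fs,
    surface = surf,
    r_surface = stats::cor(as.vector(surf$grid[ok]),
                           as.vector(sc$surface$grid[ok])),
    n_true = sum(c("colluvial", "slope", "roads") %in% fs$selected),
    n_decoy = sum(grepl("^decoy", fs$selected)),
    top_var = names(sort(relative_influence(fs$model),
                         decreasing = TRUE))[1L])
  if (correlogram) {
    geo <- geographic_distance_matrix(sc$table)
    cg <- mantel_correlogram(gd, geo, class_width = 2000, n_perm = 49L,
                             seed = seed)
    out$zero_crossing <- zero_crossing(cg)
  }
  .recovery_cache[[key]] <- out
  out
}
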