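#' Pairwise individual genetic distances
#'
#' Three individual-based metrics for codominant genotypes, none of which
#' assumes Hardy-Weinberg equilibrium:
#'
#' * `"dps"` — one minus the proportion of shared alleles,
#'   `d = 1 - sum_l sum_a min(c_xa, c_ya) / (2 * L_shared)`; equivalent to the
#'   Bray-Curtis dissimilarity of allele dosage vectors over shared loci.
#' * `"qg"` — Queller & Goodnight relatedness with reference allele
#'   frequencies from the full table (focal pair included), symmetrized as
#'   `(r_xy + r_yx) / 2`, returned as the dissimilarity `1 - r`.
#' * `"euclidean"` — Euclidean distance between allele dosage vectors
#'   (entries 0/1/2), accumulated over loci typed in both individuals. Set
#'   `dosage_scale = 0.5` for the 0/0.5/1 frequency encoding (a constant
#'   factor).
#'
#' Loci missing in either member of a pair are dropped for that pair; pairs
#' with no shared typed locus get `NA` and a warning.
#'
#' @param table a [genotype_table()].
#' @param metric one of `"dps"`, `"qg"`, `"euclidean"`.
#' @param dosage_scale multiplier applied to allele dosages for the
#'   euclidean metric (default 1, i.e. dosages in 0/1/2).
#' @return a `pairwise_matrix`: list with `ids`, symmetric `values` (the
#'   distance/dissimilarity), `metric`, `n_loci_used`, and for `"qg"` the
#'   symmetrized relatedness in `relatedness`.
#' @export
pairwise_genetic_distance <- function(table, metric = c("dps", "qg", "euclidean"),
                                      dosage_scale = 1) {
  metric <- match.arg(metric)
  n <- n_samples(table)
  L <- n_loci(table)
  typed <- !is.na(table$a1) # n x L
  shared_loci <- tcrossprod(typed * 1L) # pairs' shared typed locus counts
  vals <- matrix(0, n, n)
  if (metric == "dps") {
    shared <- matrix(0, n, n)
    for (j in seq_len(L)) {
      dj <- locus_pair_distance(table, j) # 1 - shared/2
      sj <- 2 * (1 - dj)
      sj[is.na(sj)] <- 0
      shared <- shared + sj
    }
    vals <- 1 - shared / (2 * shared_loci)
  } else if (metric == "euclidean") {
    d2 <- matrix(0, n, n)
    for (j in seq_len(L)) {
      C <- locus_dosage(table, j) * dosage_scale
      ok <- typed[, j]
      g <- tcrossprod(C)
      sq <- diag(g)
      dj <- outer(sq, sq, "+") - 2 * g
      dj[!ok, ] <- 0; dj[, !ok] <- 0
      d2 <- d2 + dj
    }
    vals <- sqrt(pmax(d2, 0))
  } else { # qg
    num <- matrix(0, n, n)   # numerator sum over loci (symmetric in pair)
    den <- matrix(0, n, n)   # denominator for r_xy: depends on row (x)
    for (j in seq_len(L)) {
      C <- locus_dosage(table, j)
      if (!ncol(C)) next
      cnt <- colSums(C)
      tot <- sum(cnt)
      if (tot == 0) next
      p <- cnt / tot
      ok <- typed[, j]
      G <- tcrossprod(C)            # allele-sharing counts
      q <- as.numeric(C %*% p)      # p_a + p_b per individual
      hom <- as.numeric(rowSums(C == 2L) > 0)
      numj <- 0.5 * G - matrix(q, n, n)       # row x: 0.5*share - (p_a+p_b)_x
      denj <- matrix(1 + hom - q, n, n)       # row x: 1 + I_ab - (p_a+p_b)_x
      both <- outer(ok, ok, "&")
      numj[!both] <- 0; denj[!both] <- 0
      num <- num + numj
      den <- den + denj
    }
    r_xy <- num / den
    r <- (r_xy + t(r_xy)) / 2
    diag(r) <- ifelse(diag(den) > 0, 1, NA_real_)
    vals <- 1 - r
  }
  none <- shared_loci == 0
  if (any(none[lower.tri(none)])) {
    warning(sum(none[lower.tri(none)]), " pair(s) share no typed locus; set NA")
    vals[none] <- NA_real_
  }
  diag(vals) <- 0
  dimnames(vals) <- list(table$id, table$id)
  out <- list(ids = table$id, values = vals, metric = metric,
              n_loci_used = shared_loci)
  if (metric == "qg") {
    r[none] <- NA_real_
    out$relatedness <- r
  }
  structure(out, class = "pairwise_matrix")
}

# n x K allele dosage matrix for locus j (rows of untyped samples are 0)
locus_dosage <- function(table, j) {
  a1 <- table$a1[, j]; a2 <- table$a2[, j]
  alleles <- sort(unique(c(a1, a2)))
  n <- length(a1)
  C <- matrix(0L, n, length(alleles))
  if (!length(alleles)) return(C)
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  ok <- which(!is.na(i1))
  C[cbind(ok, i1[ok])] <- C[cbind(ok, i1[ok])] + 1L
  C[cbind(ok, i2[ok])] <- C[cbind(ok, i2[ok])] + 1L
  C
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("pairwise_matrix (", x$metric, "): ", length(x$ids), " samples, ",
      sep = "")
  v <- x$values[lower.tri(x$values)]
  cat(sprintf("range %.3f-%.3f\n", min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Planar geographic distance matrix
#'
#' @param table a [genotype_table()] (or any list with `id`, `x`, `y`).
#' @return a `pairwise_matrix` with metric `"geographic"` in meters.
#' @export
geographic_distance_matrix <- function(table) {
  d <- as.matrix(stats::dist(cbind(table$x, table$y)))
  dimnames(d) <- list(table$id, table$id)
  structure(list(ids = table$id, values = d, metric = "geographic",
                 n_loci_used = NULL),
            class = "pairwise_matrix")
}

lower_vec <- function(m) m[lower.tri(m)]

#' Mantel test with permutation p-value and bootstrap CI
#'
#' Pearson correlation between the lower triangles of two symmetric matrices.
#' The p-value permutes the rows and columns of the second matrix jointly;
#' the confidence interval (if `n_boot > 0`) resamples individuals with
#' replacement and recomputes r on the induced submatrices (self-pairs from
#' duplicated individuals excluded).
#'
#' @param gd,geo `pairwise_matrix` objects (or plain symmetric matrices)
#'   over the same ids.
#' @param n_perm number of permutations.
#' @param n_boot bootstrap replicates for the CI (0 to skip).
#' @param seed integer seed.
#' @param alternative `"greater"` (default; isolation-by-distance is a
#'   one-sided hypothesis), `"less"`, or `"two.sided"`.
#' @return list with `r`, `p_value`, `ci95` (length-2 or `NULL`), `n`.
#' @export
mantel_test <- function(gd, geo, n_perm = 999L, n_boot = 0L, seed = 1L,
                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  A <- as_pm_matrix(gd); B <- as_pm_matrix(geo)
  if (!identical(dim(A), dim(B))) stop("matrix dimensions differ")
  n <- nrow(A)
  a <- lower_vec(A); b <- lower_vec(B)
  if (stats::sd(a, na.rm = TRUE) == 0 || stats::sd(b, na.rm = TRUE) == 0)
    stop("constant matrix: Mantel correlation undefined")
  r <- stats::cor(a, b, use = "pairwise.complete.obs")
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    s <- sample.int(n)
    rp <- stats::cor(a, lower_vec(B[s, s]), use = "pairwise.complete.obs")
    hit <- switch(alternative,
                  greater = rp >= r - 1e-12,
                  less = rp <= r + 1e-12,
                  two.sided = abs(rp) >= abs(r) - 1e-12)
    if (hit) hits <- hits + 1L
  }
  p <- (1 + hits) / (1 + n_perm)
  ci <- NULL
  if (n_boot > 0L) {
    rb <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      s <- sample.int(n, replace = TRUE)
      Ab <- A[s, s]; Bb <- B[s, s]
      keep <- lower.tri(Ab) & outer(s, s, "!=")[seq_len(n), seq_len(n)]
      rb[i] <- stats::cor(Ab[keep], Bb[keep], use = "pairwise.complete.obs")
    }
    ci <- unname(stats::quantile(rb, c(0.025, 0.975), na.rm = TRUE))
  }
  list(r = r, p_value = p, ci95 = ci, n = n)
}

as_pm_matrix <- function(x) {
  if (inherits(x, "pairwise_matrix")) return(x$values)
  as.matrix(x)
}

#' Mantel correlogram
#'
#' Per-distance-class Mantel autocorrelation: for each class, r is the
#' (sign-flipped) Pearson correlation between the genetic distances and the
#' class-membership indicator over all pairs, so positive r means pairs in
#' the class are genetically more similar than average. Per-class p-values
#' come from joint row/column permutations. Classes with fewer than
#' `min_pairs` pairs are dropped.
#'
#' @param gd,geo `pairwise_matrix` objects (genetic, geographic).
#' @param class_width distance class width in meters (default 10 km).
#' @param n_perm permutations per class.
#' @param seed integer seed.
#' @param min_pairs minimum pairs for a class to be retained (default 5).
#' @param max_distance upper bound for classes (default: max pair distance).
#' @return object of class `correlogram`: data.frame with `lo`, `hi`, `mid`,
#'   `n_pairs`, `r`, `p_value`, plus attribute `zero_crossing` (midpoint of
#'   the first class with r <= 0, or `NA` if none).
#' @export
mantel_correlogram <- function(gd, geo, class_width = 10000, n_perm = 199L,
                               seed = 1L, min_pairs = 5L, max_distance = NULL) {
  A <- as_pm_matrix(gd); B <- as_pm_matrix(geo)
  n <- nrow(A)
  a <- lower_vec(A); b <- lower_vec(B)
  if (is.null(max_distance)) max_distance <- max(b)
  edges <- seq(0, max_distance + class_width, by = class_width)
  cls <- cut(b, edges, include.lowest = TRUE, labels = FALSE)
  if (length(unique(cls)) < 2L)
    stop("all pairs fall in one distance class; decrease class_width")
  keep <- which(tabulate(cls, nbins = length(edges) - 1L) >= min_pairs)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  # permutations shared across classes: permute sample labels jointly
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  rows <- lapply(keep, function(k) {
    ind <- matrix(0, n, n)
    ind[as_pm_index(B, edges[k], edges[k + 1L])] <- 1
    iv <- lower_vec(ind)
    r_obs <- -suppressWarnings(stats::cor(a, iv, use = "pairwise.complete.obs"))
    hits <- 0L
    for (s in perms) {
      rp <- -suppressWarnings(
        stats::cor(lower_vec(A[s, s]), iv, use = "pairwise.complete.obs"))
      if (!is.na(rp) && abs(rp) >= abs(r_obs) - 1e-12) hits <- hits + 1L
    }
    data.frame(lo = edges[k], hi = edges[k + 1L],
               mid = (edges[k] + edges[k + 1L]) / 2,
               n_pairs = sum(iv), r = r_obs,
               p_value = (1 + hits) / (1 + n_perm))
  })
  out <- do.call(rbind, rows)
  zc <- out$mid[which(out$r <= 0)[1L]]
  attr(out, "zero_crossing") <- if (length(zc) && !is.na(zc)) zc else NA_real_
  class(out) <- c("correlogram", "data.frame")
  out
}

as_pm_index <- function(B, lo, hi) B > lo & B <= hi | (lo == 0 & B == 0)

#' Distance at which spatial genetic autocorrelation first becomes <= 0
#' @param x a `correlogram`.
#' @return distance in meters (`NA` if no non-positive class in range).
#' @export
zero_crossing <- function(x) attr(x, "zero_crossing")

#' Rarefied allelic richness in overlapping spatial genetic neighborhoods
#'
#' For each sample, the neighborhood is all samples within `radius`
#' (including itself). Neighborhoods with `min_n` or fewer members get `NA`.
#' The rarefaction size is `g = 2 * min(member count among qualifying
#' neighborhoods)` gene copies; per-sample richness is the mean over loci of
#' [rarefied_allelic_richness()] on the neighborhood's allele counts (at a
#' locus where fewer than `g` copies are typed, rarefaction uses the typed
#' copies).
#'
#' @param table a [genotype_table()].
#' @param radius neighborhood radius in meters.
#' @param min_n neighborhoods must exceed this many members (default 10).
#' @return data.frame `id`, `n_members`, `richness` (`NA` for
#'   non-qualifying neighborhoods); attribute `g` is the rarefaction size.
#' @export
neighborhood_allelic_richness <- function(table, radius, min_n = 10L) {
  if (radius <= 0) stop("radius must be positive")
  if (min_n < 2L) stop("min_n must be >= 2")
  d <- as.matrix(stats::dist(cbind(table$x, table$y)))
  members <- lapply(seq_len(nrow(d)), function(i) which(d[i, ] <= radius))
  sizes <- lengths(members)
  qual <- sizes > min_n
  if (!any(qual)) stop("no neighborhood exceeds min_n = ", min_n, " members")
  g <- 2L * min(sizes[qual])
  rich <- rep(NA_real_, length(sizes))
  for (i in which(qual)) {
    sub <- members[[i]]
    per_locus <- vapply(seq_len(n_loci(table)), function(j) {
      copies <- c(table$a1[sub, j], table$a2[sub, j])
      copies <- copies[!is.na(copies)]
      if (!length(copies)) return(NA_real_)
      cnt <- as.numeric(table(copies))
      rarefied_allelic_richness(cnt, min(g, sum(cnt)))
    }, numeric(1))
    rich[i] <- mean(per_locus, na.rm = TRUE)
  }
  out <- data.frame(id = table$id, n_members = sizes, richness = rich,
                    stringsAsFactors = FALSE)
  attr(out, "g") <- g
  out
}

#' Write pairwise matrices as a long-format CSV
#'
#' One row per unordered pair with columns
#' `id1,id2,geo_m,<metric...>,n_loci`.
#'
#' @param path output path.
#' @param geo geographic `pairwise_matrix`.
#' @param ... named genetic `pairwise_matrix` objects.
#' @return `path`, invisibly.
#' @export
write_pairwise_long <- function(path, geo, ...) {
  mats <- list(...)
  ids <- geo$ids
  n <- length(ids)
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  df <- data.frame(id1 = ids[ij[, 2L]], id2 = ids[ij[, 1L]],
                   geo_m = geo$values[ij], stringsAsFactors = FALSE)
  for (nm in names(mats)) df[[nm]] <- mats[[nm]]$values[ij]
  if (length(mats) && !is.null(mats[[1L]]$n_loci_used))
    df$n_loci <- mats[[1L]]$n_loci_used[ij]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
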