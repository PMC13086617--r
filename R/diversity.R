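#' Per-locus diversity summaries
#'
#' Computes, for each locus over its typed samples: number of typed samples,
#' allele count, observed heterozygosity Ho, expected heterozygosity
#' He = 1 - sum(p_i^2), unbiased expected heterozygosity
#' uHe = He * 2n / (2n - 1), and Wright's fixation index F = 1 - Ho / He
#' (reported `NA` for monomorphic loci where He = 0).
#'
#' @param table a [genotype_table()].
#' @return data.frame with one row per locus and columns
#'   `locus`, `n_typed`, `Na`, `Ho`, `He`, `uHe`, `F`.
#' @export
locus_summaries <- function(table) {
  out <- lapply(seq_along(table$loci), function(j) {
    typed <- typed_at(table, j)
    if (length(typed) == 0L)
      stop("locus ", table$loci[j], " has no typed samples")
    if (length(typed) < 2L)
      stop("locus ", table$loci[j], " has fewer than 2 typed samples")
    a1 <- table$a1[typed, j]; a2 <- table$a2[typed, j]
    n <- length(typed)
    cnt <- table(c(a1, a2))
    p <- as.numeric(cnt) / (2 * n)
    he <- 1 - sum(p^2)
    ho <- mean(a1 != a2)
    uhe <- he * 2 * n / (2 * n - 1)
    f <- if (he > 0) 1 - ho / he else NA_real_
    data.frame(locus = table$loci[j], n_typed = n, Na = length(cnt),
               Ho = ho, He = he, uHe = uhe, F = f,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Exact Hardy-Weinberg test with Monte-Carlo permutations
#'
#' Exact test of Hardy-Weinberg proportions at one locus. The test statistic
#' is the conditional probability of the observed genotype array given the
#' allele counts (Levene's distribution); the null distribution is sampled by
#' shuffling the 2n gene copies and re-pairing them into n genotypes. The
#' p-value is `(1 + #{perm with probability <= observed}) / (1 + n_perm)`,
#' so p is in (0, 1] and never exactly zero.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param n_perm number of Monte-Carlo permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return the Monte-Carlo exact p-value (scalar).
#' @export
hwe_exact_mc <- function(table, locus, n_perm = 1000L, seed = 1L) {
  j <- match(locus, table$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  typed <- typed_at(table, j)
  if (length(typed) < 5L) stop("locus ", locus, ": fewer than 5 typed samples")
  alleles <- sort(unique(c(table$a1[typed, j], table$a2[typed, j])))
  K <- length(alleles)
  if (K < 2L) stop("locus ", locus, " is monomorphic; HWE test undefined")
  i1 <- match(table$a1[typed, j], alleles)
  i2 <- match(table$a2[typed, j], alleles)
  n <- length(typed)
  # log conditional probability differs across re-pairings only through
  # h * log(2) - sum(log(n_ij!)): the allele counts are fixed by construction.
  stat <- function(v1, v2) {
    lo <- pmin(v1, v2); hi <- pmax(v1, v2)
    code <- (lo - 1L) * K + hi
    cnt <- tabulate(code, nbins = K * K)
    cnt <- cnt[cnt > 0L]
    h <- sum(lo != hi)
    h * log(2) - sum(lgamma(cnt + 1))
  }
  obs <- stat(i1, i2)
  copies <- c(i1, i2)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- copies[sample.int(2L * n)]
    if (stat(perm[1:n], perm[(n + 1L):(2L * n)]) <= obs + 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

# run code under a temporary RNG state seeded with `seed`; returns a restore fn
.Random.seed_guard <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
  }
}

# per-locus codominant mismatch distance between all sample pairs:
# 0 / 0.5 / 1 for sharing 2 / 1 / 0 allele copies. Returns an n x n matrix
# (NA where either genotype is missing).
locus_pair_distance <- function(table, j) {
  n <- n_samples(table)
  a1 <- table$a1[, j]; a2 <- table$a2[, j]
  alleles <- sort(unique(c(a1, a2)))
  d <- matrix(NA_real_, n, n)
  if (!length(alleles)) return(d)
  # dosage matrix n x K
  K <- length(alleles)
  C <- matrix(0L, n, K)
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  ok <- !is.na(i1)
  C[cbind(which(ok), i1[ok])] <- C[cbind(which(ok), i1[ok])] + 1L
  C[cbind(which(ok), i2[ok])] <- C[cbind(which(ok), i2[ok])] + 1L
  shared <- matrix(0, n, n)
  for (k in seq_len(K)) {
    ck <- C[, k]
    shared <- shared + pmin(matrix(ck, n, n), matrix(ck, n, n, byrow = TRUE))
  }
  d <- 1 - shared / 2
  d[!ok, ] <- NA_real_; d[, !ok] <- NA_real_
  diag(d) <- 0
  d
}

rd_from_pair_distances <- function(D) {
  # D: P x L matrix of per-locus pair distances (no NAs)
  vj <- apply(D, 2L, stats::var)
  VO <- stats::var(rowSums(D))
  num <- VO - sum(vj)
  den <- sum(sqrt(vj))^2 - sum(vj) # = 2 * sum_{j<k} sqrt(vj vk)
  if (den <= 0) return(NA_real_)
  num / den
}

#' Standardized index of association
#'
#' Multilocus linkage-disequilibrium statistic r_bar_d: the covariance of
#' per-locus pairwise genetic distances across loci, standardized by the
#' maximum attainable given the per-locus variances. Per-locus distance
#' between two individuals is 0 / 0.5 / 1 for sharing 2 / 1 / 0 allele
#' copies. The permutation p-value shuffles genotypes among individuals
#' independently at each locus, breaking inter-locus association while
#' preserving per-locus composition.
#'
#' Missing genotypes contribute the locus mean pair distance (mean
#' imputation over observed pairs at that locus).
#'
#' @param table a [genotype_table()] with at least 2 loci.
#' @param n_perm number of permutations for the p-value (0 to skip).
#' @param seed integer seed.
#' @return list with elements `rd_bar` and `p_value` (`NA` if `n_perm = 0`).
#' @export
index_of_association_rd <- function(table, n_perm = 999L, seed = 1L) {
  L <- n_loci(table)
  if (L < 2L) stop("the index of association requires at least 2 loci")
  n <- n_samples(table)
  low <- lower.tri(matrix(0, n, n))
  mats <- lapply(seq_len(L), function(j) {
    m <- locus_pair_distance(table, j)
    mu <- mean(m[low], na.rm = TRUE)
    m[is.na(m)] <- mu
    m
  })
  D <- vapply(mats, function(m) m[low], numeric(sum(low)))
  rd <- rd_from_pair_distances(D)
  p <- NA_real_
  if (n_perm > 0L) {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      Dp <- vapply(mats, function(m) {
        s <- sample.int(n)
        m[s, s][low]
      }, numeric(sum(low)))
      if (rd_from_pair_distances(Dp) >= rd - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
  }
  list(rd_bar = rd, p_value = p)
}

#' Pairwise standardized index of association between loci
#'
#' r_bar_d computed for every pair of loci, returned as a symmetric L x L
#' matrix. The diagonal is 1 by construction (a locus is perfectly linked
#' with itself).
#'
#' @param table a [genotype_table()] with at least 2 loci.
#' @return symmetric numeric L x L matrix with unit diagonal.
#' @export
pairwise_rd <- function(table) {
  L <- n_loci(table)
  if (L < 2L) stop("needs at least 2 loci")
  n <- n_samples(table)
  low <- lower.tri(matrix(0, n, n))
  cols <- lapply(seq_len(L), function(j) {
    m <- locus_pair_distance(table, j)
    mu <- mean(m[low], na.rm = TRUE)
    m[is.na(m)] <- mu
    m[low]
  })
  out <- matrix(1, L, L, dimnames = list(table$loci, table$loci))
  for (j in 1:(L - 1L)) for (k in (j + 1L):L) {
    out[j, k] <- out[k, j] <- rd_from_pair_distances(cbind(cols[[j]], cols[[k]]))
  }
  out
}

#' Rarefied allelic richness for one locus
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, given per-allele copy counts: `A(g) = sum_i [1 - C(N - N_i, g) /
#' C(N, g)]` with `N = sum(N_i)`.
#'
#' @param allele_counts positive integer vector of per-allele gene-copy counts.
#' @param g rarefaction size in gene copies, `1 <= g <= sum(allele_counts)`.
#' @return expected allelic richness (scalar, between 1 and the allele count).
#' @export
rarefied_allelic_richness <- function(allele_counts, g) {
  counts <- as.numeric(allele_counts)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("allele counts must be positive integers")
  N <- sum(counts)
  if (g < 1) stop("g must be >= 1")
  if (g > N) stop("g (", g, ") exceeds total gene copies (", N, ")")
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}
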