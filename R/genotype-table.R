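#' Diploid codominant genotype table
#'
#' Container for multilocus codominant (e.g., microsatellite) genotypes of
#' georeferenced individuals. Each individual carries an unordered pair of
#' allele labels per locus; a genotype is either fully typed or fully missing
#' at a locus. Coordinates are planar (a metric projected CRS is assumed
#' throughout the package).
#'
#' @param id character vector of unique sample identifiers.
#' @param x,y numeric planar coordinates in meters.
#' @param genotypes a list with one element per locus, each an n x 2 character
#'   (or integer) matrix of allele labels; `NA` marks a missing allele call.
#'   If only one of the two calls at a locus is missing the whole genotype is
#'   set missing.
#' @param loci character vector of locus names; defaults to the names of
#'   `genotypes`.
#' @param region optional character vector of region labels.
#'
#' @return An object of class `genotype_table` with fields `id`, `x`, `y`,
#'   `region`, `loci`, and allele matrices `a1`, `a2` (n x L, unordered:
#'   the pair (a1, a2) carries no order information).
#' @export
genotype_table <- function(id, x, y, genotypes, loci = names(genotypes),
                           region = NULL) {
  id <- as.character(id)
  n <- length(id)
  if (n < 2L) stop("a genotype table needs at least 2 samples")
  if (anyDuplicated(id)) stop("duplicate sample ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != n || length(y) != n) stop("coordinate length mismatch")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("coordinates must be finite")
  if (length(genotypes) < 1L) stop("at least one locus is required")
  if (is.null(loci)) loci <- paste0("L", seq_along(genotypes))
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("duplicate locus names")
  L <- length(loci)
  a1 <- matrix(NA_character_, n, L, dimnames = list(id, loci))
  a2 <- a1
  for (j in seq_len(L)) {
    g <- genotypes[[j]]
    if (is.null(dim(g)) || nrow(g) != n || ncol(g) != 2L)
      stop("genotypes[[", j, "]] must be an n x 2 matrix")
    g1 <- as.character(g[, 1L]); g2 <- as.character(g[, 2L])
    half <- xor(is.na(g1), is.na(g2))
    if (any(half)) { # single allele call: whole-locus missing
      g1[half] <- NA_character_; g2[half] <- NA_character_
    }
    a1[, j] <- g1; a2[, j] <- g2
  }
  if (!is.null(region)) {
    region <- as.character(region)
    if (length(region) != n) stop("region length mismatch")
  }
  structure(list(id = id, x = x, y = y, region = region,
                 loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$id), "samples x", length(x$loci), "loci\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  cat("  loci:", paste(utils::head(x$loci, 8L), collapse = ", "),
      if (length(x$loci) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Number of samples / loci in a genotype table
#' @param table a `genotype_table`.
#' @return integer count.
#' @export
n_samples <- function(table) length(table$id)

#' @rdname n_samples
#' @export
n_loci <- function(table) length(table$loci)

#' Read a genotype table from CSV
#'
#' Expected columns: `id`, `x`, `y`, optionally `region`, then two allele
#' columns per locus named `<locus>_1` and `<locus>_2`. Missing allele calls
#' are coded `"0"`, `""`, or `NA`. A locus with only one of its two calls
#' present at a sample is set fully missing.
#'
#' @param path CSV file path.
#' @param missing_codes character values interpreted as missing.
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path, missing_codes = c("0", "", "NA")) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("id", "x", "y")
  if (!all(need %in% names(df)))
    stop("genotype CSV must contain columns: ", paste(need, collapse = ", "))
  meta_cols <- intersect(c("id", "x", "y", "region"), names(df))
  allele_cols <- setdiff(names(df), meta_cols)
  if (length(allele_cols) %% 2L != 0L)
    stop("odd number of allele columns (", length(allele_cols),
         "); two columns per locus are required")
  base <- sub("_[12]$", "", allele_cols)
  loci <- unique(base)
  for (loc in loci) {
    if (!all(paste0(loc, c("_1", "_2")) %in% allele_cols))
      stop("locus ", loc, " lacks paired _1/_2 columns")
  }
  clean <- function(v) { v[v %in% missing_codes] <- NA_character_; v }
  genotypes <- lapply(loci, function(loc) {
    cbind(clean(df[[paste0(loc, "_1")]]), clean(df[[paste0(loc, "_2")]]))
  })
  names(genotypes) <- loci
  genotype_table(id = df$id, x = as.numeric(df$x), y = as.numeric(df$y),
                 genotypes = genotypes, loci = loci,
                 region = if ("region" %in% names(df)) df$region else NULL)
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotype_table()]; missing genotypes are written as `"0"`.
#'
#' @param table a `genotype_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  df <- data.frame(id = table$id, x = table$x, y = table$y,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$region)) df$region <- table$region
  for (j in seq_along(table$loci)) {
    v1 <- table$a1[, j]; v2 <- table$a2[, j]
    v1[is.na(v1)] <- "0"; v2[is.na(v2)] <- "0"
    df[[paste0(table$loci[j], "_1")]] <- v1
    df[[paste0(table$loci[j], "_2")]] <- v2
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# typed (non-missing) sample index for one locus
typed_at <- function(table, j) which(!is.na(table$a1[, j]))

# per-allele gene-copy counts at locus j over typed samples
allele_counts_at <- function(table, j) {
  copies <- c(table$a1[, j], table$a2[, j])
  copies <- copies[!is.na(copies)]
  if (!length(copies)) return(integer(0))
  table(copies)
}
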