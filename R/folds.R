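#' Assign samples to contiguous spatial cross-validation folds
#'
#' Clusters sample locations into `k` spatial folds for
#' leave-one-cluster-out cross-validation. Several candidate clusterings are
#' generated (k-means under different seeds, plus Ward and complete-linkage
#' hierarchical cuts) and scored by nearest-neighbor-distance matching: the
#' candidate is chosen whose pooled distribution of
#' withheld-sample-to-nearest-training-sample distances (across folds) best
#' matches the distribution of prediction-location-to-nearest-training
#' distances (1-Wasserstein distance between the two pooled distributions).
#' This favors folds whose held-out data resemble the prediction task.
#'
#' @param table sample table with `id`, `x`, `y`.
#' @param k number of folds (default 6).
#' @param target optional two-column matrix of prediction locations;
#'   defaults to a regular grid over the samples' bounding box.
#' @param n_candidates number of k-means restarts to score (default 8).
#' @param seed integer seed.
#' @return object of class `fold_assignment`: list with `fold` (named
#'   integer vector), `k`, `score` (matching diagnostic, lower is better),
#'   `method`.
#' @export
assign_spatial_folds <- function(table, k = 6L, target = NULL,
                                 n_candidates = 8L, seed = 1L) {
  coords <- cbind(table$x, table$y)
  n <- nrow(coords)
  if (n < 2L * k) stop("need at least 2k samples for k = ", k, " folds")
  if (is.null(target)) {
    gx <- seq(min(coords[, 1L]), max(coords[, 1L]), length.out = 15L)
    gy <- seq(min(coords[, 2L]), max(coords[, 2L]), length.out = 15L)
    target <- as.matrix(expand.grid(gx, gy))
  }
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  cands <- list()
  for (i in seq_len(n_candidates)) {
    km <- tryCatch(stats::kmeans(coords, centers = k, nstart = 2L),
                   error = function(e) NULL)
    if (!is.null(km)) cands[[length(cands) + 1L]] <-
        list(cl = km$cluster, method = paste0("kmeans-", i))
  }
  hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
  cands[[length(cands) + 1L]] <- list(cl = stats::cutree(hc, k),
                                      method = "ward.D2")
  hc2 <- stats::hclust(stats::dist(coords), method = "complete")
  cands[[length(cands) + 1L]] <- list(cl = stats::cutree(hc2, k),
                                      method = "complete")
  dmat <- as.matrix(stats::dist(coords))
  # cross-distances sample -> target once
  dt <- sqrt(outer(coords[, 1L], target[, 1L], "-")^2 +
             outer(coords[, 2L], target[, 2L], "-")^2)
  probs <- seq(0, 1, length.out = 101L)
  best <- NULL
  for (cand in cands) {
    sizes <- tabulate(cand$cl, k)
    if (length(unique(cand$cl)) < k || any(sizes < 2L)) next
    d_cv <- numeric(0); d_pred <- numeric(0)
    for (f in seq_len(k)) {
      tr <- cand$cl != f
      d_cv <- c(d_cv, apply(dmat[!tr, tr, drop = FALSE], 1L, min))
      d_pred <- c(d_pred, apply(dt[tr, , drop = FALSE], 2L, min))
    }
    w1 <- mean(abs(stats::quantile(d_cv, probs) -
                   stats::quantile(d_pred, probs)))
    if (is.null(best) || w1 < best$score)
      best <- list(fold = stats::setNames(cand$cl, table$id), k = k,
                   score = w1, method = cand$method)
  }
  if (is.null(best))
    stop("every candidate clustering produced a fold with < 2 samples; ",
         "reduce k")
  class(best) <- "fold_assignment"
  best
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("fold_assignment: k =", x$k, "(", x$method, "), sizes:",
      paste(tabulate(x$fold, x$k), collapse = "/"),
      sprintf("| matching score %.1f m\n", x$score))
  invisible(x)
}
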