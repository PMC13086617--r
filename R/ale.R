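#' Accumulated local effects curves
#'
#' First-order ALE for each requested variable of a fitted boosted-tree
#' model: the predictor's range is split at sample quantiles, local
#' prediction differences across each interval are averaged over the
#' observations falling in it, and the accumulated sums are centered so the
#' observation-weighted mean effect is zero. ALE is robust to correlated
#' predictors because only local (within-interval) differences are used.
#'
#' Optional uncertainty: `n_boot` refits of the model on resampled pairs
#' give pointwise 95% percentile bands; `n_random_refs` injected
#' independent uniform-noise predictors give a reference band (the central
#' 95% envelope of their centered ALE values) — curves escaping that band
#' indicate non-random structure.
#'
#' @param model a `resistance_model` (from [cv_fit()]).
#' @param variables variables to evaluate (default: the model's variables).
#'   A variable absent from the model yields a flat zero curve flagged
#'   `used = FALSE`.
#' @param n_bins number of quantile bins (default 10).
#' @param n_boot bootstrap refits for confidence bands (default 0 = none;
#'   the paper-scale choice is 500).
#' @param n_random_refs number of uniform-noise reference predictors
#'   (default 0 = none).
#' @param seed integer seed.
#' @return object of class `ale_result`: list with `curves` (per variable:
#'   `edges`, `ale`, `n`, `ci_lo`, `ci_hi`, `used`) and `band` (length-2
#'   reference band or `NULL`).
#' @export
ale_curves <- function(model, variables = model$variables, n_bins = 10L,
                       n_boot = 0L, n_random_refs = 0L, seed = 1L) {
  X <- model$data$X
  y <- model$data$y
  if (nrow(X) < 20L) stop("ALE needs at least 20 pairs")
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  predict_fn <- function(bst, M) predict(bst, M)
  curves <- lapply(variables, function(v) {
    if (!v %in% colnames(X)) {
      return(list(edges = c(0, 1), ale = c(0, 0), n = c(0L, 0L),
                  ci_lo = NULL, ci_hi = NULL, used = FALSE))
    }
    cv <- ale_one(model$booster, X, v, n_bins, predict_fn)
    cv$used <- TRUE
    cv
  })
  names(curves) <- variables
  if (n_boot > 0L) {
    boot_store <- lapply(variables, function(v)
      if (curves[[v]]$used)
        matrix(NA_real_, n_boot, length(curves[[v]]$edges)))
    names(boot_store) <- variables
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(X), replace = TRUE)
      db <- xgboost::xgb.DMatrix(X[idx, , drop = FALSE], label = y[idx])
      bb <- xgboost::xgb.train(params = model$params, data = db,
                               nrounds = model$nrounds, verbose = 0)
      for (v in variables) {
        if (!curves[[v]]$used) next
        cb <- ale_one(bb, X[idx, , drop = FALSE], v, n_bins, predict_fn,
                      edges = curves[[v]]$edges)
        boot_store[[v]][b, ] <- cb$ale
      }
    }
    for (v in variables) {
      if (!curves[[v]]$used) next
      qs <- apply(boot_store[[v]], 2L, stats::quantile,
                  probs = c(0.025, 0.975), na.rm = TRUE)
      curves[[v]]$ci_lo <- qs[1L, ]
      curves[[v]]$ci_hi <- qs[2L, ]
    }
  }
  band <- NULL
  if (n_random_refs > 0L) {
    refs <- paste0(".ref", seq_len(n_random_refs))
    Xa <- cbind(X, matrix(stats::runif(nrow(X) * n_random_refs), nrow(X),
                          n_random_refs, dimnames = list(NULL, refs)))
    da <- xgboost::xgb.DMatrix(Xa, label = y)
    ba <- xgboost::xgb.train(params = model$params, data = da,
                             nrounds = model$nrounds, verbose = 0)
    pool <- unlist(lapply(refs, function(v)
      ale_one(ba, Xa, v, n_bins, predict_fn)$ale))
    band <- unname(stats::quantile(pool, c(0.025, 0.975)))
  }
  structure(list(curves = curves, band = band, n_boot = n_boot),
            class = "ale_result")
}

# first-order ALE of one variable at quantile (or supplied) edges
ale_one <- function(booster, X, v, n_bins, predict_fn, edges = NULL) {
  x <- X[, v]
  if (is.null(edges))
    edges <- unique(stats::quantile(x, probs = seq(0, 1,
                                                   length.out = n_bins + 1L)))
  K <- length(edges) - 1L
  if (K < 1L) { # constant predictor
    return(list(edges = c(edges, edges), ale = c(0, 0), n = c(0L, 0L)))
  }
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  d <- numeric(K); nk <- integer(K)
  for (k in seq_len(K)) {
    rows <- which(bin == k)
    nk[k] <- length(rows)
    if (!length(rows)) { d[k] <- 0; next }
    hi <- X[rows, , drop = FALSE]; hi[, v] <- edges[k + 1L]
    lo <- X[rows, , drop = FALSE]; lo[, v] <- edges[k]
    d[k] <- mean(predict_fn(booster, hi) - predict_fn(booster, lo))
  }
  ale <- c(0, cumsum(d))
  center <- sum(nk * (ale[-1L] + ale[-length(ale)]) / 2) / sum(nk)
  list(edges = edges, ale = ale - center, n = c(nk, nk[K]))
}

#' @export
print.ale_result <- function(x, ...) {
  used <- vapply(x$curves, `[[`, logical(1), "used")
  cat("ale_result:", sum(used), "curves",
      if (x$n_boot > 0) paste0("(", x$n_boot, " bootstrap refits)"), "\n")
  if (!is.null(x$band))
    cat(sprintf("  random-reference band: [%.4g, %.4g]\n",
                x$band[1L], x$band[2L]))
  invisible(x)
}

#' Plot ALE curves
#' @param x an `ale_result`.
#' @param vars subset of variables to plot.
#' @param ... passed to `plot`.
#' @export
plot.ale_result <- function(x, vars = names(x$curves), ...) {
  vars <- vars[vapply(x$curves[vars], `[[`, logical(1), "used")]
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(vars)))
  on.exit(graphics::par(op))
  for (v in vars) {
    cv <- x$curves[[v]]
    ylim <- range(cv$ale, cv$ci_lo, cv$ci_hi, x$band, na.rm = TRUE)
    plot(cv$edges, cv$ale, type = "l", xlab = v, ylab = "ALE", ylim = ylim,
         ...)
    if (!is.null(cv$ci_lo)) {
      graphics::lines(cv$edges, cv$ci_lo, lty = 3)
      graphics::lines(cv$edges, cv$ci_hi, lty = 3)
    }
    if (!is.null(x$band)) graphics::abline(h = x$band, lty = 2, col = "gray")
  }
  invisible(x)
}
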