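#' Boosted-tree model specification
#'
#' Hyperparameter grid and candidate variables for gradient-boosted
#' regression trees of pairwise genetic distance. Trees consider at most
#' two-way interactions (`max_depth` capped at 2). The number of trees is
#' searched over `checkpoints` within a single training run per fold; the
#' ensemble is deterministic (no row subsampling), so results depend only on
#' the data and the grid.
#'
#' @param variables candidate explanatory variables (column names of the
#'   pair table); pairwise geographic distance (`"geo_m"`) should normally
#'   be among them.
#' @param response response column name (a pairwise genetic distance).
#' @param eta learning rates to search (default 0.005).
#' @param max_depth interaction depths to search (each <= 2; default 1:2).
#' @param min_child_weight minimum observations per terminal node
#'   (default c(5, 25, 50)).
#' @param checkpoints tree counts at which held-out error is evaluated
#'   (default seq(250, 2000, by = 50)).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(variables, response,
                       eta = 0.005, max_depth = c(1L, 2L),
                       min_child_weight = c(5L, 25L, 50L),
                       checkpoints = seq(250L, 2000L, by = 50L)) {
  if (any(max_depth > 2L)) stop("interaction depth is limited to 2")
  if (!length(variables)) stop("no candidate variables")
  if (!length(checkpoints)) stop("empty checkpoint sequence")
  structure(list(variables = variables, response = response, eta = eta,
                 max_depth = as.integer(max_depth),
                 min_child_weight = as.integer(min_child_weight),
                 checkpoints = sort(as.integer(checkpoints))),
            class = "model_spec")
}

spec_with_variables <- function(spec, variables) {
  spec$variables <- variables
  spec
}

pair_fold_split <- function(pairs, folds) {
  f1 <- folds$fold[pairs$id1]
  f2 <- folds$fold[pairs$id2]
  if (anyNA(f1) || anyNA(f2)) stop("folds do not cover all pair endpoints")
  lapply(seq_len(folds$k), function(f) {
    test <- which(f1 == f | f2 == f)
    train <- which(f1 != f & f2 != f)
    if (!length(test)) stop("fold ", f, " has an empty test set")
    if (!length(train)) stop("fold ", f, " has an empty training set")
    list(fold = f, train = train, test = test,
         withheld = names(folds$fold)[folds$fold == f])
  })
}

xgb_params <- function(eta, max_depth, min_child_weight) {
  list(objective = "reg:squarederror", eta = eta, max_depth = max_depth,
       min_child_weight = min_child_weight, subsample = 1, nthread = 1)
}

#' Fit a boosted-tree model with leave-one-spatial-cluster-out CV
#'
#' For every spatial fold, trains on all pairs with *neither* endpoint in
#' the withheld cluster and evaluates root-mean-squared error on pairs with
#' at least one endpoint in it (pairs straddle locations, so any pair
#' touching the withheld cluster is unseen). The hyperparameter grid and the
#' tree-count checkpoints are scored by mean RMSE_test across folds; the
#' final ensemble is refit on all pairs with the winning combination.
#'
#' @param pairs pair table (from [pair_transect_table()]) containing the
#'   response column and every candidate variable.
#' @param spec a [model_spec()].
#' @param folds a `fold_assignment` from [assign_spatial_folds()].
#' @param label free-form model label (e.g., `"straight-line"`, `"LCP 1"`).
#' @return object of class `resistance_model`: the fitted booster plus
#'   `variables`, `params`, `nrounds`, `mean_rmse_test`, `fold_rmse`,
#'   `r2_full`, `influence` (relative influence, sums to 100), `cv_table`,
#'   `audit` (per-fold train/test pair indices and withheld sample ids),
#'   and the training `data`.
#' @export
cv_fit <- function(pairs, spec, folds, label = "straight-line") {
  miss <- setdiff(c(spec$variables, spec$response), names(pairs))
  if (length(miss)) stop("pair table lacks columns: ",
                         paste(miss, collapse = ", "))
  y <- pairs[[spec$response]]
  X <- as.matrix(pairs[, spec$variables, drop = FALSE])
  splits <- pair_fold_split(pairs, folds)
  grid <- expand.grid(eta = spec$eta, max_depth = spec$max_depth,
                      min_child_weight = spec$min_child_weight,
                      KEEP.OUT.ATTRS = FALSE)
  cps <- spec$checkpoints
  nmax <- max(cps)
  best <- NULL
  cv_rows <- list()
  for (gi in seq_len(nrow(grid))) {
    params <- xgb_params(grid$eta[gi], grid$max_depth[gi],
                         grid$min_child_weight[gi])
    rmse <- matrix(NA_real_, length(splits), length(cps))
    for (si in seq_along(splits)) {
      sp <- splits[[si]]
      dtr <- xgboost::xgb.DMatrix(X[sp$train, , drop = FALSE],
                                  label = y[sp$train])
      bst <- xgboost::xgb.train(params = params, data = dtr, nrounds = nmax,
                                verbose = 0)
      Xte <- X[sp$test, , drop = FALSE]
      yte <- y[sp$test]
      for (ci in seq_along(cps)) {
        p <- if (cps[ci] >= nmax) predict(bst, Xte) else
          predict(bst, Xte, iterationrange = c(1L, cps[ci] + 1L))
        rmse[si, ci] <- sqrt(mean((p - yte)^2))
      }
    }
    mean_rmse <- colMeans(rmse)
    ci_best <- which.min(mean_rmse)
    cv_rows[[gi]] <- data.frame(grid[gi, , drop = FALSE],
                                nrounds = cps[ci_best],
                                mean_rmse_test = mean_rmse[ci_best])
    if (is.null(best) || mean_rmse[ci_best] < best$rmse) {
      best <- list(params = params, nrounds = cps[ci_best],
                   rmse = mean_rmse[ci_best], fold_rmse = rmse[, ci_best])
    }
  }
  dall <- xgboost::xgb.DMatrix(X, label = y)
  booster <- xgboost::xgb.train(params = best$params, data = dall,
                                nrounds = best$nrounds, verbose = 0)
  pred <- predict(booster, X)
  r2 <- if (stats::sd(pred) > 0) stats::cor(pred, y)^2 else 0
  structure(list(booster = booster, variables = spec$variables,
                 response = spec$response, params = best$params,
                 nrounds = best$nrounds, mean_rmse_test = best$rmse,
                 fold_rmse = best$fold_rmse, r2_full = r2,
                 influence = influence_from_booster(booster, spec$variables),
                 cv_table = do.call(rbind, cv_rows),
                 audit = splits, label = label,
                 data = list(X = X, y = y)),
            class = "resistance_model")
}

#' @export
print.resistance_model <- function(x, ...) {
  cat("resistance_model [", x$label, "]: ", length(x$variables),
      " variables, ", x$nrounds, " trees\n", sep = "")
  cat(sprintf("  mean RMSE_test %.4f | R2 (full data) %.4f\n",
              x$mean_rmse_test, x$r2_full))
  inf <- sort(x$influence, decreasing = TRUE)
  cat("  influence:", paste(sprintf("%s %.1f", names(inf), inf),
                            collapse = ", "), "\n")
  invisible(x)
}

influence_from_booster <- function(booster, variables) {
  out <- stats::setNames(rep(0, length(variables)), variables)
  imp <- tryCatch(xgboost::xgb.importance(model = booster),
                  error = function(e) NULL)
  if (!is.null(imp) && nrow(imp)) {
    out[imp$Feature] <- imp$Gain
  } else {
    # single-feature ensembles trip xgb.importance; sum split gains directly
    tt <- tryCatch(xgboost::xgb.model.dt.tree(model = booster),
                   error = function(e) NULL)
    if (!is.null(tt)) {
      splits <- tt$Feature != "Leaf"
      if (any(splits)) {
        agg <- tapply(tt$Gain[splits], tt$Feature[splits], sum)
        out[names(agg)] <- as.numeric(agg)
      }
    }
  }
  if (sum(out) > 0) out <- 100 * out / sum(out)
  out
}

#' Relative influence of each variable in a fitted model
#'
#' Per-variable summed squared-error reduction over all tree splits,
#' normalized to sum to 100. Variables never used by any split get 0.
#'
#' @param model a `resistance_model`.
#' @return named numeric vector summing to 100.
#' @export
relative_influence <- function(model) model$influence

#' Forward feature selection under spatial cross-validation
#'
#' Greedy forward search over the spec's candidate variables: every
#' two-variable model is evaluated by [cv_fit()] mean RMSE_test, the best
#' pair is kept, then single variables are added as long as each addition
#' strictly reduces mean RMSE_test. The trajectory is non-increasing by
#' construction.
#'
#' @param pairs pair table with response and all candidate columns.
#' @param spec a [model_spec()]; `spec$variables` is the candidate set.
#' @param folds a `fold_assignment`.
#' @param min_improve minimum RMSE reduction to accept an addition
#'   (default 0, i.e. any strict improvement beyond the `se_rule`).
#' @param se_rule additionally require the mean fold-wise RMSE improvement
#'   to exceed `se_rule` standard errors of the paired per-fold differences
#'   (default 1, the one-standard-error convention; 0 disables). This keeps
#'   additions whose apparent gain rests on a single lucky fold out of the
#'   model.
#' @return list with `selected` (character), `log` (data.frame of the
#'   search trajectory), and `model` (the final [cv_fit()] on the selected
#'   set).
#' @export
forward_feature_selection <- function(pairs, spec, folds, min_improve = 0,
                                      se_rule = 1) {
  cands <- spec$variables
  if (length(cands) < 2L) stop("need at least 2 candidate variables")
  eval_set <- function(vars)
    cv_fit(pairs, spec_with_variables(spec, vars), folds)
  combos <- utils::combn(cands, 2L, simplify = FALSE)
  fits2 <- lapply(combos, eval_set)
  rmse2 <- vapply(fits2, `[[`, numeric(1), "mean_rmse_test")
  best_i <- which.min(rmse2)
  selected <- combos[[best_i]]
  best_fit <- fits2[[best_i]]
  best_rmse <- rmse2[best_i]
  log <- data.frame(step = 1L, added = paste(selected, collapse = "+"),
                    n_vars = 2L, mean_rmse_test = best_rmse,
                    stringsAsFactors = FALSE)
  step <- 1L
  repeat {
    rest <- setdiff(cands, selected)
    if (!length(rest)) break
    fits <- lapply(rest, function(v) eval_set(c(selected, v)))
    r <- vapply(fits, `[[`, numeric(1), "mean_rmse_test")
    ok <- r < best_rmse - min_improve
    if (se_rule > 0) {
      pass_se <- vapply(fits, function(ft) {
        d <- best_fit$fold_rmse - ft$fold_rmse
        se <- stats::sd(d) / sqrt(length(d))
        se == 0 || mean(d) > se_rule * se
      }, logical(1))
      ok <- ok & pass_se
    }
    if (any(ok)) {
      add_i <- which(ok)[which.min(r[ok])]
      selected <- c(selected, rest[add_i])
      best_fit <- fits[[add_i]]
      best_rmse <- r[add_i]
      step <- step + 1L
      log <- rbind(log, data.frame(step = step, added = rest[add_i],
                                   n_vars = length(selected),
                                   mean_rmse_test = best_rmse))
    } else break
  }
  best_fit$label <- "forward-selection"
  list(selected = selected, log = log, model = best_fit)
}

#' Predict a landscape resistance surface from a fitted model
#'
#' Applies the fitted model per pixel, with pairwise geographic distance
#' held at a constant (conventionally the median pairwise distance), so the
#' surface isolates the landscape contribution. Nodata propagates.
#'
#' @param model a `resistance_model`.
#' @param stack a [raster_stack()] containing every selected landscape
#'   variable.
#' @param geo_value constant for the `geo_m` variable (required when the
#'   model uses it); see [median_pair_distance()].
#' @return a [resistance_surface()] of predicted genetic distance per pixel.
#' @export
predict_resistance <- function(model, stack, geo_value = NULL) {
  vars <- model$variables
  land <- setdiff(vars, "geo_m")
  miss <- setdiff(land, names(stack$layers))
  if (length(miss)) stop("stack lacks model layer(s): ",
                         paste(miss, collapse = ", "))
  geom <- surface_geometry(stack)
  ncell <- geom$nr * geom$nc
  M <- matrix(NA_real_, ncell, length(vars), dimnames = list(NULL, vars))
  for (v in land) M[, v] <- as.vector(stack$layers[[v]])
  if ("geo_m" %in% vars) {
    if (is.null(geo_value)) stop("geo_value required: model uses geo_m")
    M[, "geo_m"] <- geo_value
  }
  bad <- rowSums(is.na(M)) > 0L
  pred <- rep(NA_real_, ncell)
  if (any(!bad)) pred[!bad] <- predict(model$booster, M[!bad, , drop = FALSE])
  resistance_surface(matrix(pred, geom$nr, geom$nc), xll = stack$xll,
                     yll = stack$yll, pixel = stack$pixel,
                     provenance = paste0("predict:", model$label))
}

#' Median pairwise geographic distance
#' @param pairs pair table with `geo_m`.
#' @return median distance in meters.
#' @export
median_pair_distance <- function(pairs) stats::median(pairs$geo_m)

#' Linearly rescale a surface to a range
#'
#' Min-max rescale of all non-missing cells to `[lo, hi]` (monotone:
#' pixel ordering is preserved).
#'
#' @param surface a [resistance_surface()].
#' @param lo,hi target range (default 1-100).
#' @return rescaled [resistance_surface()].
#' @export
rescale_surface <- function(surface, lo = 1, hi = 100) {
  v <- surface$grid
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1L]) || rng[1L] == rng[2L])
    stop("constant surface: rescale undefined")
  surface$grid <- lo + (v - rng[1L]) / (rng[2L] - rng[1L]) * (hi - lo)
  surface$provenance <- paste0(surface$provenance, sprintf(" [%g,%g]", lo, hi))
  surface
}

#' Iterative straight-line to least-cost-path corridor refinement
#'
#' Starting from a straight-line-transect model, repeatedly: predict a
#' resistance surface, rescale it to \[1, 100\], trace least-cost paths
#' between all sample pairs, re-extract transect means along the buffered
#' paths, and refit (with forward feature selection). Iteration stops when
#' mean RMSE_test fails to strictly improve, or at `max_iter`. The best
#' model is the global RMSE_test minimum across all iterations — the
#' straight-line model may win.
#'
#' @param pairs0 straight-line pair table (response + all candidates).
#' @param table sample table with `id`, `x`, `y`.
#' @param stack a [raster_stack()].
#' @param spec a [model_spec()].
#' @param folds a `fold_assignment`.
#' @param max_iter maximum number of LCP iterations (0 = straight-line only).
#' @param buffer transect half-width in meters.
#' @param feature_select run [forward_feature_selection()] each iteration
#'   (default TRUE); otherwise [cv_fit()] on all candidates.
#' @param subdiv transect extraction subdivision.
#' @return list with `log` (Table-2-style data.frame), `models`,
#'   `best_index`, `best`, and `n_dropped` (unreachable pairs per
#'   iteration).
#' @export
iterate_corridor_model <- function(pairs0, table, stack, spec, folds,
                                   max_iter = 5L, buffer = 500,
                                   feature_select = TRUE, subdiv = 4L) {
  fit_one <- function(ptab, label) {
    if (feature_select) {
      fs <- forward_feature_selection(ptab, spec, folds)
      m <- fs$model; m$label <- label; m$selection_log <- fs$log
      m
    } else {
      cv_fit(ptab, spec, folds, label = label)
    }
  }
  models <- list(fit_one(pairs0, "straight-line"))
  n_dropped <- integer(0)
  base_cols <- intersect(c("id1", "id2", "geo_m", spec$response),
                         names(pairs0))
  i1 <- match(pairs0$id1, table$id); i2 <- match(pairs0$id2, table$id)
  for (it in seq_len(max_iter)) {
    prev <- models[[length(models)]]
    surf <- rescale_surface(
      predict_resistance(prev, stack, median_pair_distance(pairs0)), 1, 100)
    graph <- cost_graph(surf)
    paths <- vector("list", nrow(pairs0))
    ok <- rep(TRUE, nrow(pairs0))
    for (k in seq_len(nrow(pairs0))) {
      lp <- tryCatch(least_cost_path(surf, c(table$x[i1[k]], table$y[i1[k]]),
                                     c(table$x[i2[k]], table$y[i2[k]]),
                                     graph = graph),
                     error = function(e) NULL)
      if (is.null(lp)) ok[k] <- FALSE else paths[[k]] <- lp$path
    }
    if (any(!ok))
      warning(sum(!ok), " unreachable pair(s) dropped at LCP iteration ", it)
    n_dropped <- c(n_dropped, sum(!ok))
    ptab <- pair_transect_table(stack, table, pairs0[ok, base_cols],
                                buffer = buffer, paths = paths[ok],
                                subdiv = subdiv)
    m <- fit_one(ptab, paste("LCP", it))
    models[[length(models) + 1L]] <- m
    if (m$mean_rmse_test >= prev$mean_rmse_test) break
  }
  rmses <- vapply(models, `[[`, numeric(1), "mean_rmse_test")
  log <- data.frame(
    iteration = seq_along(models) - 1L,
    label = vapply(models, `[[`, character(1), "label"),
    n_vars = vapply(models, function(m) length(m$variables), integer(1)),
    variables = vapply(models, function(m)
      paste(names(sort(m$influence, decreasing = TRUE)), collapse = ", "),
      character(1)),
    mean_rmse_test = rmses,
    r2_full = vapply(models, `[[`, numeric(1), "r2_full"),
    stringsAsFactors = FALSE)
  best_index <- which.min(rmses)
  list(log = log, models = models, best_index = best_index,
       best = models[[best_index]], n_dropped = n_dropped)
}

#' Min-max normalize a response to [0, 1]
#' @param y numeric vector.
#' @return rescaled vector.
#' @export
normalize_minmax <- function(y) {
  rng <- range(y, na.rm = TRUE)
  if (rng[1L] == rng[2L]) stop("constant response: normalization undefined")
  (y - rng[1L]) / (rng[2L] - rng[1L])
}

#' Scale-adjusted RMSE for cross-metric comparison
#'
#' Genetic distance metrics live on different scales; to compare models
#' across metrics, the response is min-max normalized to \[0, 1\] before
#' modeling and the resulting mean RMSE_test is divided by the mean
#' normalized distance.
#'
#' @param model_rmse mean RMSE_test of a model fitted to the normalized
#'   response.
#' @param response_norm the normalized response values (in \[0, 1\]).
#' @return unitless adjusted RMSE.
#' @export
adjusted_rmse <- function(model_rmse, response_norm) {
  mu <- mean(response_norm, na.rm = TRUE)
  if (mu == 0) stop("mean normalized distance is zero")
  model_rmse / mu
}

#' Fit and compare models across genetic distance metrics
#'
#' Fits one spatially cross-validated model per metric on the min-max
#' normalized response and reports comparable adjusted RMSE values.
#'
#' @param pairs pair table containing one column per metric.
#' @param metrics character vector of response column names.
#' @param spec a [model_spec()] (its `response` field is overridden).
#' @param folds a `fold_assignment`.
#' @return data.frame with `metric`, `mean_rmse_test`, `adjusted_rmse`.
#' @export
compare_metric_models <- function(pairs, metrics, spec, folds) {
  rows <- lapply(metrics, function(m) {
    p <- pairs
    resp <- paste0(m, "_norm")
    p[[resp]] <- normalize_minmax(p[[m]])
    sp <- spec; sp$response <- resp
    fit <- cv_fit(p, sp, folds, label = paste("straight-line", m))
    data.frame(metric = m, mean_rmse_test = fit$mean_rmse_test,
               adjusted_rmse = adjusted_rmse(fit$mean_rmse_test, p[[resp]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
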