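# small deterministic pair-table maker: n points, given layers as per-pair
# synthetic "transect" covariates
make_pair_data <- function(n = 36, seed = 1, k_noise = 3,
                           fun = function(df) 0.5 * df$v1) {
  set.seed(seed)
  tab <- list(id = sprintf("p%02d", seq_len(n)),
              x = runif(n, 0, 3e4), y = runif(n, 0, 3e4))
  pairs <- build_pairs(tab)
  pairs$geo_m <- pairs$geo_m
  pairs$v1 <- runif(nrow(pairs))
  for (i in seq_len(k_noise)) pairs[[paste0("n", i)]] <- runif(nrow(pairs))
  pairs$y <- fun(pairs)
  list(tab = tab, pairs = pairs)
}

lean_spec <- function(vars, response = "y")
  model_spec(vars, response, eta = 0.1, max_depth = 2L,
             min_child_weight = 5L, checkpoints = c(50L, 150L))

test_that("spatial folds separate clouds, are seeded, and stay balanced", {
  set.seed(1)
  cloudA <- cbind(rnorm(15, 0, 500), rnorm(15, 0, 500))
  cloudB <- cbind(rnorm(15, 5e4, 500), rnorm(15, 5e4, 500))
  tab <- list(id = sprintf("s%02d", 1:30), x = c(cloudA[, 1], cloudB[, 1]),
              y = c(cloudA[, 2], cloudB[, 2]))
  f <- assign_spatial_folds(tab, k = 2, seed = 3)
  expect_equal(length(unique(f$fold[1:15])), 1L)
  expect_equal(length(unique(f$fold[16:30])), 1L)
  expect_identical(f$fold, assign_spatial_folds(tab, k = 2, seed = 3)$fold)
  # uniform points, k = 6: all folds between 10 and 30 of 120 in most seeds
  ok <- vapply(1:8, function(s) {
    set.seed(100 + s)
    tb <- list(id = sprintf("u%03d", 1:120), x = runif(120, 0, 1e5),
               y = runif(120, 0, 1e5))
    sizes <- tabulate(assign_spatial_folds(tb, k = 6, seed = s)$fold, 6)
    all(sizes >= 10 & sizes <= 30)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  expect_error(assign_spatial_folds(list(id = c("a", "b"), x = 1:2, y = 1:2),
                                    k = 6), "2k")
})

test_that("cv_fit: constant and noiseless responses, audit, influence", {
  pd <- make_pair_data(fun = function(df) rep(0, nrow(df)))
  folds <- assign_spatial_folds(pd$tab, k = 4, seed = 1)
  m0 <- cv_fit(pd$pairs, lean_spec(c("v1", "geo_m")), folds)
  expect_equal(m0$mean_rmse_test, 0, tolerance = 1e-9)
  # noiseless smooth function of one variable: small test error
  pd2 <- make_pair_data(fun = function(df) 2 * df$v1)
  folds2 <- assign_spatial_folds(pd2$tab, k = 4, seed = 1)
  m1 <- cv_fit(pd2$pairs, lean_spec(c("v1", "n1")), folds2)
  expect_lt(m1$mean_rmse_test, 0.1 * sd(pd2$pairs$y))
  # relative influence: sums to 100, concentrated on the real driver
  expect_equal(sum(relative_influence(m1)), 100, tolerance = 1e-6)
  expect_equal(names(which.max(relative_influence(m1))), "v1")
  expect_gt(relative_influence(m1)["v1"], 95)
  # single-variable model carries influence 100
  ms <- cv_fit(pd2$pairs, lean_spec("v1"), folds2)
  expect_equal(unname(relative_influence(ms)["v1"]), 100)
  # leakage audit: no training pair touches the withheld cluster
  for (sp in m1$audit) {
    tr <- pd2$pairs[sp$train, ]
    expect_false(any(tr$id1 %in% sp$withheld | tr$id2 %in% sp$withheld))
    te <- pd2$pairs[sp$test, ]
    expect_true(all(te$id1 %in% sp$withheld | te$id2 %in% sp$withheld))
  }
  # withheld test sets are large on clustered data (pairs touch clusters)
  frac <- vapply(m1$audit, function(sp) length(sp$test), numeric(1)) /
    nrow(pd2$pairs)
  expect_gt(min(frac), 0.25)
})

test_that("forward selection is non-increasing and ignores duplicates", {
  pd <- make_pair_data(n = 40, fun = function(df)
    1.5 * df$v1 + 0.00003 * df$geo_m)
  folds <- assign_spatial_folds(pd$tab, k = 4, seed = 2)
  pd$pairs$v1_copy <- pd$pairs$v1
  spec <- lean_spec(c("v1", "v1_copy", "geo_m", "n1", "n2"))
  fs <- forward_feature_selection(pd$pairs, spec, folds)
  expect_true(all(diff(fs$log$mean_rmse_test) <= 1e-12))
  expect_false(all(c("v1", "v1_copy") %in% fs$selected))
  expect_true("v1" %in% fs$selected || "v1_copy" %in% fs$selected)
})

test_that("ALE curves recover linear effects and flag unused variables", {
  pd <- make_pair_data(n = 40, seed = 5, fun = function(df)
    3 * df$v1 + 0.2 * rnorm(nrow(df)))
  folds <- assign_spatial_folds(pd$tab, k = 4, seed = 1)
  m <- cv_fit(pd$pairs, lean_spec(c("v1", "n1")), folds)
  ale <- ale_curves(m, n_bins = 8, seed = 1)
  cv <- ale$curves$v1
  # slope of the ALE curve approximates the true coefficient
  fit <- lm(cv$ale ~ cv$edges)
  expect_equal(unname(coef(fit)[2]), 3, tolerance = 0.1 * 3)
  # centered: observation-weighted mean effect is ~0
  mid <- (cv$ale[-1] + cv$ale[-length(cv$ale)]) / 2
  expect_lt(abs(sum(cv$n[-length(cv$n)] * mid) / sum(cv$n[-length(cv$n)])),
            1e-8)
  # variable absent from the model: flat zero, flagged
  ale2 <- ale_curves(m, variables = c("v1", "absent"), n_bins = 5, seed = 1)
  expect_false(ale2$curves$absent$used)
  expect_equal(ale2$curves$absent$ale, c(0, 0))
  # bootstrap bands contain the point estimate; reference band exists
  ale3 <- ale_curves(m, variables = "v1", n_bins = 5, n_boot = 15,
                     n_random_refs = 10, seed = 2)
  cv3 <- ale3$curves$v1
  expect_true(all(cv3$ci_lo <= cv3$ale + 1e-6 & cv3$ale <= cv3$ci_hi + 1e-6))
  expect_length(ale3$band, 2L)
  # monotone effect yields a monotone curve
  expect_true(all(diff(cv$ale) > -0.05))
})

test_that("resistance prediction: constants, irrelevant layers, errors", {
  pd <- make_pair_data(n = 40, seed = 6, fun = function(df) 2 * df$v1)
  folds <- assign_spatial_folds(pd$tab, k = 4, seed = 1)
  m <- cv_fit(pd$pairs, lean_spec(c("v1", "geo_m")), folds)
  mk <- function(v1) raster_stack(list(v1 = v1,
                                       other = matrix(runif(400), 20, 20)),
                                  pixel = 100)
  s1 <- predict_resistance(m, mk(matrix(0.4, 20, 20)), geo_value = 1e4)
  expect_equal(length(unique(as.vector(s1$grid))), 1L)
  # changing a non-selected layer leaves the surface untouched
  v <- matrix(runif(400), 20, 20)
  sA <- predict_resistance(m, mk(v), geo_value = 1e4)
  sB <- predict_resistance(m, mk(v), geo_value = 1e4)
  expect_equal(sA$grid, sB$grid)
  expect_error(predict_resistance(
    m, raster_stack(list(z = matrix(1, 5, 5))), geo_value = 1),
    "v1")
  expect_error(predict_resistance(m, mk(v)), "geo_value")
  # nodata propagates
  v[2, 3] <- NA
  sN <- predict_resistance(m, mk(v), geo_value = 1e4)
  expect_true(is.na(sN$grid[2, 3]))
})

test_that("adjusted RMSE arithmetic and the cross-metric harness", {
  expect_equal(adjusted_rmse(0.1, c(0.4, 0.6)), 0.2)
  expect_equal(adjusted_rmse(0, c(0.4, 0.6)), 0)
  expect_error(normalize_minmax(rep(2, 5)), "constant")
  pd <- make_pair_data(n = 30, seed = 8, fun = function(df) df$v1)
  pd$pairs$m1 <- pd$pairs$y
  pd$pairs$m2 <- 5 + 10 * pd$pairs$y
  pd$pairs$m3 <- pd$pairs$y + 0.2 * rnorm(nrow(pd$pairs))
  folds <- assign_spatial_folds(pd$tab, k = 3, seed = 1)
  cmp <- compare_metric_models(pd$pairs, c("m1", "m2", "m3"),
                               lean_spec(c("v1", "n1")), folds)
  expect_equal(nrow(cmp), 3L)
  # m1 and m2 are affine copies: identical adjusted RMSE
  expect_equal(cmp$adjusted_rmse[1], cmp$adjusted_rmse[2], tolerance = 1e-9)
  expect_gt(cmp$adjusted_rmse[3], cmp$adjusted_rmse[1])
})

test_that("corridor iteration stops on a uniform landscape and logs", {
  # tiny scenario: response depends on v1 transects; uniform landscape makes
  # LCPs match straight lines, so iteration 1 cannot improve and the loop
  # stops with the straight-line model as global best
  set.seed(4)
  n <- 16
  tab <- list(id = sprintf("q%02d", 1:n), x = runif(n, 500, 3500),
              y = runif(n, 500, 3500))
  stack <- raster_stack(list(v1 = matrix(runif(1600), 40, 40),
                             flat = matrix(1, 40, 40)), pixel = 100)
  pairs <- build_pairs(tab)
  pt <- pair_transect_table(stack, tab, pairs, buffer = 200)
  pt$geo_m <- pairs$geo_m
  pt$y <- 2 * pt$v1 + 1e-5 * pt$geo_m
  folds <- assign_spatial_folds(tab, k = 3, seed = 1)
  spec <- lean_spec(c("v1", "flat", "geo_m"))
  it <- iterate_corridor_model(pt, tab, stack, spec, folds, max_iter = 2,
                               buffer = 200, feature_select = FALSE)
  expect_equal(it$log$label[1], "straight-line")
  expect_true(nrow(it$log) >= 2)
  expect_equal(it$best_index, which.min(it$log$mean_rmse_test))
  # disabled loop returns the straight-line model alone
  it0 <- iterate_corridor_model(pt, tab, stack, spec, folds, max_iter = 0,
                                buffer = 200, feature_select = FALSE)
  expect_equal(nrow(it0$log), 1L)
})
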