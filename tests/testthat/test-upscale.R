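make_table <- function(n = 400, noise = 0, seed = 1) {
  # monotone response in two of four covariates
  set.seed(seed)
  x1 <- runif(n, 0, 10); x2 <- rnorm(n); x3 <- rnorm(n); x4 <- rnorm(n)
  data.frame(loss = 2 + 0.5 * x1 + exp(0.3 * x2) + rnorm(n, 0, noise),
             biome = sample(c("tropical", "temperate"), n, TRUE),
             x1 = x1, x2 = x2, x3 = x3, x4 = x4)
}

test_that("collinearity filter enforces both thresholds and logs removals", {
  set.seed(2)
  n <- 300
  a <- rnorm(n); b <- rnorm(n); c_ <- rnorm(n)
  # duplicated covariate: exactly one of the pair goes
  tab <- data.frame(loss = rnorm(n), a = a, a_dup = a + rnorm(n, 0, 1e-6),
                    b = b)
  out <- filter_collinear(tab)
  expect_equal(sum(c("a", "a_dup") %in% names(out$table)), 1)
  expect_equal(nrow(out$log), 1)
  # near-orthogonal covariates: none removed
  out2 <- filter_collinear(data.frame(loss = rnorm(n), a = a, b = b,
                                      c_ = c_))
  expect_equal(nrow(out2$log), 0)
  # constant covariate removed with a zero-variance reason
  out3 <- filter_collinear(data.frame(loss = rnorm(n), a = a, b = b,
                                      k = rep(1, n)))
  expect_equal(out3$log$variable, "k")
  expect_match(out3$log$reason, "zero variance")
  # surviving set satisfies both thresholds on a harder case
  set.seed(5)
  z <- matrix(rnorm(200 * 6), 200)
  z[, 2] <- z[, 1] * 0.95 + rnorm(200, 0, 0.2)
  z[, 4] <- z[, 3] * 0.8 + z[, 1] * 0.5 + rnorm(200, 0, 0.3)
  df <- as.data.frame(z); names(df) <- paste0("v", 1:6)
  df$loss <- rnorm(200)
  kept <- filter_collinear(df)$table
  covs <- setdiff(names(kept), "loss")
  cm <- abs(cor(kept[covs])); diag(cm) <- 0
  expect_lt(max(cm), 0.7 + 1e-12)
  expect_lt(max(diag(solve(cor(kept[covs])))), 4)
})

test_that("the worst pair's member with larger mean correlation is
           dropped", {
  set.seed(9)
  n <- 500
  x3 <- rnorm(n)
  x1 <- rnorm(n)
  x2 <- 0.95 * x1 + rnorm(n, 0, sqrt(1 - 0.95^2))  # r(x1,x2) ~ 0.9+
  x2 <- x2 + 0.3 * x3                              # x2 also tied to x3
  tab <- data.frame(loss = rnorm(n), x1 = x1, x2 = x2, x3 = x3)
  # independent oracle: from the correlation matrix, the member of the
  # worst pair with the larger mean |r| to the others must be dropped
  cm <- abs(cor(tab[c("x1", "x2", "x3")])); diag(cm) <- 0
  worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
  pair <- colnames(cm)[worst]
  expected_drop <- pair[which.max(colMeans(cm[, pair]))]
  out <- filter_collinear(tab)
  expect_equal(out$log$variable, expected_drop)
  expect_false(expected_drop %in% names(out$table))
})

test_that("cross-validated upscaler recovers signal and rejects noise", {
  tab <- make_table(n = 800, noise = 0)
  up <- fit_upscaler(tab, k = 10, seed = 1)
  expect_gte(up$cv$r2, 0.9)
  expect_length(up$cv$fold_r2, 10)
  null_tab <- tab
  set.seed(4)
  null_tab$loss <- rnorm(nrow(tab))
  up0 <- fit_upscaler(null_tab, k = 10, seed = 1)
  expect_lte(up0$cv$r2, 0.1)
  # fixed seed: identical folds and statistics
  up2 <- fit_upscaler(tab, k = 10, seed = 1)
  expect_identical(up$folds, up2$folds)
  expect_identical(up$cv, up2$cv)
  expect_error(fit_upscaler(tab[1:8, ], k = 10), "more rows than folds")
})

test_that("prediction maps honour the mask and the covariate contract", {
  w <- small_world()
  # noiseless table from the world itself: near-interpolation at training
  # cells
  set.seed(3)
  cells <- sample(which(w$mask), 600)
  obs_grid <- w$grid
  v <- matrix(NA_real_, length(w$grid$lat), length(w$grid$lon))
  v[cells] <- w$loss_true[cells]
  obs_grid$values <- v
  tab <- covariate_table(w, obs_grid)
  up <- fit_upscaler(tab, seed = 2)
  map <- predict_map(up, w$covariates, w$mask, w$grid)
  expect_true(all(is.na(map$values[!w$mask])))
  expect_false(any(is.na(map$values[w$mask])))
  rel_err <- abs(map$values[cells] - w$loss_true[cells]) /
    w$loss_true[cells]
  expect_lt(median(rel_err), 0.1)
  # empty mask and missing layer
  empty <- predict_map(up, w$covariates, matrix(FALSE, 40, 40), w$grid)
  expect_true(all(is.na(empty$values)))
  expect_error(predict_map(up, w$covariates[-1], w$mask, w$grid),
               "MAT")
})

test_that("bootstrap schemes resample as documented and CV behaves", {
  w <- small_world()
  set.seed(8)
  cells <- sample(which(w$mask), 250)
  g <- w$grid
  v <- matrix(NA_real_, 40, 40); v[cells] <- w$loss_true[cells]
  g$values <- v
  tab <- covariate_table(w, g)
  be <- bootstrap_maps(tab, w$covariates, w$mask, w$grid, "stratified",
                       iterations = 8, seed = 1, num_trees = 100)
  # stratified draws preserve per-biome counts in every iteration
  orig <- table(tab$biome)
  for (d in be$draws)
    expect_equal(table(tab$biome[d]), orig)
  expect_true(all(be$cv >= 0, na.rm = TRUE))
  expect_equal(be$iterations, 8)
  br <- bootstrap_maps(tab, w$covariates, w$mask, w$grid, "random",
                       iterations = 4, seed = 2, num_trees = 100)
  expect_true(all(lengths(br$draws) == round(0.9 * nrow(tab))))
  # constant response -> identical member maps -> CV identically zero
  tab0 <- tab; tab0$loss <- 5
  b0 <- bootstrap_maps(tab0, w$covariates, w$mask, w$grid, "random",
                       iterations = 3, seed = 3, num_trees = 50)
  expect_true(all(b0$cv[w$mask] == 0))
  expect_error(bootstrap_maps(tab[setdiff(names(tab), "biome")],
                              w$covariates, w$mask, w$grid, "stratified"),
               "biome")
})

test_that("map uncertainty grows with plot noise", {
  w <- small_world()
  set.seed(10)
  cells <- sample(which(w$mask), 300)
  tab_for <- function(noise_sd, seed) {
    g <- w$grid
    v <- matrix(NA_real_, 40, 40)
    set.seed(seed)
    v[cells] <- w$loss_true[cells] + rnorm(length(cells), 0, noise_sd)
    g$values <- v
    covariate_table(w, g)
  }
  cv_lo <- bootstrap_maps(tab_for(0.1, 1), w$covariates, w$mask, w$grid,
                          "random", iterations = 6, seed = 4,
                          num_trees = 100)$cv
  cv_hi <- bootstrap_maps(tab_for(1.5, 1), w$covariates, w$mask, w$grid,
                          "random", iterations = 6, seed = 4,
                          num_trees = 100)$cv
  expect_gt(median(cv_hi, na.rm = TRUE), median(cv_lo, na.rm = TRUE))
})

test_that("permutation importance finds the planted signal", {
  set.seed(6)
  n <- 500
  tab <- data.frame(a = runif(n, 0, 10), b = rnorm(n), c_ = rnorm(n))
  tab$loss <- 3 * tab$a + rnorm(n, 0, 0.5)
  up <- fit_upscaler(tab, k = 5, seed = 1)
  imp <- variable_importance(up, tab, seed = 2)
  expect_equal(imp$covariate[1], "a")
  expect_equal(imp$rank, 1:3)
  # pure-noise covariates at least 5x below the planted signal
  expect_gt(imp$inc_mse[imp$covariate == "a"],
            5 * max(abs(imp$inc_mse[imp$covariate != "a"])))
  # independent cross-check: randomForest's native %IncMSE agrees on the
  # top-ranked covariate
  skip_if_not_installed("randomForest")
  set.seed(3)
  rf <- randomForest::randomForest(loss ~ a + b + c_, data = tab,
                                   importance = TRUE, ntree = 300)
  rf_rank <- rownames(randomForest::importance(rf))[
    which.max(randomForest::importance(rf)[, "%IncMSE"])]
  expect_equal(rf_rank, "a")
})

test_that("driver LMM recovers coefficients per predictor sd with honest
           nulls", {
  # census-level rows: 150 plots x 4 censuses, random plot intercepts
  set.seed(12)
  n_plot <- 150; n_cens <- 4
  plot_id <- rep(sprintf("p%03d", 1:n_plot), each = n_cens)
  u <- rep(rnorm(n_plot, 0, 0.5), each = n_cens)
  mat <- rep(rnorm(n_plot, 15, 5), each = n_cens) + rnorm(n_plot * n_cens)
  null_x <- rnorm(n_plot * n_cens)
  y <- 2 * (mat - mean(mat)) / sd(mat) + u + rnorm(n_plot * n_cens, 0, 0.3)
  d <- data.frame(loss = y, mat = mat, null_x = null_x, plot_id = plot_id)
  fit <- fit_driver_lmm(d, "loss", c("mat", "null_x"), "plot_id")
  expect_equal(attr(fit, "method"), "lmm")
  est <- fit$estimate[fit$term == "mat"]
  expect_true(fit$ci_lower[fit$term == "mat"] < 2 &&
                2 < fit$ci_upper[fit$term == "mat"] ||
                abs(est - 2) < 0.2)
  expect_true(fit$ci_lower[fit$term == "null_x"] < 0 &&
                0 < fit$ci_upper[fit$term == "null_x"])
  expect_equal(fit$stars[fit$term == "mat"], "***")
  # one row per plot: grouping is degenerate, OLS fallback warns
  d1 <- d[!duplicated(d$plot_id), ]
  expect_warning(f1 <- fit_driver_lmm(d1, "loss", "mat", "plot_id"),
                 "OLS")
  expect_equal(attr(f1, "method"), "ols")
  expect_error(fit_driver_lmm(d, "loss", "absent", "plot_id"),
               "missing column")
})

test_that("stand density index follows the Reineke form", {
  expect_equal(stand_density_index(500, 25.4), 500)
  expect_equal(stand_density_index(300, 50.8), 300 * 2^1.605)
  expect_equal(stand_density_index(300, 50.8), 912.8, tolerance = 1e-3)
  expect_equal(stand_density_index(600, 30), 2 * stand_density_index(300, 30))
  expect_error(stand_density_index(0, 20), "positive")
  expect_error(stand_density_index(100, -1), "positive")
})

test_that("standard error of the regional mean shrinks with sample size", {
  w <- small_world()
  est_se <- function(n) {
    means <- vapply(1:30, function(r) {
      mean(sample_plots(w, n = n, noise_sd = 1, seed = 1000 + r)$loss)
    }, 0)
    sd(means)
  }
  expect_lt(est_se(400), est_se(100))
})
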