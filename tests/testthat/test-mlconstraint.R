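# small trained surrogate, shared across blocks
surrogate_fixture <- function() {
  if (is.null(.fixtures$sur)) {
    ens <- small_ensemble()
    .fixtures$sur <- train_surrogate(ens$members[[1]], "npp", "noclim",
                                     ens$mask, split_seed = 7)
  }
  .fixtures$sur
}

test_that("model-observation comparison computes delta and ensemble CV
           cellwise", {
  ens <- small_ensemble()
  obs <- ens$truth
  cmp <- compare_model_obs(ens, obs)
  # hand check at one cell: two members only
  two <- ens; two$members <- ens$members[1:2]
  v1 <- two$members[[1]]$loss_his$values[5, 5]
  v2 <- two$members[[2]]$loss_his$values[5, 5]
  cmp2 <- compare_model_obs(two, obs)
  expect_equal(cmp2$ens_mean$values[5, 5], mean(c(v1, v2)))
  expect_equal(cmp2$delta$values[5, 5], mean(c(v1, v2)) - obs$values[5, 5])
  expect_equal(cmp2$ens_cv$values[5, 5],
               100 * sd(c(v1, v2)) / mean(c(v1, v2)))
  # ensemble equal to the observation everywhere -> delta identically 0
  same <- ens
  same$members <- lapply(ens$members[1:2], function(m) {
    m$loss_his$values <- obs$values; m })
  expect_true(all(compare_model_obs(same, obs)$delta$values == 0))
  # explicit toy: models 4 and 8 vs observation 5
  g1 <- equatorial_grid(matrix(4, 2, 2)); g2 <- equatorial_grid(matrix(8, 2, 2))
  ga <- equatorial_grid(matrix(5, 2, 2))
  toy <- list(structure(list(name = "a", loss_his = g1), class = "model_fields"),
              structure(list(name = "b", loss_his = g2), class = "model_fields"))
  ct <- compare_model_obs(toy, ga)
  expect_equal(ct$delta$values[1, 1], 1)
  expect_equal(ct$ens_cv$values[1, 1], 100 * sd(c(4, 8)) / 6)
  expect_equal(round(ct$ens_cv$values[1, 1], 1), 47.1)
  # CV undefined where the mean is zero
  gz <- equatorial_grid(matrix(c(0, 1, 1, 1), 2, 2))
  gz2 <- equatorial_grid(matrix(c(0, 1, 1, 1), 2, 2))
  toyz <- list(structure(list(name = "a", loss_his = gz), class = "model_fields"),
               structure(list(name = "b", loss_his = gz2), class = "model_fields"))
  expect_true(is.na(compare_model_obs(toyz, ga)$ens_cv$values[1, 1]))
  expect_error(compare_model_obs(list(toy[[1]]), ga), "at least 2")
})

test_that("surrogates are reproducible, skilled on the coupled ensemble,
           and honest on permuted targets", {
  ens <- small_ensemble()
  s1 <- surrogate_fixture()
  s2 <- train_surrogate(ens$members[[1]], "npp", "noclim", ens$mask,
                        split_seed = 7)
  expect_equal(s1$train, s2$train)
  expect_equal(s1$validation_r, s2$validation_r)
  expect_gte(s1$validation_r, 0.65)
  sc <- train_surrogate(ens$members[[1]], "npp", "clim", ens$mask,
                        split_seed = 7)
  expect_gte(sc$validation_r, 0.9)
  expect_equal(sc$predictors, c("loss_his", "mat_pro", "map_pro"))
  # permuted target: no skill
  permuted <- ens$members[[1]]
  set.seed(5)
  idx <- which(ens$mask)
  permuted$npp_pro$values[idx] <- sample(permuted$npp_pro$values[idx])
  sp <- train_surrogate(permuted, "npp", "noclim", ens$mask,
                        split_seed = 7)
  expect_lt(abs(sp$validation_r), 0.2)
  expect_error(train_surrogate(ens$members[[1]], "npp", "warp", ens$mask),
               "unknown scenario")
  expect_error(train_surrogate(ens$members[[1]], "npp", "noclim",
                               matrix(FALSE, 20, 20)), "at least 100")
})

test_that("the bootstrap observation honours its moments and degenerate
           limits", {
  ens1 <- structure(list(mean = matrix(4, 6, 6), cv = matrix(0, 6, 6),
                         mean_grid = NULL), class = "bootstrap_ensemble")
  ens2 <- structure(list(mean = matrix(6, 6, 6), cv = matrix(0, 6, 6),
                         mean_grid = NULL), class = "bootstrap_ensemble")
  # both CV maps zero: every sampled map equals the overall mean
  obs <- build_loss_observation(ens1, ens2, n_maps = 20, seed = 2)
  expect_equal(obs$mean, matrix(5, 6, 6))
  expect_equal(obs$sd, matrix(0, 6, 6))
  for (m in obs$maps) expect_equal(m, matrix(5, 6, 6))
  # overall sd combines the two schemes: 2 * (m1 cv1 + m2 cv2) / 100
  ens1b <- ens1; ens1b$cv <- matrix(10, 6, 6)   # sd1 = 0.4
  ens2b <- ens2; ens2b$cv <- matrix(5, 6, 6)    # sd2 = 0.3
  obs2 <- build_loss_observation(ens1b, ens2b, n_maps = 400, seed = 3)
  expect_equal(obs2$sd, matrix(2 * (0.4 + 0.3), 6, 6))
  quad <- build_loss_observation(ens1b, ens2b, n_maps = 2, seed = 3,
                                 combine = "quadrature")
  expect_equal(quad$sd[1, 1], 2 * sqrt(0.4^2 + 0.3^2))
  # sampled maps concentrate on the overall mean
  samp <- simplify2array(obs2$maps)
  cellmean <- apply(samp, c(1, 2), mean)
  expect_lt(max(abs(cellmean - 5)), 3 * 1.4 / sqrt(400))
  expect_true(all(samp >= 0))
  # reproducible; negative CV rejected
  obs3 <- build_loss_observation(ens1b, ens2b, n_maps = 3, seed = 3)
  expect_identical(obs3$maps[[2]],
                   build_loss_observation(ens1b, ens2b, n_maps = 3,
                                          seed = 3)$maps[[2]])
  ens_neg <- ens1b; ens_neg$cv <- matrix(-1, 6, 6)
  expect_error(build_loss_observation(ens_neg, ens2b), "negative CV")
})

test_that("feeding a member its own historical LOSS reproduces its
           unconstrained flux within surrogate error", {
  ens <- small_ensemble()
  regs <- region_set(data.frame(region = "domain", lon_min = -180,
                                lon_max = 180, lat_min = -90,
                                lat_max = 90))
  areas <- cell_areas(ens$truth)
  forest_area <- sum(areas[ens$mask])
  for (i in seq_along(ens$members)) {
    m <- ens$members[[i]]
    sur <- train_surrogate(m, "npp", "noclim", ens$mask,
                           split_seed = 40 + i)
    obs_self <- loss_observation_from_maps(m$loss_his$values,
                                           0 * m$loss_his$values,
                                           ens$truth, n_maps = 1,
                                           seed = 1)
    single <- ens; single$members <- list(m)
    cr <- apply_constraint(list(sur), single, obs_self, regs,
                           fluxes = "npp")
    tol <- 2 * sur$validation_rmse * forest_area / 1e15
    expect_lt(abs(cr$after[1, 1, 1, "npp"] - cr$before[1, 1, "npp"]), tol)
  }
})

test_that("constraint aggregates keep the NEE identity exactly and report
           both pooling modes", {
  w <- small_world()
  ens <- small_ensemble()
  regs <- halves_regions(w$extent)
  surs <- list()
  for (m in ens$members) for (fx in c("npp", "hr"))
    surs[[paste(m$name, fx)]] <- train_surrogate(m, fx, "noclim",
                                                 ens$mask,
                                                 split_seed = 3)
  obs <- loss_observation_from_maps(ens$truth$values,
                                    0.1 * ens$truth$values, ens$truth,
                                    n_maps = 5, seed = 9)
  cr <- apply_constraint(surs, ens, obs, regs)
  expect_equal(cr$before[, , "nee"],
               cr$before[, , "npp"] - cr$before[, , "hr"], tolerance = 0)
  expect_equal(cr$after[, , , "nee"],
               cr$after[, , , "npp"] - cr$after[, , , "hr"],
               tolerance = 0)
  # missing surrogate is a named error
  expect_error(apply_constraint(surs[-1], ens, obs, regs),
               "missing surrogate")
  ba <- compare_before_after(cr)
  expect_equal(nrow(ba), 2 * 3)
  expect_true(all(ba$n_after == 6))
  pooled <- compare_before_after(cr, pooling = "pooled")
  expect_true(all(pooled$n_after == 30))
})

test_that("surrogate response is monotone in the observed LOSS on the
           saturating ensemble", {
  ens <- small_ensemble()
  sur <- surrogate_fixture()
  lo <- ens$truth$values
  hi <- lo + 1
  p_lo <- forestloss:::predict_surrogate(sur, lo, ens$members[[1]],
                                         ens$mask)
  p_hi <- forestloss:::predict_surrogate(sur, hi, ens$members[[1]],
                                         ens$mask)
  s_lo <- sum(p_lo[ens$mask]); s_hi <- sum(p_hi[ens$mask])
  expect_gte(s_hi, s_lo - 0.005 * abs(s_lo))  # tree-model flatness slack
})

test_that("opposite-sign regional biases compensate in the union", {
  w <- small_world()
  truth05 <- regrid(flux_grid(w$loss_true, w$grid$lat, w$grid$lon,
                              units = "Mg ha-1 yr-1"), 0.5)
  pattern <- matrix(rep(c(1, -1), each = 10), 20, 20, byrow = TRUE)
  cp <- coupling_spec(n_models = 4, bias = 1.2, bias_field_sd = 0,
                      noise_sd = 10)
  ens <- simulate_ensemble(w, cp, bias_pattern = pattern, seed = 77)
  regs <- halves_regions(w$extent)
  surs <- list()
  for (m in ens$members)
    surs[[m$name]] <- train_surrogate(m, "npp", "noclim", ens$mask,
                                      split_seed = 5)
  obs <- loss_observation_from_maps(truth05$values, 0.05 * truth05$values,
                                    ens$truth, n_maps = 5, seed = 3)
  cr <- apply_constraint(surs, ens, obs, regs, fluxes = "npp")
  d_west <- mean(cr$after_model[, "west", "npp"]) -
    mean(cr$before[, "west", "npp"])
  d_east <- mean(cr$after_model[, "east", "npp"]) -
    mean(cr$before[, "east", "npp"])
  d_union <- d_west + d_east
  expect_lt(abs(d_union), max(abs(d_west), abs(d_east)))
})

test_that("before/after ANOVA matches the closed-form oracle", {
  # identical groups: F = 0, p = 1
  same <- compare_before_after(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # closed-form one-way ANOVA on two fixed groups
  g1 <- c(9.9, 10.1, 10.0, 9.95, 10.05, 10.0)
  g2 <- c(5.1, 4.9, 5.0, 5.05, 4.95, 5.0)
  gm <- mean(c(g1, g2))
  ssb <- 6 * (mean(g1) - gm)^2 + 6 * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f_oracle <- (ssb / 1) / (ssw / 10)
  p_oracle <- stats::pf(f_oracle, 1, 10, lower.tail = FALSE)
  got <- compare_before_after(g1, g2)
  expect_equal(got$F, f_oracle, tolerance = 1e-12)
  expect_equal(got$p, p_oracle, tolerance = 1e-12)
  expect_lt(got$p, 0.001)
  expect_equal(got$stars, "***")
  expect_error(compare_before_after(g1, 5), "degenerate")
})
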