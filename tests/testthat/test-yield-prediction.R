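test_that("standardization uses training parameters only", {
  tr <- matrix(c(1, 2, 3, 5, 5, 5), ncol = 2) # second column constant
  te <- matrix(c(10, 20, 7, 8), ncol = 2)
  expect_message(std <- standardize_features(tr, te), "zero-variance")
  expect_equal(as.numeric(std$train[, 1]), c(-1, 0, 1))
  expect_equal(ncol(std$train), 1)
  # test columns transformed with the train center/scale, not their own
  expect_equal(as.numeric(std$test[, 1]), (c(10, 20) - 2) / 1)
  expect_error(standardize_features(matrix(1, 3, 2)), "constant")
})

test_that("SVR fits a noiseless linear signal essentially perfectly", {
  set.seed(2)
  x <- matrix(rnorm(60), ncol = 1)
  y <- drop(2 * x)
  std <- standardize_features(x, x)
  pred <- svr_fit_predict(std$train, y, std$test, sigma = 0.5, cost = 1000,
                          epsilon = 0.01)
  expect_gte(cor(pred, y), 0.99)
})

test_that("SVR predictions are deterministic and pointwise on the test set", {
  set.seed(3)
  x <- matrix(rnorm(80), ncol = 2)
  y <- x[, 1] - x[, 2] + rnorm(40, 0, 0.1)
  p1 <- svr_fit_predict(x, y, x, sigma = 0.1, cost = 100)
  p2 <- svr_fit_predict(x, y, x, sigma = 0.1, cost = 100)
  expect_identical(p1, p2)
  # appending an extra test row cannot change other rows' predictions
  p3 <- svr_fit_predict(x, y, rbind(x, 0), sigma = 0.1, cost = 100)
  expect_equal(p3[seq_len(nrow(x))], p1)
})

test_that("pure-noise targets give near-zero cross-validated accuracy", {
  set.seed(4)
  x <- matrix(rnorm(60 * 5), ncol = 5)
  y <- rnorm(60)
  run <- grid_search_cv(x, y, k = 5, repeats = 4,
                        sigma_grid = c(0.01, 0.1), cost_grid = list(10, 100),
                        seed = 8)
  expect_lt(abs(run$mean_r), 2 / sqrt(nrow(run$fold_r)))
})

test_that("fold bookkeeping, balancing and reproducibility hold", {
  tr <- simulate_trial(trial_config(n_genotypes = 20, n_reps = 3, rng_seed = 13))
  obs <- simulate_trait_observations(tr, c(400, 800), selections = "RS23",
                                     traits = c("Height95", "NDVI"))
  fm <- feature_matrix(obs, tr$yield, "RS23")
  expect_equal(dim(fm$x), c(60, 4)) # 2 traits x 2 flights
  run <- grid_search_cv(fm$x, fm$y, k = 5, repeats = 3, groups = fm$groups,
                        sigma_grid = c(0.01, 0.1), cost_grid = list(10, "n"),
                        seed = 21)
  expect_equal(nrow(run$fold_r), 15) # k x repeats recorded correlations
  expect_true(all(abs(run$fold_r$r) <= 1, na.rm = TRUE))
  expect_equal(run$mean_r, mean(run$fold_r$r, na.rm = TRUE))
  # the "n" cost token resolves to the feature count
  expect_true(all(run$params$cost %in% c(10, ncol(fm$x))))
  run2 <- grid_search_cv(fm$x, fm$y, k = 5, repeats = 3, groups = fm$groups,
                         sigma_grid = c(0.01, 0.1), cost_grid = list(10, "n"),
                         seed = 21)
  expect_identical(run$fold_r, run2$fold_r)
  # balanced folds: per-fold subpopulation counts differ by at most 1
  set.seed(1)
  groups <- rep(c("temperate", "tropical"), each = 30)
  fold <- rowseg:::make_folds(60, 5, groups)
  counts <- table(fold, groups)
  expect_true(all(apply(counts, 2, function(cc) max(cc) - min(cc)) <= 1))
  expect_error(rowseg:::make_folds(10, 6, rep(c("a", "b"), c(5, 5))),
               "incompatible")
})

test_that("no information leaks from test folds into training", {
  # canary: perturbing a held-out row must not move training-fold predictions
  set.seed(6)
  x <- matrix(rnorm(50 * 3), ncol = 3)
  y <- x[, 1] + rnorm(50, 0, 0.2)
  te <- 41:50
  x_te <- x[te, , drop = FALSE]
  x_te_out <- x_te; x_te_out[1, ] <- 1e3 # wild outlier in the test set only
  std1 <- standardize_features(x[-te, ], x_te)
  std2 <- standardize_features(x[-te, ], x_te_out)
  expect_identical(std1$train, std2$train)
  expect_identical(std1$center, std2$center)
  p_tr1 <- svr_fit_predict(std1$train, y[-te], std1$train, 0.1, 50)
  p_tr2 <- svr_fit_predict(std2$train, y[-te], std2$train, 0.1, 50)
  expect_identical(p_tr1, p_tr2)
  # untouched test rows keep their predictions too
  p_te1 <- svr_fit_predict(std1$train, y[-te], std1$test, 0.1, 50)
  p_te2 <- svr_fit_predict(std2$train, y[-te], std2$test, 0.1, 50)
  expect_equal(p_te1[-1], p_te2[-1])
})

test_that("prediction accuracy decreases with yield noise", {
  mean_rs <- vapply(c(50, 300, 1000), function(noise) {
    tr <- simulate_trial(trial_config(n_genotypes = 20, n_reps = 3,
                                      yield_noise_sd = noise, rng_seed = 17))
    obs <- simulate_trait_observations(tr, c(500, 900), selections = "RS23",
                                       traits = c("Height95", "NDVI"))
    fm <- feature_matrix(obs, tr$yield, "RS23")
    grid_search_cv(fm$x, fm$y, k = 5, repeats = 2, groups = fm$groups,
                   sigma_grid = c(0.01, 0.1), cost_grid = list(10, 100),
                   seed = 3)$mean_r
  }, numeric(1))
  expect_true(all(diff(mean_rs) < 0))
})
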