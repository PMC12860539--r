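test_that("Fourier features obey the sin/cos structure and bounds", {
  map <- fourier_map(d = 5, scale = 0.3, seed = 2)
  expect_identical(dim(map$B), c(5L, 5L))

  # zero input maps to (0,...,0, 1,...,1) for any B
  z <- fourier_features(numeric(5), map)
  expect_equal(as.numeric(z), c(rep(0, 5), rep(1, 5)))

  # a zeroed projection matrix gives the same degenerate output
  map0 <- map; map0$B[] <- 0
  z0 <- fourier_features(rnorm(5), map0)
  expect_equal(as.numeric(z0), c(rep(0, 5), rep(1, 5)))

  # bounded output and the Pythagorean pairing, even for huge raw inputs
  X <- matrix(rnorm(40, sd = 1e4), 8, 5)
  F <- fourier_features(X, map)
  expect_true(all(F >= -1 & F <= 1))
  expect_equal(F[, 1:5]^2 + F[, 6:10]^2, matrix(1, 8, 5), tolerance = 1e-12)

  # the map is frozen: same seed, same B
  expect_identical(fourier_map(d = 5, scale = 0.3, seed = 2)$B, map$B)
  expect_error(fourier_features(matrix(0, 2, 4), map), "expects 5")
})

test_that("z-score standardization round-trips and passes constant columns", {
  M <- cbind(rnorm(50, 3, 2), rep(1.5, 50), rnorm(50))
  z <- needleuq:::zscore_fit(M)
  expect_equal(needleuq:::zscore_invert(needleuq:::zscore_apply(M, z), z), M,
               tolerance = 1e-12)
  expect_identical(z$scale[2], 1)
})

test_that("OLS recovers an exact linear map and zero targets", {
  set.seed(61)
  X <- matrix(runif(300 * 4), 300, 4)
  A <- matrix(rnorm(4 * 3), 4, 3)
  b <- c(1, -2, 0.5)
  Y <- X %*% A + rep(b, each = 300)
  fit <- train_ols(list(X = X, Y = Y))
  expect_equal(predict(fit, X), Y, tolerance = 1e-8)

  fit0 <- train_ols(list(X = X, Y = matrix(0, 300, 3)))
  expect_equal(max(abs(predict(fit0, X))), 0, tolerance = 1e-12)

  expect_error(train_ols(list(X = X[1:3, ], Y = Y[1:3, ])), "more samples")
})

test_that("network surrogates fit zero targets to near zero", {
  set.seed(62)
  X <- matrix(runif(2000 * 6), 2000, 6)
  Y0 <- matrix(0, 2000, 4)
  # early stopping disabled: the check is that optimization drives the
  # predictions to zero, not where the plateau rule halts
  mlp <- train_mlp(list(X = X, Y = Y0), seed = 1, epochs = 800,
                   n_iter_no_change = 0)
  expect_lt(mean(abs(predict(mlp, X))), 1e-3)
  ff <- train_ffnn(list(X = X, Y = Y0), epochs = 1500, seed = 1)
  expect_lt(mean(abs(predict(ff, X))), 1e-3)
})

test_that("training is deterministic under a fixed seed", {
  ds <- small_dataset()
  a <- train_ffnn(ds, epochs = 20, seed = 3)
  b <- train_ffnn(ds, epochs = 20, seed = 3)
  expect_identical(a$weights, b$weights)
  expect_identical(evaluate_surrogate(a, ds, 65)$mae,
                   evaluate_surrogate(b, ds, 65)$mae)
  c <- train_ffnn(ds, epochs = 20, seed = 4)
  expect_false(identical(a$weights, c$weights))
})

test_that("surrogates learn the simulator mapping on a small dataset", {
  ds <- small_dataset()
  ols <- train_ols(ds)
  mlp <- train_mlp(ds, seed = 1)
  # the nonlinear model beats the linear baseline at the reference depth,
  # and beats mean-prediction there (the biased OLS need not)
  i65 <- ds$val$depth == 65
  spread65 <- mean(abs(sweep(ds$val$Y[i65, ], 2,
                             colMeans(ds$train$Y[ds$train$depth == 65, ]))))
  expect_lt(evaluate_surrogate(mlp, ds, 65)$mae,
            evaluate_surrogate(ols, ds, 65)$mae)
  expect_lt(evaluate_surrogate(mlp, ds, 65)$mae, spread65)
})

test_that("evaluation aggregates per-sample MAE and is order-invariant", {
  ds <- small_dataset()
  ols <- train_ols(ds)
  ev <- evaluate_surrogate(ols, ds, depth = 65)
  expect_identical(ev$n, 60L)
  expect_equal(ev$mae, mean(ev$mae_per_sample))

  # a model identical to the simulator has zero error
  perfect <- evaluate_surrogate(ols, list(X = ds$val$X,
                                          Y = predict(ols, ds$val$X),
                                          trajectory = ds$val$trajectory,
                                          depth = ds$val$depth), 65)
  expect_equal(perfect$mae, 0, tolerance = 1e-12)

  # permuting the validation set leaves aggregates unchanged
  set.seed(1); p <- sample(nrow(ds$val$X))
  evp <- evaluate_surrogate(ols, list(X = ds$val$X[p, ], Y = ds$val$Y[p, ],
                                      trajectory = ds$val$trajectory[p],
                                      depth = ds$val$depth[p]), 65)
  expect_equal(evp$mae, ev$mae)
  expect_equal(evp$signed_mean, ev$signed_mean)

  expect_error(evaluate_surrogate(ols, ds, depth = 999), "999")

  tip <- evaluate_surrogate(ols, ds, 65, scope = "tip")
  expect_equal(tip$mae, mean(abs(ev$errors[, 48])))
})

test_that("error profiles bin absolute error along the needle", {
  ds <- small_dataset()
  ols <- train_ols(ds)
  prof <- error_profile(ols, ds, depth = 120, bin = 0.01)
  expect_setequal(unique(prof$node), 1:48)
  # counts per node sum to the number of depth-120 validation samples
  expect_true(all(tapply(prof$count, prof$node, sum) == 60))
  expect_true(all(prof$bin_lower_mm >= 0))
})

test_that("models round-trip through JSON serialization", {
  ds <- small_dataset()
  Xv <- ds$val$X[1:20, ]
  for (model in list(train_ols(ds),
                     train_mlp(ds, seed = 1, epochs = 30),
                     train_ffnn(ds, epochs = 30, seed = 1))) {
    path <- withr::local_tempfile(fileext = ".json")
    save_surrogate(model, path)
    back <- load_surrogate(path)
    expect_identical(back$kind, model$kind)
    expect_equal(predict(back, Xv), predict(model, Xv), tolerance = 1e-12)
  }
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"format\": \"something-else\"}", bad)
  expect_error(load_surrogate(bad), "not a saved")
})

test_that("grid search scores every cell and returns the argmin", {
  ds <- generate_dataset(n_train = 20, n_val = 0, seed = 77)
  g1 <- grid_search_ffnn(ds, lr_grid = 0.005, scale_grid = 0.2,
                         epochs = 10, seed = 1)
  expect_identical(nrow(g1$table), 1L)
  expect_equal(unname(g1$best["lr"]), 0.005)

  g <- grid_search_ffnn(ds, lr_grid = c(0.005, 0.001),
                        scale_grid = c(0.1, 0.3), epochs = 10, seed = 1)
  expect_identical(nrow(g$table), 4L)
  expect_true(all(is.finite(g$table$mae)))
  best_row <- which.min(g$table$mae)
  expect_equal(unname(g$best["lr"]), g$table$lr[best_row])
  expect_equal(unname(g$best["scale"]), g$table$scale[best_row])
})

test_that("a diverging learning rate aborts with a diagnostic naming it", {
  set.seed(3)
  X <- matrix(runif(100 * 3), 100, 3)
  Y <- matrix(rnorm(100 * 2, sd = 5), 100, 2)
  expect_error(train_ffnn(list(X = X, Y = Y), lr = 1e12, epochs = 50,
                          seed = 1), "lr")
})
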