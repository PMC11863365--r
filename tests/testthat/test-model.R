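test_that("the same seed reproduces the identical model", {
  d <- simulate_descriptor_study(n = 40, p = 30, seed = 3)
  m1 <- train_sensitivity_model(d$X, d$y, seed = 17)
  m2 <- train_sensitivity_model(d$X, d$y, seed = 17)
  expect_identical(m1$train_ids, m2$train_ids)
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$selected_descriptors, m2$selected_descriptors)
  expect_identical(predict_mR(m1, d$X), predict_mR(m2, d$X))
})

test_that("an 80:20 split of 50 lipids yields 40 train and 10 test", {
  d <- simulate_descriptor_study(n = 50, p = 20, seed = 5)
  m <- train_sensitivity_model(d$X, d$y, seed = 2, split_fraction = 0.8)
  expect_length(m$train_ids, 40)
  expect_length(m$test_ids, 10)
  expect_length(intersect(m$train_ids, m$test_ids), 0)
  expect_setequal(c(m$train_ids, m$test_ids), rownames(d$X))
})

test_that("a noise-free linear target is recovered almost exactly", {
  set.seed(1)
  n <- 50; p <- 20
  X <- matrix(runif(n * p, -1, 1), n, p,
              dimnames = list(paste0("l", 1:n), paste0("d", 1:p)))
  y <- setNames(2 + 0.5 * X[, 1] + 0.3 * X[, 2] + 0.2 * X[, 3], rownames(X))
  m <- train_sensitivity_model(X, y, seed = 5)
  expect_lt(m$test_mdape, 5)
})

test_that("scaler parameters depend on training rows only", {
  d <- simulate_descriptor_study(n = 40, p = 15, seed = 8)
  m1 <- train_sensitivity_model(d$X, d$y, seed = 4)
  X2 <- d$X
  X2[m1$test_ids[1], ] <- X2[m1$test_ids[1], ] + 100
  m2 <- train_sensitivity_model(X2, d$y, seed = 4)
  expect_identical(m1$scaler, m2$scaler)
})

test_that("prediction requires the selected descriptors and is row-deterministic", {
  d <- simulate_descriptor_study(n = 40, p = 15, seed = 8)
  m <- train_sensitivity_model(d$X, d$y, seed = 4)
  expect_error(predict_mR(m, d$X[, -match(m$selected_descriptors[1], colnames(d$X))]),
               m$selected_descriptors[1])
  two <- d$X[c(1, 1), ]
  p2 <- predict_mR(m, two)
  expect_identical(p2[[1]], p2[[2]])
  expect_true(all(predict_mR(m, d$X) > 0))
})

test_that("training predictions stay within the training residual band", {
  d <- simulate_descriptor_study(n = 40, p = 15, noise_sd = 0.05, seed = 12)
  m <- train_sensitivity_model(d$X, d$y, seed = 4)
  pr <- predict_mR(m, d$X[m$train_ids, ])
  expect_lt(median(abs(pr - d$y[m$train_ids]) / d$y[m$train_ids]), 0.25)
})

test_that("the ensemble selects the lower-median error model deterministically", {
  d <- simulate_descriptor_study(n = 40, p = 25, seed = 21)
  ens1 <- run_ensemble(d$X, d$y, n_iterations = 3, base_seed = 100)
  expect_equal(ens1$errors[ens1$selected_index], sort(ens1$errors)[2])
  ens2 <- run_ensemble(d$X, d$y, n_iterations = 3, base_seed = 100)
  expect_identical(ens1$selected_index, ens2$selected_index)
  expect_identical(predict_mR(ens1$selected_model, d$X),
                   predict_mR(ens2$selected_model, d$X))
  one <- run_ensemble(d$X, d$y, n_iterations = 1, base_seed = 7)
  expect_equal(one$selected_index, 1L)
  # even count: the lower median is taken
  ens4 <- run_ensemble(d$X, d$y, n_iterations = 4, base_seed = 100)
  expect_equal(ens4$errors[ens4$selected_index], sort(ens4$errors)[2])
})

test_that("Box-Cox on reduces mean percent error relative to Box-Cox off", {
  mean_apes <- sapply(1:3, function(r) {
    d <- simulate_descriptor_study(n = 60, p = 40, noise_sd = 0.05,
                                   seed = 300 + r)
    on <- train_sensitivity_model(d$X, d$y, seed = r, use_boxcox = TRUE)
    off <- train_sensitivity_model(d$X, d$y, seed = r, use_boxcox = FALSE)
    c(on = on$test_mean_ape, off = off$test_mean_ape)
  })
  expect_lte(mean(mean_apes["on", ]), mean(mean_apes["off", ]) * 1.05)
})

test_that("descriptor importance recovers the informative set and aggregates families", {
  d <- simulate_descriptor_study(n = 50, p = 40, k_informative = 3,
                                 noise_sd = 0.02, seed = 60)
  ens <- run_ensemble(d$X, d$y, n_iterations = 5, base_seed = 10)
  imp <- descriptor_importance(ens)
  top <- head(imp$by_descriptor$descriptor, 6)
  expect_gte(sum(d$informative %in% top), 2)
  # RFE disabled: every descriptor is always selected
  ens_all <- run_ensemble(d$X, d$y, n_iterations = 2, base_seed = 10,
                          use_rfe = FALSE)
  imp_all <- descriptor_importance(ens_all)
  expect_true(all(imp_all$by_descriptor$frequency == 1))
  expect_equal(nrow(imp_all$by_descriptor), ncol(d$X))
})

test_that("the learning curve has one row per usable fraction and warns otherwise", {
  d <- simulate_descriptor_study(n = 30, p = 15, seed = 33)
  lc <- learning_curve(d$X, d$y, split_fractions = 0.8,
                       n_iterations_per_point = 2)
  expect_equal(nrow(lc), 1)
  expect_equal(lc$split_fraction, 0.8)
  expect_true(is.finite(lc$mdape))
  d20 <- simulate_descriptor_study(n = 20, p = 10, seed = 34)
  expect_warning(
    lc2 <- learning_curve(d20$X, d20$y, split_fractions = c(0.94, 0.8),
                          n_iterations_per_point = 2),
    "skipped")
  expect_equal(nrow(lc2), 1)
})

test_that("a saved model bundle round-trips exactly", {
  d <- simulate_descriptor_study(n = 30, p = 10, seed = 70)
  m <- train_sensitivity_model(d$X, d$y, seed = 2)
  tf <- tempfile(fileext = ".rds")
  save_sensitivity_model(m, tf)
  m2 <- load_sensitivity_model(tf)
  expect_identical(predict_mR(m, d$X), predict_mR(m2, d$X))
  unlink(tf)
})
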