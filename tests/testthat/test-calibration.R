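test_that("an exact line is fitted exactly", {
  fit <- fit_calibration_curve(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fit$slope_m, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
})

test_that("constant areas give slope 0 and R-squared 0", {
  fit <- fit_calibration_curve(c(1, 2, 3), c(5, 5, 5))
  expect_equal(fit$slope_m, 0)
  expect_equal(fit$r_squared, 0)
})

test_that("slope, intercept and R-squared match the lm() oracle on random series", {
  set.seed(91)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    concs <- sort(runif(n, 0.1, 10))
    while (any(diff(concs) <= 0)) concs <- sort(runif(n, 0.1, 10))
    areas <- runif(1, 0.5, 50) * concs + rnorm(n)
    fit <- fit_calibration_curve(concs, areas)
    ref <- lm(areas ~ concs)
    expect_equal(fit$slope_m, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(fit$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  }
})

test_that("level policy drops the top level by default and is configurable", {
  expect_equal(apply_level_policy(6), 1:5)
  expect_equal(apply_level_policy(6, "none"), 1:6)
  expect_equal(apply_level_policy(4, "drop_top_k", k = 1), 1:3)
  expect_error(apply_level_policy(3, "drop_top"), "fewer than 3")
})

test_that("relativization divides by the reference slope and sets it to exactly 1", {
  cal <- data.frame(lipid_id = c("a", "b", "ref"),
                    lipid_class = "PC",
                    slope_m = c(4, 2, 2), intercept = 0,
                    r_squared = 1, m_R = NA_real_, status = "included",
                    stringsAsFactors = FALSE)
  out <- relativize_slopes(cal, "ref")
  expect_equal(out$m_R, c(2, 1, 1))
  expect_identical(out$m_R[3], 1)

  cal$slope_m[3] <- 0
  cal$status[3] <- "excluded_nonpositive_slope"
  expect_error(relativize_slopes(cal, "ref"), "cannot relativize")
})

test_that("ratios of relative sensitivities do not depend on the reference", {
  set.seed(7)
  for (i in 1:20) {
    slopes <- runif(6, 0.1, 10)
    cal <- data.frame(lipid_id = paste0("l", 1:6), lipid_class = "PC",
                      slope_m = slopes, intercept = 0, r_squared = 1,
                      m_R = NA_real_, status = "included",
                      stringsAsFactors = FALSE)
    out1 <- relativize_slopes(cal, "l1")
    out2 <- relativize_slopes(cal, "l4")
    expect_equal(out1$m_R[2] / out1$m_R[3], slopes[2] / slopes[3])
    expect_equal(out1$m_R[2] / out1$m_R[3], out2$m_R[2] / out2$m_R[3])
  }
})

test_that("relative sensitivities are invariant to a global area rescaling", {
  sim <- small_sim(seed = 5)
  cal1 <- calibrate_panel(sim$panel, sim$responses, "positive")
  resp2 <- sim$responses
  resp2$areas$area <- resp2$areas$area * 137.5
  cal2 <- calibrate_panel(sim$panel, resp2, "positive")
  expect_equal(cal2$m_R, cal1$m_R, tolerance = 1e-12)
})

test_that("noise-free responses reproduce the true sensitivities", {
  sim <- small_sim(seed = 9, noise_sd = 0)
  cal <- calibrate_panel(sim$panel, sim$responses, "positive")
  expect_true(all(cal$status == "included"))
  expect_equal(cal$m_R, unname(sim$true_mR[cal$lipid_id]), tolerance = 1e-9)
})

test_that("a saturating top level triggers the linearity filter only without the level-drop policy", {
  sat_id <- "PC_30_1"
  sim <- small_sim(seed = 11, noise_sd = 0, saturating_ids = sat_id)
  cal_drop <- calibrate_panel(sim$panel, sim$responses, "positive")
  cal_all <- calibrate_panel(sim$panel, sim$responses, "positive",
                             levels_used = apply_level_policy(6, "none"))
  expect_equal(cal_drop$status[cal_drop$lipid_id == sat_id], "included")
  expect_equal(cal_all$status[cal_all$lipid_id == sat_id], "excluded_linearity")
  expect_lt(cal_all$r_squared[cal_all$lipid_id == sat_id], 0.8)
  tt_drop <- build_training_table(cal_drop, sim$descriptors)
  tt_all <- build_training_table(cal_all, sim$descriptors)
  expect_equal(nrow(tt_drop$X) - 1L, nrow(tt_all$X))
})

test_that("the training table keeps only included lipids with descriptors", {
  cal <- data.frame(lipid_id = paste0("l", 1:7), lipid_class = "PC",
                    slope_m = 1, intercept = 0, r_squared = 1,
                    m_R = 1:7,
                    status = c(rep("included", 5), "excluded_linearity",
                               "excluded_missing"),
                    stringsAsFactors = FALSE)
  desc <- matrix(rnorm(45), 9, 5,
                 dimnames = list(c(paste0("l", 1:7), "x1", "x2"), paste0("d", 1:5)))
  expect_warning(tt <- build_training_table(cal, desc), "fewer than 10")
  expect_equal(rownames(tt$X), paste0("l", 1:5))
  expect_equal(unname(tt$y), 1:5)
})
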