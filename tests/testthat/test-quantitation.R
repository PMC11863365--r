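test_that("concentration follows the relativized blank-subtracted response", {
  # relativized (y - b) = 6, m_R = 3 -> concentration 2
  expect_equal(as.numeric(predict_concentration(y = 700, b = 100, mR = 3,
                                                reference_area = 100)), 2)
  # blank-only sample
  expect_equal(as.numeric(predict_concentration(y = 50, b = 50, mR = 2,
                                                reference_area = 100)), 0)
  # negative estimates are floored and flagged
  out <- predict_concentration(y = 10, b = 50, mR = 2, reference_area = 100)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "floored"))
  expect_error(predict_concentration(1, 0, mR = 0, reference_area = 1), "m_R")
  expect_error(predict_concentration(1, 0, mR = 1, reference_area = 0),
               "reference areas")
})

test_that("noise-free simulated samples are quantified exactly with true sensitivities", {
  sim <- small_sim(seed = 3, noise_sd = 0)
  q <- quantify_samples(sim$responses, sim$panel, sim$true_mR, "positive")
  expect_true(all(is.finite(q$predicted_conc)))
  expect_lt(max(abs(q$predicted_conc - q$true_conc) / q$true_conc), 1e-9)
})

test_that("quantitation is invariant to a common area rescaling", {
  sim <- small_sim(seed = 3)
  q1 <- quantify_samples(sim$responses, sim$panel, sim$true_mR, "positive")
  resp2 <- sim$responses
  resp2$areas$area <- resp2$areas$area * 0.037
  q2 <- quantify_samples(resp2, sim$panel, sim$true_mR, "positive")
  expect_equal(q2$predicted_conc, q1$predicted_conc, tolerance = 1e-12)
})

test_that("surrogate matching prefers class, then chain length, then double bonds", {
  stds <- data.frame(lipid_id = c("PC_30_1", "PC_34_1", "PG_33_1"),
                     lipid_class = c("PC", "PC", "PG"),
                     carbons = c(30, 34, 33), double_bonds = c(1, 1, 1),
                     conc = 1, area = 1, stringsAsFactors = FALSE)
  an <- list(lipid_class = "PC", carbons = 33, double_bonds = 1, area = 1)
  expect_equal(match_surrogate(an, stds)$lipid_id, "PC_34_1")
  # chain tie broken by double bonds
  stds2 <- data.frame(lipid_id = c("PC_32_0", "PC_34_3"), lipid_class = "PC",
                      carbons = c(32, 34), double_bonds = c(0, 3),
                      conc = 1, area = 1, stringsAsFactors = FALSE)
  an2 <- list(lipid_class = "PC", carbons = 33, double_bonds = 0, area = 1)
  expect_equal(match_surrogate(an2, stds2)$lipid_id, "PC_32_0")
  # full tie: lexicographically smallest id
  stds3 <- data.frame(lipid_id = c("PC_b", "PC_a"), lipid_class = "PC",
                      carbons = 33, double_bonds = 1,
                      conc = 1, area = 1, stringsAsFactors = FALSE)
  expect_equal(match_surrogate(an, stds3)$lipid_id, "PC_a")
  expect_error(match_surrogate(list(lipid_class = "TG", carbons = 50,
                                    double_bonds = 1), stds),
               "no surrogate")
})

test_that("one-point calibration is exact for an identical matched standard", {
  stds <- data.frame(lipid_id = "PC_33_1", lipid_class = "PC", carbons = 33,
                     double_bonds = 1, conc = 4, area = 200,
                     stringsAsFactors = FALSE)
  an <- list(lipid_class = "PC", carbons = 33, double_bonds = 1, area = 100)
  out <- one_point_calibration(an, stds)
  expect_equal(out$conc, 2)
  expect_equal(out$matched_standard, "PC_33_1")
})

test_that("a class of identical sensitivities gives the one-point answer; singletons fall back", {
  m <- 50
  stds <- data.frame(lipid_id = paste0("PC_", c(30, 32, 34), "_1"),
                     lipid_class = "PC", carbons = c(30, 32, 34),
                     double_bonds = 1, conc = c(1, 2, 4),
                     area = m * c(1, 2, 4), stringsAsFactors = FALSE)
  an <- list(lipid_class = "PC", carbons = 32, double_bonds = 1, area = m * 3)
  cc <- class_curve_calibration(an, stds)
  op <- one_point_calibration(an, stds)
  expect_equal(cc$conc, 3)
  expect_equal(cc$conc, op$conc)
  expect_warning(single <- class_curve_calibration(an, stds[1, ]),
                 "one-point")
  expect_equal(single$n_standards, 1L)
  expect_equal(single$matched_standard, "PC_30_1")
})
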