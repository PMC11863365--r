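make_quant <- function(pred, truth, lipids, samples) {
  q <- data.frame(sample_id = samples, lipid_id = lipids, method = "svr_model",
                  predicted_mR = 1, y = 1, b = 0,
                  predicted_conc = pred, true_conc = truth,
                  stringsAsFactors = FALSE)
  q$percent_error <- 100 * abs(q$predicted_conc - q$true_conc) / q$true_conc
  class(q) <- c("quant_result", "data.frame")
  q
}

test_that("perfect predictions give zero error and zero imprecision", {
  q <- make_quant(rep(2, 6), rep(2, 6),
                  rep(c("a", "b"), each = 3), rep(paste0("s", 1:3), 2))
  rep <- percent_error_summary(q)
  expect_equal(rep$global_mean_error, 0)
  expect_equal(rep$precision, 0)
  expect_length(rep$outlier_ids, 0)
})

test_that("a constant +50% bias gives mean APE 50 and CV 0 for that lipid", {
  q <- make_quant(c(3, 3, 3, 2, 2, 2), rep(2, 6),
                  rep(c("hi", "ok"), each = 3), rep(paste0("s", 1:3), 2))
  rep <- percent_error_summary(q)
  pl <- rep$per_lipid
  expect_equal(pl$mean_ape[pl$lipid_id == "hi"], 50)
  expect_equal(pl$cv[pl$lipid_id == "hi"], 0)
})

test_that("precision equals the hand-computed mean CV on a 3x5 toy table", {
  set.seed(2)
  pred <- runif(15, 1, 3)
  lipids <- rep(c("a", "b", "c"), each = 5)
  q <- make_quant(pred, rep(2, 15), lipids, rep(paste0("s", 1:5), 3))
  byhand <- mean(sapply(split(pred, lipids),
                        function(v) 100 * sd(v) / mean(v)))
  expect_equal(percent_error_summary(q)$precision, byhand)
})

test_that("precision with replicate groups averages within-group CVs", {
  set.seed(5)
  pred <- c(runif(3, 0.9, 1.1), runif(3, 9, 11))   # two levels, 3 replicates
  q <- make_quant(pred, rep(c(1, 10), each = 3), "a", paste0("s", 1:6))
  groups <- setNames(rep(c("L1", "L2"), each = 3), paste0("s", 1:6))
  rep <- percent_error_summary(q, replicate_groups = groups)
  byhand <- mean(c(100 * sd(pred[1:3]) / mean(pred[1:3]),
                   100 * sd(pred[4:6]) / mean(pred[4:6])))
  expect_equal(rep$precision, byhand)
  # default (ungrouped) mixes the levels and is far larger
  expect_gt(percent_error_summary(q)$precision, rep$precision * 5)
})

test_that("10% multiplicative noise yields the folded-normal mean error", {
  set.seed(77)
  n <- 4000
  truth <- runif(n, 1, 5)
  pred <- truth * (1 + rnorm(n, 0, 0.1))
  q <- make_quant(pred, truth, paste0("l", seq_len(n)), "s1")
  rep <- suppressWarnings(percent_error_summary(q))
  expect_equal(rep$global_mean_error, 100 * 0.1 * sqrt(2 / pi),
               tolerance = 0.05)
})

test_that("the outlier rule flags gross outliers, never homogeneous errors", {
  expect_length(outlier_rule(setNames(rep(20, 8) + (1:8) / 10, letters[1:8])), 0)
  errs <- setNames(c(rep(20, 9) + (1:9) / 5, 200), letters[1:10])
  expect_equal(outlier_rule(errs), "j")
  expect_length(outlier_rule(c(a = 1, b = 100, c = 1, d = 1)), 0)  # < 5 lipids
})

test_that("the with-outlier global error is never below the without-outlier one", {
  set.seed(10)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    pred <- runif(n, 0.5, 2)
    if (i %% 2 == 0) pred[1] <- 10
    q <- make_quant(pred, rep(1, n), paste0("l", 1:n), "s1")
    rep <- percent_error_summary(q)
    expect_gte(rep$global_mean_error, rep$global_mean_error_outliers_removed)
  }
})

test_that("rows without truth are dropped with a warning", {
  q <- make_quant(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, NA, 5, 6),
                  paste0("l", 1:6), "s1")
  expect_warning(rep <- percent_error_summary(q), "dropped")
  expect_equal(nrow(rep$per_lipid), 5)
})

test_that("leave-class-out on an out-of-law class yields negative R2; a single held lipid reports APE", {
  d <- simulate_descriptor_study(n = 50, p = 30, noise_sd = 0.02, seed = 90)
  cls <- rep(c("A", "B", "C", "D", "E"), each = 10)
  y <- d$y
  y[cls == "E"] <- y[cls == "E"] * exp(3)   # offset far outside training law
  out <- holdout_by_class(d$X, y, cls, "E", seed = 1)
  expect_lt(out$r2, 0)
  expect_equal(out$n_train, 40)
  # in-law class: far better generalization than the out-of-law one
  inlaw <- holdout_by_class(d$X, d$y, cls, "E", seed = 1)
  expect_gt(inlaw$r2, out$r2)
  # degenerate: one held lipid -> R2 undefined, APE still reported
  cls1 <- c("solo", rep("rest", 49))
  one <- holdout_by_class(d$X, d$y, cls1, "solo", seed = 1)
  expect_true(is.na(one$r2))
  expect_equal(nrow(one$per_lipid), 1)
  expect_true(is.finite(one$per_lipid$ape))
})

test_that("size hold-outs pick per-class mass extremes with deterministic ties", {
  d <- simulate_descriptor_study(n = 40, p = 20, noise_sd = 0.02, seed = 91)
  cls <- rep(c("A", "B", "C", "D"), each = 10)
  masses <- rep(seq(400, 850, 50), 4)
  out <- holdout_by_size(d$X, d$y, masses, cls, "largest", k_per_class = 1)
  expect_length(out$held_ids, 4)
  expect_true(all(out$held_ids %in% rownames(d$X)[masses == 850]))
  # mass tie: lexicographically smallest id is held out
  masses2 <- rep(500, 40)
  out2 <- holdout_by_size(d$X, d$y, masses2, cls, "smallest", k_per_class = 1)
  expect_equal(out2$held_ids,
               unname(vapply(split(rownames(d$X), cls),
                             function(v) sort(v)[1], "")))
  expect_warning(
    holdout_by_size(d$X, d$y, masses, c("tiny", cls[-1]), "largest"),
    "too small")
})

test_that("recovery is the matrix/neat area ratio with enhancement flagging", {
  m <- c(a = 100, b = 120, c = 0)
  n <- c(a = 100, b = 100, c = 100, d = 50)
  out <- recovery(m, n)
  expect_equal(out$recovery, c(100, 120, 0))
  expect_equal(out$flag, c("", "enhancement", ""))
  out2 <- recovery(c(a = 10), c(a = 0))
  expect_true(is.na(out2$recovery))
  expect_equal(out2$flag, "undefined")
})
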