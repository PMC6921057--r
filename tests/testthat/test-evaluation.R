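test_that("obs/pred ratios summarize with mean, range and CI policy", {
  r <- ratio_obs_pred(c(7.86, 8.15), c(6.23, 6.22))
  expect_equal(r$ratios, c(7.86 / 6.23, 8.15 / 6.22))
  expect_equal(r$mean, mean(c(7.86 / 6.23, 8.15 / 6.22)))
  expect_true(all(is.na(r$ci95)))      # n = 2: range only
  r3 <- ratio_obs_pred(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$mean, 1)
  expect_equal(r3$ci95, c(1, 1))       # zero spread collapses the CI
  expect_error(ratio_obs_pred(1, 0), "non-positive")
})

test_that("AFE is the geometric mean of fold errors", {
  expect_equal(afe(c(2, 0.5), c(1, 1)), 1, tolerance = 1e-12)
  expect_equal(afe(c(3, 7), c(3, 7)), 1)
  set.seed(8)
  obs <- runif(20, 0.5, 20); pred <- runif(20, 0.5, 20)
  expect_equal(afe(obs, pred), exp(mean(log(obs / pred))), tolerance = 1e-12)
  expect_equal(afe(rev(obs), rev(pred)), afe(obs, pred), tolerance = 1e-12)
})

test_that("RMSE matches hand arithmetic and is order-invariant", {
  expect_equal(rmse(c(4, 4), c(4, 4)), 0)
  expect_equal(rmse(10, 8), 2)
  set.seed(9)
  obs <- runif(15, 1, 10); pred <- runif(15, 1, 10)
  expect_equal(rmse(rev(obs), rev(pred)), rmse(obs, pred), tolerance = 1e-12)
})

test_that("two-fold band is inclusive at both boundaries", {
  expect_true(twofold_check(1, 2)$within)     # ratio 0.5
  expect_true(twofold_check(2, 1)$within)     # ratio 2
  expect_false(twofold_check(2.01, 1)$within)
  tf <- twofold_check(c(1, 3, 0.4), c(1, 1, 1))
  expect_equal(tf$within, c(TRUE, FALSE, FALSE))
  expect_false(tf$overall)
})

test_that("goodness-of-fit residuals behave on degenerate inputs", {
  obs <- data.frame(time = 0:10, conc = 5 * exp(-0.3 * (0:10)))
  g0 <- gof_residuals(obs, obs)
  expect_equal(g0$residual, rep(0, 11))
  pred2 <- data.frame(time = seq(0, 10, 0.5),
                      conc = 2 * 5 * exp(-0.3 * seq(0, 10, 0.5)))
  g2 <- gof_residuals(obs, pred2)
  # predicted exactly twice observed: every point sits on the envelope edge
  expect_equal(g2$observed / g2$predicted, rep(0.5, 11), tolerance = 1e-9)
  expect_true(all(g2$within_twofold))
  expect_error(gof_residuals(obs, data.frame(time = 20:30, conc = 1:11)),
               "overlap")
})

test_that("residuals against a noisy realization of the truth center on zero", {
  truth <- data.frame(time = seq(0, 24, 0.5),
                      conc = 8 * (exp(-0.15 * seq(0, 24, 0.5)) -
                                    exp(-1.2 * seq(0, 24, 0.5))))
  obs <- generate_observed(truth, noise_model(proportional_cv = 0.2,
                                              additive_sd = 0, lloq = 0,
                                              n_subjects = 200, seed = 31))
  g <- gof_residuals(obs$mean_profile, truth)
  expect_lt(abs(mean(g$residual)) / mean(truth$conc), 0.02)
})

test_that("the packaged pair table reproduces the published summary shapes", {
  pairs <- observed_predicted_pairs()
  expect_false(any(pairs$population == "tuberculosis"))  # flagged out
  all_pairs <- observed_predicted_pairs(include_flagged = TRUE)
  expect_equal(sum(all_pairs$flag != ""), 9)
  t5 <- reproduce_evaluation_summary(pairs)
  expect_true(all(c("mean_ratio", "afe", "rmse", "within_twofold") %in%
                    names(t5)))
  # healthy oral group: 4 dose levels per parameter, all within two-fold
  ho <- t5[t5$population == "healthy" & t5$route == "oral", ]
  expect_equal(ho$n, rep(4, 3))
  expect_true(all(ho$within_twofold))
  # n >= 3 groups carry a finite CI
  expect_true(all(is.finite(ho$ci95_lo)))
})
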