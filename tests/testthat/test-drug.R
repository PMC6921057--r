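test_that("an unbound neutral compound partitions like tissue water", {
  comp <- water_only_composition()
  ps <- predict_kp(neutral_unbound_drug(), comp)
  tis <- comp[comp$tissue != "blood_cells", ]
  expected <- setNames(tis$f_ew + tis$f_iw, tis$tissue)
  expect_equal(ps$kp[names(expected)], expected, tolerance = 1e-6)
  # Vss oracle: independent arithmetic sum over volumes x water fractions
  ref <- reference_physiology()
  v <- ref$organ_volumes
  vt <- v[setdiff(names(v), "blood")]
  vss_hand <- (unname(v["blood"]) + sum(vt * expected[names(vt)])) / 70
  expect_equal(ps$vss_pred, vss_hand, tolerance = 1e-6)
})

test_that("rifampicin Vss prediction lands in the literature range", {
  ps <- predict_kp(rifampicin_parameters())
  expect_gt(ps$vss_pred, 0.33)
  expect_lt(ps$vss_pred, 0.53)
  expect_true(all(ps$kp > 0))
  # exceeds the plasma volume per kg, as any distribution volume must
  expect_gt(ps$vss_pred, 5.6 * 0.55 / 70)
})

test_that("Kp prediction is deterministic and invariant to tissue ordering", {
  comp <- default_tissue_composition()
  ps1 <- predict_kp(rifampicin_parameters(), comp)
  set.seed(5)
  ps2 <- predict_kp(rifampicin_parameters(), comp[sample(nrow(comp)), ])
  expect_identical(ps1$kp, ps2$kp)
  expect_identical(ps1$vss_pred, ps2$vss_pred)
})

test_that("Vss grows with lipophilicity for a neutral compound", {
  d <- neutral_unbound_drug()
  d$fu_plasma <- 0.5
  comp <- default_tissue_composition()
  vss <- vapply(seq(0, 3, by = 0.5), function(lp) {
    d$logP_ow <- lp
    predict_kp(d, comp)$vss_pred
  }, numeric(1))
  expect_true(all(diff(vss) > 0))
})

test_that("albumin-type binding contribution is linear in (1-fu)/fu", {
  comp <- default_tissue_composition()
  comp$f_nl <- 0; comp$f_np <- 0       # freeze the non-binding terms
  d <- neutral_unbound_drug()          # logP -12: lipid terms extinguished
  d$fu_plasma <- 0.5                   # (1-fu)/fu = 1
  kpu1 <- predict_kp(d, comp)$kpu
  d$fu_plasma <- 1 / 3                 # (1-fu)/fu = 2
  kpu2 <- predict_kp(d, comp)$kpu
  tis <- comp[comp$tissue != "blood_cells", ]
  water <- setNames(tis$f_ew + tis$f_iw, tis$tissue)
  bind1 <- kpu1 - water[names(kpu1)]
  bind2 <- kpu2 - water[names(kpu2)]
  expect_equal(unname(bind2), unname(2 * bind1), tolerance = 1e-3)
})

test_that("fu adjustment follows the one-binding-protein model", {
  expect_equal(adjust_fu(0.34, 45, 45), 0.34)
  expect_equal(adjust_fu(0.34, 45, 38),
               1 / (1 + (38 / 45) * (0.66 / 0.34)), tolerance = 1e-12)
  expect_equal(round(adjust_fu(0.34, 45, 38), 3), 0.379)
  expect_equal(adjust_fu(0.34, 45, 0), 1)
  # strictly decreasing in disease albumin, image inside (0, 1]
  alb <- seq(0, 120, by = 5)
  fu <- vapply(alb, function(a) adjust_fu(0.34, 45, a), numeric(1))
  expect_true(all(diff(fu) < 0))
  expect_true(all(fu > 0 & fu <= 1))
  expect_error(adjust_fu(0.34, -1, 38), "positive")
})

test_that("unbound blood fraction converts and caps correctly", {
  expect_equal(fu_blood(0.34, 0.67), 0.34 / 0.67)
  expect_equal(round(fu_blood(0.34, 0.67), 4), 0.5075)
  expect_equal(fu_blood(0.5, 1), 0.5)
  expect_warning(capped <- fu_blood(0.9, 0.8), "capping")
  expect_equal(capped, 1)
  expect_error(fu_blood(0.34, 0), "positive")
})

test_that("partitioning inputs are validated", {
  d <- rifampicin_parameters()
  d$fu_plasma <- 0
  expect_error(predict_kp(d), "fu_plasma")
  comp <- default_tissue_composition()
  expect_error(predict_kp(rifampicin_parameters(),
                          comp[comp$tissue != "muscle", ]), "muscle")
  d2 <- rifampicin_parameters()
  d2$pKa_acidic <- 9   # not an ampholyte ordering
  expect_error(validate_drug(d2), "ampholyte")
})
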