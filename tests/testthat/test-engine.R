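test_that("retrograde intrinsic clearance matches the closed form", {
  expect_equal(retrograde_clint(7, 90, 0.5075), 7 * 90 / (0.5075 * 83),
               tolerance = 1e-12)
  expect_equal(round(retrograde_clint(7, 90, 0.5075), 2), 14.96)
  # low-extraction limit: CLu_int -> CL_H when fu_b = 1 and CL_H << Q_H
  expect_equal(retrograde_clint(0.01, 100, 1), 0.01, tolerance = 1e-3)
  expect_error(retrograde_clint(95, 90, 0.5), "flow-limited")
  expect_error(retrograde_clint(0, 90, 0.5), "positive")
})

test_that("retrograde and forward well-stirred forms are exact inverses", {
  grid <- expand.grid(cl = c(0.5, 3, 7, 20), q = c(50, 90, 120),
                      fu = c(0.1, 0.5075, 1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    clu <- retrograde_clint(g$cl, g$q, g$fu)
    expect_equal(wellstirred_cl(clu, g$q, g$fu), g$cl, tolerance = 1e-10)
  }
})

test_that("absorption rate constant follows the permeability relation", {
  expect_equal(ka_from_peff(2.4e-4, 1.75), 2 * 2.4e-4 / 1.75 * 3600,
               tolerance = 1e-12)
  expect_equal(round(ka_from_peff(2.4e-4), 3), 0.987)
  expect_equal(round(ka_from_peff(2.15e-4), 3), 0.885)
  expect_equal(ka_from_peff(4.8e-4), 2 * ka_from_peff(2.4e-4))
})

test_that("i.v. AUC obeys the linear-clearance identity", {
  p <- simulate_profile(ref_phys, ref_drug, ref_partition, iv600())
  m <- run_nca(p$time, p$conc_plasma, 600, "iv", infusion_duration = 0.5)
  expect_equal(m$auc_0_inf, 600 / p$cl_total_plasma, tolerance = 0.01)
  # and NCA recovers the engine's total plasma clearance within 2%
  expect_equal(m$cl_over_f, p$cl_total_plasma, tolerance = 0.02)
})

test_that("mass balance closes to 0.1% at every output time", {
  p_iv <- simulate_profile(ref_phys, ref_drug, ref_partition, iv600())
  expect_lt(max(abs(mass_balance_error(p_iv))), 1e-3)
  p_po <- simulate_profile(ref_phys, ref_drug, ref_partition, oral600())
  expect_lt(max(abs(mass_balance_error(p_po))), 1e-3)
})

test_that("AUC and Cmax are dose-linear", {
  reg300 <- dose_regimen("oral", dose_mg = 300, times = fast_times)
  p3 <- simulate_profile(ref_phys, ref_drug, ref_partition, reg300)
  p6 <- simulate_profile(ref_phys, ref_drug, ref_partition, oral600())
  m3 <- run_nca(p3$time, p3$conc_plasma, 300, "oral")
  m6 <- run_nca(p6$time, p6$conc_plasma, 600, "oral")
  expect_equal(m6$auc_0_inf / m3$auc_0_inf, 2, tolerance = 1e-6)
  expect_equal(m6$cmax / m3$cmax, 2, tolerance = 1e-6)
})

test_that("a no-elimination unit-Kp system conserves a well-mixed plateau", {
  d <- neutral_unbound_drug()
  d$cl_iv <- 0; d$cl_renal <- 0
  kpu <- setNames(rep(1, 13), c("adipose", "bone", "brain", "gut", "heart",
                                "kidney", "liver", "lung", "muscle", "skin",
                                "spleen", "pancreas", "rest"))
  part <- structure(list(kpu = kpu, kp = kpu, ep = 1, fu_ref = 1,
                         blood_to_plasma = 1, hematocrit = 0.45,
                         vss_pred = NA, ka_ap = NA),
                    class = "partition_set")
  reg <- dose_regimen("iv_infusion", dose_mg = 600,
                      infusion_duration = 0.1, times = fast_times)
  p <- simulate_profile(ref_phys, d, part, reg)
  v_total <- sum(ref_phys$organ_volumes)
  tail_c <- p$conc_plasma[p$time > 24]
  expect_equal(mean(tail_c), 600 / v_total, tolerance = 5e-3)
  expect_lt(diff(range(tail_c)) / mean(tail_c), 1e-4)
})

test_that("moment-based Vss from i.v. output matches the predicted Vss", {
  p <- simulate_profile(ref_phys, ref_drug, ref_partition, iv600())
  m <- run_nca(p$time, p$conc_plasma, 600, "iv", infusion_duration = 0.5)
  expect_equal(m$vss / ref_phys$body_weight, ref_partition$vss_pred,
               tolerance = 0.05)
})

test_that("lower permeability delays the absorption peak", {
  d_slow <- rifampicin_parameters(peff_source = "reported")   # 2.15e-4
  p_fast <- simulate_profile(ref_phys, ref_drug, ref_partition, oral600())
  p_slow <- simulate_profile(ref_phys, d_slow, ref_partition, oral600())
  tmax <- function(p) p$time[which.max(p$conc_plasma)]
  expect_gt(tmax(p_slow), tmax(p_fast))
})

test_that("oral bioavailability equals fa times hepatic escape", {
  p_po <- simulate_profile(ref_phys, ref_drug, ref_partition, oral600())
  m_po <- run_nca(p_po$time, p_po$conc_plasma, 600, "oral")
  f_sim <- m_po$auc_0_inf * p_po$cl_total_plasma / 600
  expect_equal(f_sim, p_po$f_abs_gut * p_po$f_hepatic, tolerance = 0.01)
  expect_gt(p_po$f_hepatic, 0.9)   # low-extraction drug escapes first pass
})

test_that("population simulation summarizes and is deterministic", {
  pop <- sample_population(3, disease_modifiers("healthy"), seed = 4)
  reg <- dose_regimen("oral", dose_mg_per_kg = 10,
                      times = seq(0, 24, by = 0.5))
  s1 <- simulate_population(pop, ref_drug, ref_partition, reg)
  s2 <- simulate_population(pop, ref_drug, ref_partition, reg)
  expect_identical(s1$summary, s2$summary)
  expect_true(all(s1$summary$p05 <= s1$summary$p95 + 1e-12))
  # n = 1: the summary mean is the single profile
  pop1 <- sample_population(1, disease_modifiers("healthy"), seed = 4)
  s <- simulate_population(pop1, ref_drug, ref_partition, reg)
  expect_equal(s$summary$mean, s$profiles[[1]]$conc_plasma)
  expect_equal(s$summary$p05, s$summary$p95)
})
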