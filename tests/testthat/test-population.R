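test_that("reference physiology satisfies its structural invariants", {
  ref <- reference_physiology()
  expect_s3_class(ref, "physiology_spec")
  q <- ref$organ_blood_flows
  art <- sum(q[setdiff(names(q), c("liver", "lung", "blood"))]) +
    ref$hepatic_artery_flow
  expect_equal(art, ref$cardiac_output, tolerance = 1e-12)
  expect_equal(unname(q["liver"]),
               ref$hepatic_artery_flow + ref$portal_vein_flow)
  expect_lte(sum(ref$organ_volumes), ref$body_weight / 0.95)
  # hepatic blood flow near the standard ~90 L/h reference value
  expect_equal(unname(q["liver"]), 90, tolerance = 0.01)
})

test_that("zero-CV healthy sampling at reference weight returns the reference", {
  ind <- sample_individual(
    demographics = list(weight_range = c(70, 70), age_range = c(30, 30)),
    modifiers = disease_modifiers("healthy"), cv = zero_cv, rng_seed = 1)
  ref <- reference_physiology()
  expect_equal(ind$organ_volumes, ref$organ_volumes, tolerance = 1e-12)
  expect_equal(ind$organ_blood_flows, ref$organ_blood_flows, tolerance = 1e-12)
  expect_equal(ind$albumin_conc, ref$albumin_conc)
  expect_equal(ind$cardiac_output, ref$cardiac_output, tolerance = 1e-12)
})

test_that("tuberculosis modifiers set albumin to 38 g/L and lower weight", {
  tb <- disease_modifiers("tuberculosis")
  ind <- sample_individual(modifiers = tb, cv = zero_cv, rng_seed = 3)
  expect_equal(ind$albumin_conc, 38)
  expect_gte(ind$body_weight, 38)
  expect_lte(ind$body_weight, 55)
})

test_that("sampling is bitwise reproducible under a fixed seed", {
  m <- disease_modifiers("cirrhosis", "B")
  a <- sample_individual(modifiers = m, rng_seed = 42)
  b <- sample_individual(modifiers = m, rng_seed = 42)
  expect_identical(a, b)
  p1 <- sample_population(8, disease_modifiers("tuberculosis"), seed = 7)
  p2 <- sample_population(8, disease_modifiers("tuberculosis"), seed = 7)
  expect_identical(p1, p2)
})

test_that("all-ones healthy modifiers are the identity", {
  ref <- reference_physiology()
  out <- apply_modifiers(ref, disease_modifiers("healthy"))
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("liver volume scalar acts multiplicatively", {
  ref <- reference_physiology()
  m <- disease_modifiers("cirrhosis", "A")
  m$liver_volume_scalar <- 0.5
  out <- apply_modifiers(ref, m)
  expect_equal(unname(out$organ_volumes["liver"]),
               unname(ref$organ_volumes["liver"]) * 0.5)
})

test_that("flow conservation survives any valid modifier application", {
  ref <- reference_physiology()
  for (cp in c("A", "B", "C")) {
    out <- apply_modifiers(ref, disease_modifiers("cirrhosis", cp))
    q <- out$organ_blood_flows
    art <- sum(q[setdiff(names(q), c("liver", "lung", "blood"))]) +
      out$hepatic_artery_flow
    expect_equal(art, out$cardiac_output, tolerance = 1e-6)
    expect_equal(unname(q["liver"]),
                 out$hepatic_artery_flow + out$portal_vein_flow,
                 tolerance = 1e-9)
  }
  # randomized scalar sweep (kept below the level that would exhaust the
  # rest-of-body flow budget, which is a designed error)
  set.seed(11)
  for (i in 1:20) {
    m <- disease_modifiers("cirrhosis", "B")
    m$hepatic_flow_scalar <- runif(1, 0.4, 1.1)
    m$renal_flow_scalar <- runif(1, 0.4, 1.1)
    m$liver_volume_scalar <- runif(1, 0.4, 1.1)
    out <- apply_modifiers(ref, m)
    q <- out$organ_blood_flows
    art <- sum(q[setdiff(names(q), c("liver", "lung", "blood"))]) +
      out$hepatic_artery_flow
    expect_equal(art, out$cardiac_output, tolerance = 1e-6)
  }
})

test_that("default cirrhosis severity is monotone in albumin and liver volume", {
  alb <- vapply(c("A", "B", "C"), function(cp)
    disease_modifiers("cirrhosis", cp)$albumin_target, numeric(1))
  liv <- vapply(c("A", "B", "C"), function(cp)
    disease_modifiers("cirrhosis", cp)$liver_volume_scalar, numeric(1))
  expect_true(all(diff(alb) < 0))       # C < B < A
  expect_lt(alb[["A"]], 45)             # all below healthy reference
  expect_true(all(diff(liv) < 0))
  expect_lt(liv[["A"]], 1)
})

test_that("zero CV with degenerate demographics yields identical individuals", {
  pop <- sample_population(
    5, disease_modifiers("healthy"),
    demographics = list(weight_range = c(65, 65), age_range = c(40, 40),
                        female_proportion = 0),
    cv = zero_cv, seed = 2)
  for (i in 2:5)
    expect_equal(pop$individuals[[i]], pop$individuals[[1]],
                 tolerance = 1e-12)
})

test_that("population export flattens one row per individual", {
  pop <- sample_population(4, disease_modifiers("cirrhosis", "C"), seed = 9)
  df <- population_to_df(pop)
  expect_equal(nrow(df), 4)
  expect_true(all(c("albumin_conc", "vol_liver", "flow_kidney") %in%
                    names(df)))
  expect_true(all(df$vol_liver > 0))
})

test_that("invalid ranges and modifiers are rejected", {
  expect_error(sample_individual(
    demographics = list(age_range = c(5, 10))), "15-95")
  expect_error(sample_individual(
    demographics = list(weight_range = c(-3, 10))), "positive")
  expect_error(disease_modifiers("cirrhosis", "none"), "cp_class")
  expect_error(disease_modifiers("healthy", "A"), "cirrhosis only")
  m <- disease_modifiers("cirrhosis", "C")
  m$hepatic_flow_scalar <- 0
  expect_error(apply_modifiers(reference_physiology(), m), "\\(0, 2\\]")
})
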