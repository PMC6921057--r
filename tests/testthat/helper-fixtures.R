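# Shared fixtures built in code: reference objects, a coarse-but-accurate
# time grid for fast ODE runs, and degenerate composition tables.

zero_cv <- list(volumes = 0, flows = 0, albumin = 0)

fast_times <- seq(0, 48, by = 0.25)

ref_drug <- rifampicin_parameters()
ref_partition <- predict_kp(ref_drug)
ref_phys <- reference_physiology()

iv600 <- function(times = fast_times)
  dose_regimen("iv_infusion", dose_mg = 600, times = times)
oral600 <- function(times = fast_times)
  dose_regimen("oral", dose_mg = 600, times = times)

# composition with water only (no lipids, no acidic phospholipid, no
# albumin): for a neutral unbound compound every Kp collapses to the water
# fraction
water_only_composition <- function() {
  comp <- default_tissue_composition()
  comp$f_nl <- 0
  comp$f_np <- 0
  comp$ap_mg_g[comp$tissue != "blood_cells"] <- 0
  comp$alb_ratio <- 0
  comp
}

neutral_unbound_drug <- function() {
  d <- rifampicin_parameters()
  d$compound_type <- "neutral"
  d$fu_plasma <- 1
  d$blood_to_plasma <- 1
  d$logP_ow <- -12   # lipid partitioning numerically extinguished
  d
}
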