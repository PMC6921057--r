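# Whole-body perfusion-limited PBPK engine: retrograde well-stirred
# clearance, first-order oral absorption from jejunal permeability, and the
# ODE core (deSolve/lsoda).

# ODE tissue order (12 perfused non-lung compartments)
ENGINE_TISSUES <- c("adipose", "bone", "brain", "gut", "heart", "kidney",
                    "liver", "muscle", "skin", "spleen", "pancreas", "rest")

#' Retrograde intrinsic clearance (well-stirred liver)
#'
#' Solves the well-stirred model
#' `CL_H = Q_H * fu_B * CLu_int / (Q_H + fu_B * CLu_int)` backwards:
#' `CLu_int = CL_H * Q_H / (fu_B * (Q_H - CL_H))`.
#'
#' @param cl_h Systemic hepatic clearance, L/h; must satisfy `0 < cl_h < q_h`.
#' @param q_h Hepatic blood flow, L/h.
#' @param fu_b Unbound fraction in blood.
#' @return Unbound intrinsic hepatic clearance, L/h.
#' @export
#' @examples
#' retrograde_clint(7, 90, 0.5075)  # ~14.96
retrograde_clint <- function(cl_h, q_h, fu_b) {
  if (q_h <= 0 || fu_b <= 0) stop("q_h and fu_b must be positive")
  if (cl_h <= 0) stop("cl_h must be positive")
  if (cl_h >= q_h)
    stop("hepatic clearance at or above hepatic blood flow: ",
         "no finite intrinsic clearance exists (flow-limited)")
  cl_h * q_h / (fu_b * (q_h - cl_h))
}

#' Forward well-stirred hepatic clearance
#'
#' @param clu_int Unbound intrinsic clearance, L/h.
#' @param q_h Hepatic blood flow, L/h.
#' @param fu_b Unbound fraction in blood.
#' @return Hepatic (blood) clearance, L/h.
#' @export
wellstirred_cl <- function(clu_int, q_h, fu_b) {
  q_h * fu_b * clu_int / (q_h + fu_b * clu_int)
}

#' First-order absorption rate constant from jejunal permeability
#'
#' Thin-cylinder small-intestine approximation `ka = (2 * Peff / r) * 3600`,
#' the deliberate first-order simplification of a multi-segment mechanistic
#' absorption model.
#'
#' @param peff Effective human jejunal permeability, cm/s.
#' @param radius_cm Small-intestinal radius, cm (default 1.75).
#' @return Absorption rate constant, 1/h.
#' @export
#' @examples
#' ka_from_peff(2.4e-4)  # ~0.987 per hour
ka_from_peff <- function(peff, radius_cm = 1.75) {
  if (peff <= 0 || radius_cm <= 0) stop("peff and radius must be positive")
  2 * peff / radius_cm * 3600
}

#' Dose regimen
#'
#' @param route `"iv_infusion"` or `"oral"`.
#' @param dose_mg Absolute dose in mg (exclusive with `dose_mg_per_kg`).
#' @param dose_mg_per_kg Weight-based dose, resolved against each
#'   individual's body weight at simulation time.
#' @param infusion_duration Infusion length in h (i.v. only; default 0.5).
#' @param fasted Fasting state flag (bookkeeping; all packaged study designs
#'   are fasted).
#' @param times Output time grid in h.
#' @return A `dose_regimen` object.
#' @export
dose_regimen <- function(route = c("iv_infusion", "oral"), dose_mg = NULL,
                         dose_mg_per_kg = NULL, infusion_duration = 0.5,
                         fasted = TRUE, times = seq(0, 48, by = 0.1)) {
  route <- match.arg(route)
  if (is.null(dose_mg) == is.null(dose_mg_per_kg))
    stop("give exactly one of dose_mg or dose_mg_per_kg")
  if (!is.null(dose_mg) && dose_mg <= 0) stop("dose must be positive")
  if (!is.null(dose_mg_per_kg) && dose_mg_per_kg <= 0)
    stop("dose must be positive")
  if (route == "iv_infusion" && infusion_duration <= 0)
    stop("infusion_duration must be positive for i.v. dosing")
  if (any(diff(times) <= 0) || times[1] < 0)
    stop("times must be a non-negative increasing grid")
  structure(list(route = route, dose_mg = dose_mg,
                 dose_mg_per_kg = dose_mg_per_kg,
                 infusion_duration = infusion_duration, fasted = fasted,
                 times = times), class = "dose_regimen")
}

resolve_dose <- function(regimen, body_weight) {
  if (!is.null(regimen$dose_mg)) regimen$dose_mg
  else regimen$dose_mg_per_kg * body_weight
}

#' Drug-level clearance model
#'
#' Derives the unbound intrinsic hepatic clearance once, retrograde from the
#' assigned i.v. (hepatic) clearance against the reference hepatic blood flow
#' and the reference unbound blood fraction; carries renal clearance along.
#' The implied hepatic extraction ratio is checked against the low-clearance
#' regime (E < 0.3) expected for this drug.
#'
#' @param drug A `drug_parameters` record.
#' @param reference Reference physiology anchoring `Q_H`.
#' @return A `clearance_model` list: `clu_int`, `cl_renal`, `q_h_ref`,
#'   `fu_b_ref`, `hepatic_extraction`.
#' @export
drug_clearance_model <- function(drug, reference = reference_physiology()) {
  validate_drug(drug)
  q_h <- reference$hepatic_artery_flow + reference$portal_vein_flow
  fu_b <- fu_blood(drug$fu_plasma, drug$blood_to_plasma)
  clu_int <- if (drug$cl_iv == 0) 0 else retrograde_clint(drug$cl_iv, q_h, fu_b)
  e <- if (drug$cl_iv == 0) 0 else drug$cl_iv / q_h
  if (e >= 1) stop("hepatic extraction out of range")
  if (e >= 0.3)
    warning("hepatic extraction ", round(e, 2),
            " is outside the low-clearance regime assumed for this drug")
  structure(list(clu_int = clu_int, cl_renal = drug$cl_renal, q_h_ref = q_h,
                 fu_b_ref = fu_b, hepatic_extraction = e),
            class = "clearance_model")
}

#' Simulate one individual
#'
#' Perfusion-limited whole-body ODE model: non-eliminating tissues follow
#' `dA/dt = Q * (C_art - A / (V * Kp / B:P))`; the liver receives hepatic
#' artery plus portal (gut, spleen, pancreas) inflow and any absorbed oral
#' drug, and eliminates at `fu_B * cyp_scalar * CLu_int * C_liver,out`; the
#' kidney clears `CL_R` of arterial plasma; the lung sits in series with the
#' venous return.  Oral doses enter a gut-lumen depot (fraction absorbable
#' `fa`) and transfer first-order (`ka` from permeability) into the portal
#' inflow; i.v. doses infuse into venous blood at `dose / duration`.  The
#' individual's unbound fraction is derived from their albumin via
#' [adjust_fu()] and the partition coefficients are rescaled accordingly.
#'
#' @param individual A `physiology_spec`.
#' @param drug A `drug_parameters` record.
#' @param partition A `partition_set` from [predict_kp()].
#' @param regimen A `dose_regimen`.
#' @param modifiers Optional `disease_modifiers` (supplies the CYP abundance
#'   and renal scalars; physiological changes are assumed already applied to
#'   `individual`).
#' @param clearance Optional precomputed [drug_clearance_model()].
#' @param fa Fraction of an oral dose available for absorption (default 0.95).
#' @param scale_renal_cl Scale renal clearance with the disease renal-flow
#'   scalar (default TRUE).
#' @param rtol,atol Solver tolerances (lsoda, stiff-capable).
#' @return A `concentration_profile`: `time` (h), `conc_plasma` (mg/L venous
#'   plasma), `amounts` (matrix, mg per compartment over time),
#'   `eliminated_hepatic`/`eliminated_renal` (cumulative mg), `dose_mg`,
#'   `f_abs_gut`, `f_hepatic`, `cl_hepatic_blood`, `cl_total_plasma` and the
#'   administered-to-date amounts for mass balance.
#' @export
simulate_profile <- function(individual, drug, partition, regimen,
                             modifiers = disease_modifiers("healthy"),
                             clearance = drug_clearance_model(drug),
                             fa = 0.95, scale_renal_cl = TRUE,
                             rtol = 1e-8, atol = 1e-10) {
  validate_physiology(individual)
  validate_drug(drug)
  stopifnot(inherits(partition, "partition_set"),
            inherits(regimen, "dose_regimen"))

  bw <- individual$body_weight
  dose <- resolve_dose(regimen, bw)
  bp <- drug$blood_to_plasma
  fu_i <- adjust_fu(drug$fu_plasma, REF_ALBUMIN, individual$albumin_conc)
  fu_b <- fu_blood(fu_i, bp)
  kp <- partition$kpu * fu_i
  kpb <- kp[ENGINE_TISSUES] / bp
  kpb_lung <- kp["lung"] / bp

  v <- individual$organ_volumes
  q <- individual$organ_blood_flows
  vt <- v[ENGINE_TISSUES]
  qt <- q[ENGINE_TISSUES]
  co <- individual$cardiac_output
  q_ha <- individual$hepatic_artery_flow
  q_h <- q_ha + individual$portal_vein_flow
  v_lung <- unname(v["lung"])
  v_art <- unname(v["blood"]) / 3
  v_ven <- unname(v["blood"]) * 2 / 3

  # drug-record clearances are population-typical inputs: hepatic clearance
  # varies across individuals through Q_H and fu_B, renal clearance only
  # through the disease renal-flow scalar
  clint_eff <- clearance$clu_int * modifiers$cyp_abundance_scalar
  cl_r <- drug$cl_renal
  if (scale_renal_cl) cl_r <- cl_r * modifiers$renal_flow_scalar

  i_li <- match("liver", ENGINE_TISSUES)
  i_portal <- match(PORTAL_TISSUES, ENGINE_TISSUES)
  i_ki <- match("kidney", ENGINE_TISSUES)
  oral <- regimen$route == "oral"
  ka <- if (oral) ka_from_peff(drug$peff_man) else 0
  inf_dur <- regimen$infusion_duration
  n_t <- length(ENGINE_TISSUES)
  vkpb <- vt * kpb

  deriv <- function(t, y, p, inf_rate) {
    lumen <- y[1]
    a_t <- y[2:(n_t + 1)]
    a_lung <- y[n_t + 2]; a_art <- y[n_t + 3]; a_ven <- y[n_t + 4]
    c_art <- a_art / v_art
    c_ven <- a_ven / v_ven
    c_out <- a_t / vkpb
    c_lu_out <- a_lung / (v_lung * kpb_lung)

    d_t <- qt * (c_art - c_out)
    # liver: arterial + portal inflow + absorbed drug, minus outflow + metabolism
    elim_h <- clint_eff * fu_b * c_out[i_li]
    d_t[i_li] <- q_ha * c_art + sum(qt[i_portal] * c_out[i_portal]) +
      ka * lumen - q_h * c_out[i_li] - elim_h
    elim_r <- cl_r * c_art / bp
    d_t[i_ki] <- d_t[i_ki] - elim_r
    d_lung <- co * (c_ven - c_lu_out)
    d_art <- co * c_lu_out - co * c_art
    d_ven <- sum((qt * c_out)[-c(i_li, i_portal)]) + q_h * c_out[i_li] +
      inf_rate - co * c_ven
    list(c(-ka * lumen, d_t, d_lung, d_art, d_ven, elim_h, elim_r))
  }

  y0 <- numeric(n_t + 6)
  names(y0) <- c("lumen", ENGINE_TISSUES, "lung", "art", "ven",
                 "elim_hepatic", "elim_renal")
  times <- regimen$times
  solve_seg <- function(y, tt, rate) {
    o <- deSolve::lsoda(y, tt, deriv, parms = NULL, inf_rate = rate,
                        rtol = rtol, atol = atol)
    if (attr(o, "istate")[1] < 0)
      stop("ODE solver failed; final state: ",
           paste(signif(o[nrow(o), -1], 4), collapse = ", "))
    o
  }
  if (oral) {
    y0["lumen"] <- fa * dose
    out <- solve_seg(y0, times, 0)
  } else {
    rate <- dose / inf_dur
    t1 <- sort(unique(c(times[times <= inf_dur], inf_dur)))
    if (t1[1] > 0) t1 <- c(0, t1)
    o1 <- solve_seg(y0, t1, rate)
    y1 <- o1[nrow(o1), -1]
    t2 <- sort(unique(c(inf_dur, times[times > inf_dur])))
    o2 <- solve_seg(y1, t2, 0)
    keep1 <- o1[, 1] %in% times & o1[, 1] < inf_dur
    keep2 <- o2[, 1] %in% times
    out <- rbind(o1[keep1, , drop = FALSE], o2[keep2, , drop = FALSE])
  }

  tt <- out[, 1]
  amounts <- out[, -1, drop = FALSE]
  conc_plasma <- amounts[, "ven"] / v_ven / bp
  if (any(conc_plasma < -1e-9))
    stop("negative plasma concentrations beyond tolerance: internal ",
         "inconsistency")
  conc_plasma[conc_plasma < 0] <- 0

  cl_hb <- wellstirred_cl(clint_eff, q_h, fu_b)
  administered <- if (oral) rep(dose, length(tt))
                  else dose * pmin(tt / inf_dur, 1)
  unabsorbable <- if (oral) (1 - fa) * dose else 0
  structure(list(
    time = tt, conc_plasma = unname(conc_plasma), amounts = amounts,
    eliminated_hepatic = unname(amounts[, "elim_hepatic"]),
    eliminated_renal = unname(amounts[, "elim_renal"]),
    dose_mg = dose, route = regimen$route,
    infusion_duration = if (oral) NA_real_ else inf_dur,
    f_abs_gut = if (oral) fa else 1,
    f_hepatic = 1 - cl_hb / q_h,
    fu_plasma = fu_i, fu_blood = fu_b,
    cl_hepatic_blood = cl_hb,
    cl_total_plasma = cl_hb * bp + cl_r,
    administered = administered, unabsorbable = unabsorbable
  ), class = "concentration_profile")
}

#' Mass-balance error of a simulated profile
#'
#' Relative deviation of (compartment amounts + cumulative elimination +
#' unabsorbable oral remainder) from the administered-to-date dose, at every
#' output time.
#'
#' @param profile A `concentration_profile`.
#' @return Numeric vector of relative errors over time.
#' @export
mass_balance_error <- function(profile) {
  total <- rowSums(profile$amounts) + profile$unabsorbable
  adm <- profile$administered
  err <- (total - adm) / profile$dose_mg
  err[adm > 0]
}

#' Simulate a virtual population
#'
#' Runs [simulate_profile()] for every individual (resolving mg/kg doses
#' against individual weights) and summarizes the plasma concentration
#' curves pointwise as mean, 5th/95th percentiles, minimum and maximum.
#' Deterministic given the population sample.
#'
#' @param pop A `population_sample`.
#' @param drug,partition,regimen,... Passed to [simulate_profile()]; the
#'   population's own modifiers are used.
#' @return A `population_simulation`: `profiles` (list), `summary`
#'   (data.frame time/mean/p05/p95/min/max) and the inputs.
#' @export
simulate_population <- function(pop, drug, partition, regimen, ...) {
  stopifnot(inherits(pop, "population_sample"), pop$n >= 1)
  clearance <- drug_clearance_model(drug)
  profiles <- vector("list", pop$n)
  for (i in seq_len(pop$n)) {
    profiles[[i]] <- tryCatch(
      simulate_profile(pop$individuals[[i]], drug, partition, regimen,
                       modifiers = pop$modifiers, clearance = clearance, ...),
      error = function(e) stop("individual ", i, ": ", conditionMessage(e)))
  }
  cmat <- vapply(profiles, function(p) p$conc_plasma,
                 numeric(length(regimen$times)))
  if (is.null(dim(cmat))) cmat <- matrix(cmat, nrow = length(regimen$times))
  summary <- data.frame(
    time = regimen$times,
    mean = rowMeans(cmat),
    p05 = apply(cmat, 1, quantile, probs = 0.05, names = FALSE),
    p95 = apply(cmat, 1, quantile, probs = 0.95, names = FALSE),
    min = apply(cmat, 1, min),
    max = apply(cmat, 1, max))
  structure(list(profiles = profiles, summary = summary, regimen = regimen,
                 modifiers = pop$modifiers, n = pop$n, seed = pop$seed),
            class = "population_simulation")
}
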