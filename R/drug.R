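# Drug parameter record, Rodgers-Rowland tissue:plasma partitioning and
# plasma-protein-binding adjustments.

PLASMA_PH <- 7.4
# plasma lipid fractions used by the albumin/neutral binding route
PLASMA_F_NL <- 0.0023
PLASMA_F_NP <- 0.0013

#' Rifampicin model input parameters
#'
#' The final rifampicin input record: physicochemistry (MW 822.9 g/mol,
#' logP 2.7, ampholyte with pKa 1.7 and 7.9), absorption (effective jejunal
#' permeability, with both the literature value 2.15e-4 cm/s and the
#' optimized 2.4e-4 cm/s retained), distribution (B/P 0.67; fu 0.34
#' optimized, 0.15 reported) and elimination (CL_iv 7 L/h assigned as hepatic
#' clearance; CL_R 1.5 L/h).
#'
#' @param fu_source `"optimized"` (0.34, the simulation default) or
#'   `"reported"` (0.15).
#' @param peff_source `"optimized"` (2.4e-4 cm/s) or `"reported"`
#'   (2.15e-4 cm/s).
#' @return An object of class `drug_parameters`.
#' @export
#' @examples
#' rifampicin_parameters()$fu_plasma  # 0.34
rifampicin_parameters <- function(fu_source = c("optimized", "reported"),
                                  peff_source = c("optimized", "reported")) {
  fu_source <- match.arg(fu_source)
  peff_source <- match.arg(peff_source)
  drug <- structure(list(
    name = "rifampicin",
    molecular_weight = 822.9,
    logP_ow = 2.7,
    pKa_acidic = 1.7,
    pKa_basic = 7.9,
    compound_type = "ampholyte",
    peff_man = if (peff_source == "optimized") 2.4e-4 else 2.15e-4,
    peff_source = peff_source,
    blood_to_plasma = 0.67,
    fu_plasma = if (fu_source == "optimized") 0.34 else 0.15,
    fu_source = fu_source,
    cl_iv = 7,       # L/h, assigned as hepatic clearance
    cl_renal = 1.5,  # L/h
    vss_reported_range = c(0.33, 0.53),  # L/kg, documentation only
    vss_mode = "predicted"
  ), class = "drug_parameters")
  validate_drug(drug)
}

validate_drug <- function(drug) {
  stopifnot(inherits(drug, "drug_parameters"))
  if (drug$fu_plasma <= 0 || drug$fu_plasma > 1)
    stop("fu_plasma must lie in (0, 1]")
  if (drug$blood_to_plasma <= 0) stop("blood_to_plasma must be positive")
  if (drug$cl_iv < 0 || drug$cl_renal < 0)
    stop("clearances must be non-negative")
  if (identical(drug$compound_type, "ampholyte") &&
      !(drug$pKa_acidic < drug$pKa_basic))
    stop("an ampholyte requires pKa_acidic < pKa_basic")
  invisible(drug)
}

#' Tissue composition table
#'
#' Reads the packaged tissue composition table (water, neutral lipid and
#' phospholipid fractions, acidic phospholipid content, tissue-to-plasma
#' albumin ratio and intracellular pH per tissue, plus a `blood_cells` row
#' for erythrocytes) used by [predict_kp()].
#'
#' @param file Optional path to an alternative CSV with the same columns.
#' @return A `data.frame` with one row per tissue.
#' @export
default_tissue_composition <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "tissue_composition.csv",
                        package = "rifpbpk")
  comp <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("tissue", "f_ew", "f_iw", "f_nl", "f_np", "ap_mg_g",
              "alb_ratio", "ph_iw")
  if (!all(needed %in% names(comp))) stop("composition table missing columns")
  if (any(comp$f_ew < 0 | comp$f_ew > 1 | comp$f_iw < 0 | comp$f_iw > 1))
    stop("water fractions must lie in [0, 1]")
  # published composition rows can overshoot unity by <1% (rounding of
  # independently measured fractions); reject only real inconsistencies
  if (any(comp$f_ew + comp$f_iw + comp$f_nl + comp$f_np > 1.01))
    stop("water + lipid fractions exceed unity")
  comp
}

# Macroscopic ampholyte species ladder relative to the predominant middle
# (zwitterionic) species: cation below pKa_acidic, anion above pKa_basic.
ampholyte_x <- function(pH, pKa_a, pKa_b)
  1 + 10^(pKa_a - pH) + 10^(pH - pKa_b)
ampholyte_base_prot <- function(pH, pKa_a, pKa_b)
  1 + 10^(pKa_a - pH)   # species carrying a protonated basic centre

#' Predict tissue:plasma partition coefficients and Vss (Rodgers-Rowland)
#'
#' Rodgers-Rowland ("method 2") partitioning.  For the ampholyte route the
#' reference species is the zwitterion of the macroscopic ladder
#' cation = zwitterion = anion (Henderson-Hasselbalch at plasma pH 7.4, red
#' cell pH and per-tissue intracellular pH); drug distributes into tissue
#' water, the neutral microspecies partitions into neutral lipid and neutral
#' phospholipid, and the protonated-base species binds acidic phospholipids
#' with an association constant back-calculated from red-cell partitioning
#' (blood:plasma ratio and hematocrit).  For neutral/acidic compounds the
#' acidic-phospholipid term is replaced by albumin-type binding scaled by
#' `(1 - fu)/fu` and the tissue-to-plasma albumin ratio.  Vss sums plasma,
#' red-cell (via the erythrocyte:plasma ratio) and tissue contributions per
#' kg body weight.
#'
#' @param drug A `drug_parameters` record.
#' @param composition Composition table from [default_tissue_composition()].
#' @param hematocrit Red-cell volume fraction of blood.
#' @param physiology Optional `physiology_spec` supplying organ volumes and
#'   body weight for the Vss sum (defaults to [reference_physiology()]).
#' @return An object of class `partition_set`: `kp` (named tissue:plasma
#'   coefficients at the record's fu), `kpu` (unbound-referenced, so the
#'   engine can rescale to disease fu), `ep` (erythrocyte:plasma ratio),
#'   `vss_pred` (L/kg) and `ka_ap` (the fitted acidic-phospholipid constant,
#'   ampholyte/base route only).
#' @export
#' @examples
#' ps <- predict_kp(rifampicin_parameters(), default_tissue_composition())
#' round(ps$vss_pred, 2)
predict_kp <- function(drug, composition = default_tissue_composition(),
                       hematocrit = 0.45,
                       physiology = reference_physiology()) {
  validate_drug(drug)
  if (drug$fu_plasma <= 0)
    stop("fu_plasma of zero is not a valid partitioning input")
  bc <- composition[composition$tissue == "blood_cells", ]
  tis <- composition[composition$tissue != "blood_cells", ]
  missing <- setdiff(setdiff(TISSUES, "blood"), tis$tissue)
  if (length(missing))
    stop("composition table lacks tissue(s): ", paste(missing, collapse = ", "))
  tis <- tis[match(setdiff(TISSUES, "blood"), tis$tissue), ]

  P <- 10^drug$logP_ow
  fu <- drug$fu_plasma
  bp <- drug$blood_to_plasma
  ep <- (bp - (1 - hematocrit)) / hematocrit   # erythrocyte:plasma ratio
  nlnp <- function(f_nl, f_np, scale) (P * f_nl + (0.3 * P + 0.7) * f_np) * scale

  type <- drug$compound_type
  ka_ap <- NA_real_
  if (type %in% c("ampholyte", "base")) {
    if (type == "ampholyte") {
      pka_a <- drug$pKa_acidic; pka_b <- drug$pKa_basic
    } else {                      # monoprotic base: no anionic branch
      pka_a <- -Inf; pka_b <- drug$pKa_basic
    }
    X <- function(pH) ampholyte_x(pH, pka_a, pka_b)
    Bp <- function(pH) ampholyte_base_prot(pH, pka_a, pka_b)
    Y <- X(PLASMA_PH)
    # neutral microspecies relative to the reference species
    f_neu <- if (type == "ampholyte") 10^(pka_a - pka_b) else 1
    kpu_bc <- ep / fu
    resid <- kpu_bc - (X(bc$ph_iw) / Y) * bc$f_iw -
      nlnp(bc$f_nl, bc$f_np, f_neu / Y)
    if (resid <= 0)
      stop("red-cell partitioning leaves no room for acidic-phospholipid ",
           "binding; check B/P, hematocrit and fu")
    ka_ap <- resid * Y / (Bp(bc$ph_iw) * bc$ap_mg_g)
    kpu <- tis$f_ew + (X(tis$ph_iw) / Y) * tis$f_iw +
      ka_ap * tis$ap_mg_g * Bp(tis$ph_iw) / Y +
      nlnp(tis$f_nl, tis$f_np, f_neu / Y)
  } else {
    # neutral or acidic: ionized fraction does not enter lipid; binding is
    # albumin-type, linear in (1 - fu)/fu via the tissue albumin ratio
    ion <- if (type == "acid") 10^(PLASMA_PH - drug$pKa_acidic) else 0
    Y <- 1 + ion
    ka_alb <- (1 / fu) - 1 - nlnp(PLASMA_F_NL, PLASMA_F_NP, 1 / Y)
    ka_alb <- max(ka_alb, 0)
    kpu <- tis$f_ew + tis$f_iw +
      nlnp(tis$f_nl, tis$f_np, 1 / Y) + ka_alb * tis$alb_ratio
  }
  kp <- setNames(kpu * fu, tis$tissue)
  if (any(kp <= 0)) stop("non-positive partition coefficient computed")

  v <- physiology$organ_volumes
  v_blood <- unname(v["blood"])
  v_pl <- v_blood * (1 - hematocrit)
  v_rbc <- v_blood * hematocrit
  vt <- v[setdiff(TISSUES, "blood")]
  vss <- (v_pl + v_rbc * ep + sum(vt * kp[names(vt)])) / physiology$body_weight
  structure(list(kp = kp, kpu = setNames(kpu, tis$tissue), ep = ep,
                 fu_ref = fu, blood_to_plasma = bp, hematocrit = hematocrit,
                 vss_pred = vss, ka_ap = ka_ap),
            class = "partition_set")
}

#' Adjust the unbound plasma fraction for a changed albumin concentration
#'
#' One-binding-protein model: binding capacity scales proportionally with the
#' albumin concentration, so
#' `fu_d = 1 / (1 + (albumin_disease / albumin_ref) * (1 - fu_ref) / fu_ref)`.
#' Hypoalbuminemia (albumin below reference) therefore raises the unbound
#' fraction towards 1.
#'
#' @param fu_ref Reference unbound fraction in (0, 1].
#' @param albumin_ref,albumin_disease Albumin concentrations, g/L.
#' @return The disease unbound fraction.
#' @export
#' @examples
#' adjust_fu(0.34, 45, 38)  # tuberculosis: ~0.379
adjust_fu <- function(fu_ref, albumin_ref, albumin_disease) {
  if (fu_ref <= 0 || fu_ref > 1) stop("fu_ref must lie in (0, 1]")
  if (albumin_ref <= 0) stop("albumin_ref must be positive")
  if (albumin_disease < 0) stop("albumin_disease must be non-negative")
  1 / (1 + (albumin_disease / albumin_ref) * (1 - fu_ref) / fu_ref)
}

#' Unbound fraction in whole blood
#'
#' Standard conversion `fu_B = fu / (B:P)`, capped at 1 (with a warning) when
#' weak red-cell partitioning would push it above unity.
#'
#' @param fu_plasma Unbound plasma fraction.
#' @param blood_to_plasma Blood-to-plasma concentration ratio.
#' @return Unbound fraction referenced to whole blood.
#' @export
#' @examples
#' fu_blood(0.34, 0.67)  # 0.5075
fu_blood <- function(fu_plasma, blood_to_plasma) {
  if (fu_plasma <= 0) stop("fu_plasma must be positive")
  if (blood_to_plasma <= 0) stop("blood_to_plasma must be positive")
  fub <- fu_plasma / blood_to_plasma
  if (fub > 1) {
    warning("fu/B:P exceeds 1; capping unbound blood fraction at 1")
    fub <- 1
  }
  fub
}
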