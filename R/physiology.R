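# Fixed 14-tissue set used throughout the model. "rest" is the lumped
# rest-of-body compartment; "blood" covers plasma + red cells.
TISSUES <- c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
             "lung", "muscle", "skin", "spleen", "pancreas", "rest", "blood")

# Tissues drained by the portal vein (their venous outflow perfuses the liver).
PORTAL_TISSUES <- c("gut", "spleen", "pancreas")

# Tissues whose arterial outflow is summed against cardiac output.  The liver
# receives arterial blood only through the hepatic artery; lung is in series
# with the venous return; blood is not a perfused organ.
ARTERIAL_TISSUES <- setdiff(TISSUES, c("liver", "lung", "blood"))

REF_BODY_WEIGHT <- 70   # kg, reference adult male

#' Reference adult physiology
#'
#' Builds the reference 70 kg adult male physiology used as the anchor for all
#' virtual individuals: organ volumes and blood flows in the ICRP-style
#' reference-human tradition, cardiac output 390 L/h, hepatic blood flow
#' (hepatic artery + portal vein) 89.7 L/h, hematocrit 0.45 and plasma albumin
#' 45 g/L.  Volumes scale with body weight (exponent 1), flows with
#' weight^0.75.
#'
#' @param body_weight Body weight in kg.
#' @param sex `"male"` or `"female"` (demographic bookkeeping only; the organ
#'   tables are not sex-specific).
#' @param age Age in years.
#' @return An object of class `physiology_spec`: a list with fields `sex`,
#'   `age`, `body_weight` (kg), `hematocrit`, `albumin_conc` (g/L),
#'   `organ_volumes` (named L, 14 tissues), `organ_blood_flows` (named L/h),
#'   `cardiac_output`, `hepatic_artery_flow`, `portal_vein_flow` and
#'   `renal_plasma_flow` (all L/h).
#' @export
#' @examples
#' ref <- reference_physiology()
#' ref$hepatic_artery_flow + ref$portal_vein_flow  # total hepatic blood flow
reference_physiology <- function(body_weight = REF_BODY_WEIGHT,
                                 sex = "male", age = 30) {
  stopifnot(body_weight > 0)
  # volumes (L) at 70 kg
  vols <- c(adipose = 14.3, bone = 10.5, brain = 1.45, gut = 1.65,
            heart = 0.33, kidney = 0.31, liver = 1.80, lung = 0.50,
            muscle = 29.0, skin = 3.40, spleen = 0.15, pancreas = 0.10,
            rest = 2.00, blood = 5.60)
  # arterial blood flows (L/h) at 70 kg; cardiac output 390 L/h (6.5 L/min)
  flows <- c(adipose = 19.50, bone = 15.60, brain = 46.80, gut = 54.60,
             heart = 15.60, kidney = 68.25, muscle = 66.30, skin = 19.50,
             spleen = 8.58, pancreas = 3.12, rest = 48.75)
  ha <- 23.40  # hepatic artery
  sv <- (body_weight / REF_BODY_WEIGHT)        # volume scalar
  sq <- sv^0.75                                # flow scalar
  vols <- vols * sv
  flows <- flows * sq
  ha <- ha * sq
  co <- sum(flows) + ha
  pv <- sum(flows[PORTAL_TISSUES])
  hct <- 0.45
  obf <- c(flows, liver = ha + pv, lung = co, blood = co)[TISSUES]
  spec <- structure(list(
    sex = sex, age = age, body_weight = body_weight,
    hematocrit = hct, albumin_conc = 45,
    organ_volumes = vols[TISSUES],
    organ_blood_flows = obf,
    cardiac_output = co,
    hepatic_artery_flow = ha,
    portal_vein_flow = pv,
    renal_plasma_flow = unname(flows["kidney"]) * (1 - hct)
  ), class = "physiology_spec")
  validate_physiology(spec)
}

#' Validate a physiology specification
#'
#' Checks the structural invariants of a [reference_physiology()] object:
#' strictly positive volumes and flows, albumin within (15, 60) g/L,
#' conservation of arterial outflow against cardiac output (1e-6 relative),
#' consistency of the hepatic flows, and the whole-body density bound
#' (total organ volume no larger than body weight / 0.95).
#'
#' @param spec A `physiology_spec`.
#' @return `spec`, invisibly unchanged, or an error.
#' @export
validate_physiology <- function(spec) {
  stopifnot(inherits(spec, "physiology_spec"))
  v <- spec$organ_volumes; q <- spec$organ_blood_flows
  if (!identical(names(v), TISSUES) || !identical(names(q), TISSUES))
    stop("organ maps must cover the fixed 14-tissue set, in order")
  if (any(v <= 0) || any(q <= 0))
    stop("all organ volumes and blood flows must be strictly positive")
  if (spec$albumin_conc <= 15 || spec$albumin_conc >= 60)
    stop("albumin_conc outside the plausible (15, 60) g/L window")
  if (spec$hematocrit <= 0 || spec$hematocrit >= 1)
    stop("hematocrit must be a fraction in (0, 1)")
  art <- sum(q[ARTERIAL_TISSUES]) + spec$hepatic_artery_flow
  if (abs(art - spec$cardiac_output) > 1e-6 * spec$cardiac_output)
    stop("arterial outflows do not sum to cardiac output")
  if (abs(spec$hepatic_artery_flow + spec$portal_vein_flow - q["liver"]) >
      1e-6 * q["liver"])
    stop("hepatic artery + portal vein must equal total liver flow")
  if (abs(sum(q[PORTAL_TISSUES]) - spec$portal_vein_flow) >
      1e-6 * spec$portal_vein_flow)
    stop("portal vein flow must equal the summed splanchnic outflows")
  if (sum(v) > spec$body_weight / 0.95)
    stop("total organ volume violates the whole-body density bound")
  invisible(spec)
}

#' @export
print.physiology_spec <- function(x, ...) {
  cat(sprintf("<physiology_spec> %s, %g y, %.1f kg\n", x$sex, x$age,
              x$body_weight))
  cat(sprintf("  albumin %.1f g/L | hct %.2f | CO %.1f L/h | Q_H %.1f L/h\n",
              x$albumin_conc, x$hematocrit, x$cardiac_output,
              x$hepatic_artery_flow + x$portal_vein_flow))
  invisible(x)
}
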