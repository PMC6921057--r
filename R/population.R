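# Virtual population generation: disease modifiers + seeded sampling around
# the reference physiology.

REF_ALBUMIN <- 45   # g/L, healthy reference plasma albumin

# Default coefficients of variation for inter-individual variability.
DEFAULT_CV <- list(volumes = 0.20, flows = 0.20, albumin = 0.10)

#' Disease modifier sets
#'
#' Returns the pathophysiological modifier set for a population: plasma
#' albumin target, liver-volume, hepatic/renal blood-flow and hepatic enzyme
#' (CYP) abundance scalars, and the default body-weight range.  Healthy is the
#' identity.  Tuberculosis reduces plasma albumin to 38 g/L and uses the lower
#' body-weight range typical of the clinical studies.  Cirrhosis modifiers are
#' stratified by Child-Pugh class and read from the packaged, editable YAML
#' config (`inst/extdata/cirrhosis_modifiers.yaml`), whose shipped defaults
#' are literature-informed stand-ins for the (unpublished) simulator-internal
#' values.
#'
#' @param disease `"healthy"`, `"tuberculosis"` or `"cirrhosis"`.
#' @param cp_class Child-Pugh class `"A"`, `"B"` or `"C"`; required for
#'   cirrhosis, must be `"none"` otherwise.
#' @param config_file Optional path to a YAML file overriding the packaged
#'   cirrhosis modifier table.
#' @return An object of class `disease_modifiers`.
#' @export
#' @examples
#' disease_modifiers("tuberculosis")$albumin_target  # 38 g/L
disease_modifiers <- function(disease = c("healthy", "tuberculosis",
                                          "cirrhosis"),
                              cp_class = "none", config_file = NULL) {
  disease <- match.arg(disease)
  if (disease == "cirrhosis") {
    if (!cp_class %in% c("A", "B", "C"))
      stop("cirrhosis requires cp_class A, B or C")
  } else if (!identical(cp_class, "none")) {
    stop("cp_class applies to cirrhosis only")
  }
  m <- list(disease = disease, cp_class = cp_class,
            albumin_target = "unchanged",
            liver_volume_scalar = 1, cyp_abundance_scalar = 1,
            hepatic_flow_scalar = 1, renal_flow_scalar = 1,
            body_weight_range = c(60, 85))
  if (disease == "tuberculosis") {
    m$albumin_target <- 38          # g/L, hypoalbuminemia
    m$body_weight_range <- c(38, 55)
  } else if (disease == "cirrhosis") {
    path <- if (is.null(config_file))
      system.file("extdata", "cirrhosis_modifiers.yaml", package = "rifpbpk")
    else config_file
    cfg <- yaml::read_yaml(path)[[cp_class]]
    m$albumin_target <- cfg$albumin_g_per_L
    m$liver_volume_scalar <- cfg$liver_volume_scalar
    m$cyp_abundance_scalar <- cfg$cyp_abundance_scalar
    m$hepatic_flow_scalar <- cfg$hepatic_flow_scalar
    m$renal_flow_scalar <- cfg$renal_flow_scalar
  }
  structure(m, class = "disease_modifiers")
}

validate_modifiers <- function(m) {
  stopifnot(inherits(m, "disease_modifiers"))
  sc <- c(m$liver_volume_scalar, m$cyp_abundance_scalar,
          m$hepatic_flow_scalar, m$renal_flow_scalar)
  if (any(sc <= 0) || any(sc > 2))
    stop("disease scalars must lie in (0, 2]")
  if (m$disease == "healthy" &&
      (any(sc != 1) || !identical(m$albumin_target, "unchanged")))
    stop("healthy modifiers must be the identity")
  if (m$disease == "tuberculosis" && !identical(m$cp_class, "none"))
    stop("tuberculosis carries no Child-Pugh class")
  if (m$disease == "cirrhosis" && !m$cp_class %in% c("A", "B", "C"))
    stop("cirrhosis requires cp_class A, B or C")
  invisible(m)
}

#' Apply disease modifiers to a physiology
#'
#' Multiplies the liver volume, hepatic flows (hepatic artery and splanchnic
#' inflows) and renal flow by the modifier scalars, sets plasma albumin to the
#' target, and re-balances the flow budget by absorbing the residual into the
#' rest-of-body flow so that the sum of arterial outflows still equals cardiac
#' output.  The CYP abundance scalar is physiology-free and passes through to
#' the simulation engine untouched.
#'
#' @param base A valid `physiology_spec`.
#' @param modifiers A `disease_modifiers` object.
#' @return A modified, re-validated `physiology_spec`.
#' @export
apply_modifiers <- function(base, modifiers) {
  validate_physiology(base)
  validate_modifiers(modifiers)
  spec <- base
  spec$organ_volumes["liver"] <-
    spec$organ_volumes["liver"] * modifiers$liver_volume_scalar
  q <- spec$organ_blood_flows
  ha <- spec$hepatic_artery_flow * modifiers$hepatic_flow_scalar
  q[PORTAL_TISSUES] <- q[PORTAL_TISSUES] * modifiers$hepatic_flow_scalar
  q["kidney"] <- q["kidney"] * modifiers$renal_flow_scalar
  # cardiac output is held; rest-of-body absorbs the residual
  others <- setdiff(ARTERIAL_TISSUES, "rest")
  q["rest"] <- spec$cardiac_output - sum(q[others]) - ha
  if (q["rest"] <= 0)
    stop("modifiers drive the rest-of-body flow non-positive")
  q["liver"] <- ha + sum(q[PORTAL_TISSUES])
  q["lung"] <- q["blood"] <- spec$cardiac_output
  spec$organ_blood_flows <- q
  spec$hepatic_artery_flow <- ha
  spec$portal_vein_flow <- sum(q[PORTAL_TISSUES])
  spec$renal_plasma_flow <- unname(q["kidney"]) * (1 - spec$hematocrit)
  if (!identical(modifiers$albumin_target, "unchanged")) {
    if (modifiers$albumin_target <= 0) stop("albumin target must be positive")
    spec$albumin_conc <- modifiers$albumin_target
  }
  validate_physiology(spec)
}

# rare extreme albumin deviates are truncated to the valid (15, 60) g/L window
clamp_albumin <- function(x) pmin(pmax(x, 15.5), 59.5)

# log-normal deviate with median 1 and the requested CV (0 -> exactly 1)
lognormal_deviate <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  exp(rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Sample one virtual individual
#'
#' Draws body weight uniformly from the range, age uniformly from the age
#' range and sex by the female proportion; scales the reference physiology
#' allometrically (volumes with weight, flows with weight^0.75); applies
#' independent log-normal inter-individual deviates (median-one, CV per
#' parameter class); renormalizes organ volumes to the reference whole-body
#' volume fraction so the density bound always holds; then applies the
#' disease modifiers.
#'
#' @param demographics List with `age_range` (years, within 15-95),
#'   `weight_range` (kg) and `female_proportion`.
#' @param modifiers A `disease_modifiers` object.
#' @param cv List of CVs for `volumes`, `flows` and `albumin`; defaults 20%,
#'   20% and 10%.
#' @param rng_seed Optional integer; when given the individual is drawn from a
#'   freshly seeded stream and is exactly reproducible.
#' @return A `physiology_spec`.
#' @export
#' @examples
#' tb <- sample_individual(modifiers = disease_modifiers("tuberculosis"),
#'                         cv = list(volumes = 0, flows = 0, albumin = 0),
#'                         rng_seed = 1)
#' tb$albumin_conc  # 38
sample_individual <- function(demographics = list(), modifiers =
                                disease_modifiers("healthy"),
                              cv = DEFAULT_CV, rng_seed = NULL) {
  validate_modifiers(modifiers)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  cv <- utils::modifyList(DEFAULT_CV, cv)
  dem <- utils::modifyList(list(age_range = c(20, 50),
                                weight_range = modifiers$body_weight_range,
                                female_proportion = 0), demographics)
  ar <- dem$age_range; wr <- dem$weight_range
  if (length(ar) != 2 || ar[1] > ar[2] || ar[1] < 15 || ar[2] > 95)
    stop("age range must lie within 15-95 years")
  if (length(wr) != 2 || wr[1] > wr[2] || wr[1] <= 0)
    stop("weight range must be positive and ordered")
  weight <- runif(1, wr[1], wr[2])
  age <- runif(1, ar[1], ar[2])
  sex <- if (runif(1) < dem$female_proportion) "female" else "male"
  spec <- reference_physiology(body_weight = weight, sex = sex, age = age)

  total_frac <- sum(spec$organ_volumes) / weight  # reference body-volume frac
  v <- spec$organ_volumes * lognormal_deviate(length(TISSUES), cv$volumes)
  spec$organ_volumes <- v * (total_frac * weight / sum(v))

  q <- spec$organ_blood_flows
  q[ARTERIAL_TISSUES] <- q[ARTERIAL_TISSUES] *
    lognormal_deviate(length(ARTERIAL_TISSUES), cv$flows)
  ha <- spec$hepatic_artery_flow * lognormal_deviate(1, cv$flows)
  co <- sum(q[ARTERIAL_TISSUES]) + ha
  q["liver"] <- ha + sum(q[PORTAL_TISSUES])
  q["lung"] <- q["blood"] <- co
  spec$organ_blood_flows <- q
  spec$hepatic_artery_flow <- ha
  spec$portal_vein_flow <- sum(q[PORTAL_TISSUES])
  spec$cardiac_output <- co
  spec$renal_plasma_flow <- unname(q["kidney"]) * (1 - spec$hematocrit)
  # truncate albumin deviates to the physiologically valid window
  spec$albumin_conc <- clamp_albumin(REF_ALBUMIN * lognormal_deviate(1, cv$albumin))

  out <- apply_modifiers(spec, healthy_identity(modifiers))
  if (!identical(modifiers$albumin_target, "unchanged")) {
    # disease albumin target replaces the healthy mean; variability re-applied
    out$albumin_conc <- clamp_albumin(modifiers$albumin_target *
                                        lognormal_deviate(1, cv$albumin))
  }
  validate_physiology(out)
}

# The physiological part of the modifiers (albumin handled separately so the
# disease target can carry its own variability).
healthy_identity <- function(m) {
  m2 <- m
  m2$albumin_target <- "unchanged"
  m2
}

#' Sample a virtual population
#'
#' Seeded sampling of `n` individuals under one modifier set; regenerating
#' with the same seed and settings reproduces identical individuals.
#'
#' @param n Number of individuals.
#' @param modifiers A `disease_modifiers` object.
#' @param demographics,cv Passed to [sample_individual()].
#' @param seed Integer seed for the whole sample.
#' @return An object of class `population_sample` with fields `individuals`,
#'   `seed`, `modifiers` and `n`.
#' @export
sample_population <- function(n, modifiers = disease_modifiers("healthy"),
                              demographics = list(), cv = DEFAULT_CV,
                              seed = 1L) {
  stopifnot(n >= 1)
  # per-individual derived seeds: individual i sees the same deviate stream
  # across populations sharing a master seed (common random numbers, so
  # disease contrasts are paired rather than independent draws)
  set.seed(seed)
  ind_seeds <- sample.int(.Machine$integer.max - 1L, n)
  individuals <- lapply(seq_len(n), function(i)
    sample_individual(demographics, modifiers, cv, rng_seed = ind_seeds[i]))
  structure(list(individuals = individuals, seed = seed,
                 modifiers = modifiers, n = n),
            class = "population_sample")
}

#' Flatten a population to a data frame
#'
#' One row per individual with demographics, albumin, hematocrit, cardiac
#' output, hepatic/renal flows and all organ volumes and blood flows as
#' columns; suitable for CSV export.
#'
#' @param pop A `population_sample`.
#' @return A `data.frame`.
#' @export
population_to_df <- function(pop) {
  stopifnot(inherits(pop, "population_sample"))
  rows <- lapply(seq_along(pop$individuals), function(i) {
    s <- pop$individuals[[i]]
    data.frame(id = i, sex = s$sex, age = s$age, body_weight = s$body_weight,
               hematocrit = s$hematocrit, albumin_conc = s$albumin_conc,
               cardiac_output = s$cardiac_output,
               hepatic_artery_flow = s$hepatic_artery_flow,
               portal_vein_flow = s$portal_vein_flow,
               renal_plasma_flow = s$renal_plasma_flow,
               t(setNames(s$organ_volumes, paste0("vol_", TISSUES))),
               t(setNames(s$organ_blood_flows, paste0("flow_", TISSUES))))
  })
  do.call(rbind, rows)
}
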