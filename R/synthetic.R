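# Observed-like synthetic mean profiles with known ground truth, and the
# packaged clinical study designs.

#' Assay/population noise model for synthetic observed profiles
#'
#' @param proportional_cv Between-subject multiplicative CV (fraction).
#' @param additive_sd Additive assay noise, µg/mL.
#' @param n_subjects Subjects averaged into the mean curve.
#' @param lloq Lower limit of quantification, µg/mL (values below are
#'   censored).
#' @param seed Integer seed.
#' @return A `noise_model` object.
#' @export
noise_model <- function(proportional_cv = 0.25, additive_sd = 0.05,
                        n_subjects = 24, lloq = 0.1, seed = 1L) {
  if (proportional_cv < 0 || additive_sd < 0 || lloq < 0)
    stop("noise parameters must be non-negative")
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  structure(list(proportional_cv = proportional_cv,
                 additive_sd = additive_sd, n_subjects = n_subjects,
                 lloq = lloq, seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate an observed-like mean profile from a known truth
#'
#' Emulates a digitized clinical mean curve: each subject's curve is the
#' truth times independent mean-one log-normal deviates (per point) plus
#' additive Gaussian assay noise, floored at zero; values below the LLOQ are
#' censored; the reported mean at a time point averages the quantifiable
#' subjects and the point is dropped (with a warning) when fewer than half
#' of the subjects are quantifiable.  The multiplicative deviates are
#' mean-one (log-scale shift −sigma²/2) so the mean curve is unbiased for
#' the truth as the number of subjects grows.
#'
#' @param true_profile A `concentration_profile`, or a data frame with
#'   `time` and `conc` columns.
#' @param noise A [noise_model()].
#' @return List with `mean_profile` (data.frame `time`, `conc`,
#'   `n_quantifiable`) and `subjects` (long data.frame `subject`, `time`,
#'   `conc`, censored values NA).
#' @export
#' @examples
#' tr <- data.frame(time = 0:12, conc = 10 * exp(-0.3 * (0:12)))
#' obs <- generate_observed(tr, noise_model(seed = 7))
generate_observed <- function(true_profile, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (inherits(true_profile, "concentration_profile")) {
    tt <- true_profile$time; cc <- true_profile$conc_plasma
  } else {
    tt <- true_profile$time; cc <- true_profile$conc
  }
  if (any(cc < 0)) stop("true profile must be non-negative")
  set.seed(noise$seed)
  n <- noise$n_subjects
  sig <- sqrt(log(1 + noise$proportional_cv^2))
  m <- matrix(cc, nrow = length(cc), ncol = n)
  if (noise$proportional_cv > 0)
    m <- m * exp(matrix(rnorm(length(m), -sig^2 / 2, sig), nrow = nrow(m)))
  if (noise$additive_sd > 0)
    m <- m + matrix(rnorm(length(m), 0, noise$additive_sd), nrow = nrow(m))
  m[m < 0] <- 0
  m[m < noise$lloq] <- NA_real_
  n_q <- rowSums(!is.na(m))
  keep <- n_q >= n / 2
  if (!all(keep))
    warning(sum(!keep), " time point(s) dropped: fewer than half of the ",
            "subjects quantifiable")
  mean_profile <- data.frame(time = tt[keep],
                             conc = rowMeans(m[keep, , drop = FALSE],
                                             na.rm = TRUE),
                             n_quantifiable = n_q[keep])
  subjects <- data.frame(subject = rep(seq_len(n), each = length(tt)),
                         time = rep(tt, times = n), conc = as.vector(m))
  list(mean_profile = mean_profile, subjects = subjects)
}

#' Packaged clinical study designs
#'
#' The single-dose rifampicin study designs used for model development and
#' evaluation: 17 healthy designs (2 i.v. infusion, 15 oral; 300-600 mg and
#' 10 mg/kg), 6 tuberculosis oral designs (450-600 mg, 10 mg/kg) and 4
#' cirrhosis (Child-Pugh A) oral designs (4, 6, 8 and 10 mg/kg), each with
#' the study's subject count, age range, weight range and female proportion
#' (all fasted).  Missing demographic entries are filled with the
#' population's default ranges.
#'
#' @return A data.frame of ready-to-run scenario configurations.
#' @export
#' @examples
#' nrow(subset(scenario_suite(), population == "cirrhosis"))  # 4
scenario_suite <- function() {
  h <- function(id, n, dose, unit, route, a1, a2, w1, w2, fem)
    data.frame(scenario_id = id, population = "healthy", cp_class = "none",
               n_subjects = n, dose = dose, dose_unit = unit, route = route,
               age_min = a1, age_max = a2, weight_min = w1, weight_max = w2,
               female_proportion = fem, fasted = TRUE)
  healthy <- rbind(
    h("H01_iv450",   2, 450, "mg", "iv_infusion", 25, 60, 60, 85, 0),
    h("H02_iv600",   6, 600, "mg", "iv_infusion", 25, 60, 60, 85, 0),
    h("H03_po300",  12, 300, "mg", "oral", 25, 53, 48, 88, 0),
    h("H04_po600",  24, 600, "mg", "oral", 19, 45, 60, 101.4, 0),
    h("H05_po600",  18, 600, "mg", "oral", 18, 55, 50, 85, 0),
    h("H06_po600",  22, 600, "mg", "oral", 18, 55, 50, 85, 0),
    h("H07_po600",  16, 600, "mg", "oral", 28, 59, 51, 80, 0.68),
    h("H08_po600",  18, 600, "mg", "oral", 18, 40, 60, 85, 0.5),
    h("H09_po450",  66, 450, "mg", "oral", 18, 55, 50, 85, 0.5),
    h("H10_po600",  61, 600, "mg", "oral", 18, 55, 50, 85, 0),
    h("H11_po600",  19, 600, "mg", "oral", 19, 29, 49, 95, 0.73),
    h("H12_po600",   8, 600, "mg", "oral", 18, 50, 70, 90, 0.5),
    h("H13_po10mgkg", 6, 10, "mg_per_kg", "oral", 60, 95, 44, 81, 0.33),
    h("H14_po450",  13, 450, "mg", "oral", 18, 45, 60, 85, 0),
    h("H15_po450",  13, 450, "mg", "oral", 15, 59, 60, 85, 0),
    h("H16_po300",  30, 300, "mg", "oral", 20, 50, 60, 85, 0.5),
    h("H17_po10mgkg", 24, 10, "mg_per_kg", "oral", 18, 65, 60, 85, 0.6))
  tb <- function(id, n, dose, unit, a1, a2, w1, w2, fem)
    data.frame(scenario_id = id, population = "tuberculosis",
               cp_class = "none", n_subjects = n, dose = dose,
               dose_unit = unit, route = "oral", age_min = a1, age_max = a2,
               weight_min = w1, weight_max = w2, female_proportion = fem,
               fasted = TRUE)
  tuberculosis <- rbind(
    tb("T01_po10mgkg", 24, 10, "mg_per_kg", 18, 65, 38, 55, 0.6),
    tb("T02_po600", 23, 600, "mg", 18, 55, 42, 52, 0.47),
    tb("T03_po450", 24, 450, "mg", 18, 55, 42, 52, 0.47),
    tb("T04_po450", 18, 450, "mg", 18, 60, 42, 52, 0.61),
    tb("T05_po450", 13, 450, "mg", 15, 59, 38, 55, 0),
    tb("T06_po450", 20, 450, "mg", 30, 51, 38, 48, 0.4))
  cir <- function(id, dose)
    data.frame(scenario_id = id, population = "cirrhosis", cp_class = "A",
               n_subjects = 7, dose = dose, dose_unit = "mg_per_kg",
               route = "oral", age_min = 18, age_max = 60, weight_min = 60,
               weight_max = 85, female_proportion = 0.5, fasted = TRUE)
  cirrhosis <- rbind(cir("C01_po4mgkg", 4), cir("C02_po6mgkg", 6),
                     cir("C03_po8mgkg", 8), cir("C04_po10mgkg", 10))
  out <- rbind(healthy, tuberculosis, cirrhosis)
  rownames(out) <- NULL
  out
}
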