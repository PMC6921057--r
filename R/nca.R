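# Non-compartmental analysis of concentration-time profiles.

#' Non-compartmental analysis
#'
#' Computes the standard single-dose NCA metrics from a concentration-time
#' series: AUC(0-t) by the linear trapezoid, terminal slope `lambda_z` by
#' unweighted log-linear regression on the terminal points (last 3 by
#' default, extendable by a best-adjusted-R-squared search over 3-6 points,
#' ties broken toward fewer points), AUC(0-inf) by `C_last / lambda_z`
#' extrapolation, Cmax/Tmax, AUMC, half-life, clearance `dose / AUC(0-inf)`
#' (apparent CL/F for oral input) and, for i.v. infusion input, moment-based
#' Vss `CL * (AUMC/AUC - AUC-weighted infusion correction)`.
#'
#' @param time Strictly increasing sampling times, h.
#' @param conc Non-negative concentrations, same units throughout (µg/mL).
#' @param dose_mg Administered dose, mg.
#' @param route `"iv"` or `"oral"`; a missing time-zero sample for an oral
#'   profile is treated as concentration zero.
#' @param lambda_z_points Fixed number of terminal points, or `NULL` for the
#'   adjusted-R-squared search.
#' @param infusion_duration Infusion length in h (for the i.v. Vss moment
#'   correction); ignored for oral input.
#' @return An object of class `nca_metrics` with fields `auc_0_t`,
#'   `auc_0_inf`, `aumc`, `cmax`, `tmax`, `lambda_z`, `half_life`,
#'   `cl_over_f`, `extrapolated_fraction`, `vss` (i.v. only),
#'   `lambda_z_n_points` and `flag_extrapolation` (TRUE when more than 20%
#'   of the AUC is extrapolated).
#' @export
#' @examples
#' run_nca(c(0, 1, 2, 3), c(0, 10, 5, 2.5), dose_mg = 100, route = "iv")
run_nca <- function(time, conc, dose_mg, route = c("iv", "oral"),
                    lambda_z_points = NULL, infusion_duration = 0) {
  route <- match.arg(route)
  if (length(time) != length(conc)) stop("time and conc lengths differ")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (route == "oral" && time[1] > 0) {
    time <- c(0, time); conc <- c(0, conc)
  }
  if (length(time) < 4) stop("at least 4 points are required")
  if (dose_mg <= 0) stop("dose must be positive")

  auc_0_t <- sum(diff(time) * (head2(conc) + tail2(conc)) / 2)
  aumc_0_t <- sum(diff(time) * (head2(time * conc) + tail2(time * conc)) / 2)
  if (auc_0_t <= 0) stop("profile carries no exposure")
  cmax <- max(conc)
  tmax <- time[which.max(conc)]

  lz <- terminal_slope(time, conc, tmax, lambda_z_points)
  c_last <- conc[max(which(conc > 0))]
  t_last <- time[max(which(conc > 0))]
  auc_extra <- c_last / lz$lambda_z
  auc_0_inf <- auc_0_t + auc_extra
  aumc <- aumc_0_t + c_last * t_last / lz$lambda_z + c_last / lz$lambda_z^2
  extrap <- auc_extra / auc_0_inf
  cl <- dose_mg / auc_0_inf
  vss <- if (route == "iv") {
    mrt <- aumc / auc_0_inf - infusion_duration / 2
    cl * mrt
  } else NA_real_
  structure(list(auc_0_t = auc_0_t, auc_0_inf = auc_0_inf, aumc = aumc,
                 cmax = cmax, tmax = tmax, lambda_z = lz$lambda_z,
                 half_life = log(2) / lz$lambda_z, cl_over_f = cl,
                 extrapolated_fraction = extrap, vss = vss, route = route,
                 dose_mg = dose_mg, lambda_z_n_points = lz$n_points,
                 flag_extrapolation = extrap > 0.2),
            class = "nca_metrics")
}

head2 <- function(x) x[-length(x)]
tail2 <- function(x) x[-1]

# log-linear terminal regression; candidates are the last n points strictly
# after Tmax with positive concentrations
terminal_slope <- function(time, conc, tmax, n_fixed = NULL) {
  usable <- which(time >= tmax & conc > 0)
  if (length(usable) < 3)
    stop("terminal phase unidentifiable: fewer than 3 positive points ",
         "after Tmax")
  fit_n <- function(n) {
    idx <- utils::tail(usable, n)
    fit <- lm(log(conc[idx]) ~ time[idx])
    slope <- -coef(fit)[[2]]
    # noise-free profiles fit exactly; the perfect-fit warning is meaningless
    r2adj <- suppressWarnings(summary(fit)$adj.r.squared)
    list(lambda_z = slope, r2adj = r2adj, n = n)
  }
  if (!is.null(n_fixed)) {
    if (n_fixed < 3 || n_fixed > length(usable))
      stop("invalid number of terminal points")
    best <- fit_n(n_fixed)
  } else {
    cands <- lapply(3:min(6, length(usable)), fit_n)
    r2 <- vapply(cands, `[[`, numeric(1), "r2adj")
    best <- cands[[which.max(r2 - 1e-12 * seq_along(r2))]]  # ties -> fewer
  }
  if (!is.finite(best$lambda_z) || best$lambda_z <= 1e-8)
    stop("terminal slope is non-positive: no terminal elimination phase")
  list(lambda_z = best$lambda_z, n_points = best$n)
}

#' NCA over a set of profiles
#'
#' @param profiles List of `concentration_profile` objects (or data frames
#'   with `time` and `conc` columns plus a `dose_mg` attribute supplied via
#'   `dose_mg`).
#' @param dose_mg Optional dose override (vector recycled over profiles).
#' @param route `"iv"` or `"oral"`.
#' @param ... Passed to [run_nca()].
#' @return A data.frame, one row per profile, with all NCA fields.
#' @export
nca_table <- function(profiles, dose_mg = NULL, route = "iv", ...) {
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    if (inherits(p, "concentration_profile")) {
      d <- if (is.null(dose_mg)) p$dose_mg else rep(dose_mg, length.out = i)[i]
      m <- run_nca(p$time, p$conc_plasma, d, route,
                   infusion_duration =
                     if (is.na(p$infusion_duration)) 0 else p$infusion_duration,
                   ...)
    } else {
      m <- run_nca(p$time, p$conc, rep(dose_mg, length.out = i)[i], route, ...)
    }
    data.frame(profile = i, auc_0_t = m$auc_0_t, auc_0_inf = m$auc_0_inf,
               aumc = m$aumc, cmax = m$cmax, tmax = m$tmax,
               lambda_z = m$lambda_z, half_life = m$half_life,
               cl_over_f = m$cl_over_f,
               extrapolated_fraction = m$extrapolated_fraction,
               vss = m$vss, lambda_z_n_points = m$lambda_z_n_points)
  })
  do.call(rbind, rows)
}
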