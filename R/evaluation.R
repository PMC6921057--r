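# Model evaluation statistics: observed/predicted ratios with range or 95%
# CI, average fold error, root mean square error, the two-fold criterion and
# goodness-of-fit residuals.

#' Observed/predicted ratio summary
#'
#' Per-pair ratio `observed / predicted`, with its mean, min-max range and,
#' when three or more pairs are available, a t-based 95% confidence interval
#' of the mean (with two pairs only the range is meaningful and `ci95` is
#' `NA`, mirroring how two-study summaries are reported).
#'
#' @param observed,predicted Positive numeric vectors of equal length.
#' @return List with `ratios`, `mean`, `range` and `ci95`.
#' @export
#' @examples
#' ratio_obs_pred(c(7.86, 8.15), c(6.23, 6.22))$mean  # ~1.29
ratio_obs_pred <- function(observed, predicted) {
  check_pairs(observed, predicted)
  r <- observed / predicted
  n <- length(r)
  ci <- if (n >= 3) {
    se <- sd(r) / sqrt(n)
    mean(r) + c(-1, 1) * qt(0.975, n - 1) * se
  } else c(NA_real_, NA_real_)
  list(ratios = r, mean = mean(r), range = range(r), ci95 = ci)
}

check_pairs <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1)
    stop("observed and predicted must be equal-length, non-empty")
  if (any(observed <= 0)) stop("non-positive observed value")
  if (any(predicted <= 0)) stop("non-positive predicted value")
  invisible(TRUE)
}

#' Average fold error
#'
#' `AFE = 10^(mean(log10(fold error)))` with fold error = observed/predicted:
#' the geometric mean of the obs/pred ratios.  Symmetric on the log scale, so
#' fold errors 2 and 0.5 average to exactly 1.
#'
#' @inheritParams ratio_obs_pred
#' @return The average fold error (dimensionless, > 0).
#' @export
afe <- function(observed, predicted) {
  check_pairs(observed, predicted)
  10^mean(log10(observed / predicted))
}

#' Root mean square error
#'
#' `RMSE = sqrt(mean((observed - predicted)^2))`, in the units of the
#' compared parameter.
#'
#' @inheritParams ratio_obs_pred
#' @return The RMSE (>= 0).
#' @export
rmse <- function(observed, predicted) {
  check_pairs(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

#' Two-fold criterion
#'
#' Flags each obs/pred ratio as inside the inclusive `[0.5, 2]` acceptance
#' band; `overall` is `TRUE` only when every pair passes.
#'
#' @inheritParams ratio_obs_pred
#' @return List with `ratios`, `within` (logical per pair) and `overall`.
#' @export
#' @examples
#' twofold_check(1, 2)$within  # ratio 0.5: boundary counts as inside
twofold_check <- function(observed, predicted) {
  check_pairs(observed, predicted)
  r <- observed / predicted
  within <- r >= 0.5 & r <= 2
  list(ratios = r, within = within, overall = all(within))
}

#' Goodness-of-fit residual table
#'
#' Interpolates the predicted profile onto the observed sampling times and
#' tabulates the residual (observed - predicted) against prediction and
#' time, together with the log-scale pred-vs-obs pairs and a flag for points
#' outside the two-fold envelope.
#'
#' @param obs_profile,pred_profile Data frames (or lists) with `time` and
#'   `conc` elements; the prediction may also be a `concentration_profile`.
#' @return A data.frame with columns `time`, `observed`, `predicted`,
#'   `residual` and `within_twofold` (NA where either value is
#'   non-positive).
#' @export
gof_residuals <- function(obs_profile, pred_profile) {
  ot <- obs_profile$time; oc <- obs_profile$conc
  if (inherits(pred_profile, "concentration_profile")) {
    pt <- pred_profile$time; pc <- pred_profile$conc_plasma
  } else {
    pt <- pred_profile$time; pc <- pred_profile$conc
  }
  if (min(ot) > max(pt) || max(ot) < min(pt))
    stop("observed and predicted time ranges do not overlap")
  keep <- ot >= min(pt) & ot <= max(pt)
  ot <- ot[keep]; oc <- oc[keep]
  pred <- approx(pt, pc, xout = ot)$y
  ratio <- ifelse(oc > 0 & pred > 0, oc / pred, NA_real_)
  data.frame(time = ot, observed = oc, predicted = pred,
             residual = oc - pred,
             within_twofold = ratio >= 0.5 & ratio <= 2)
}

#' Packaged observed/predicted parameter pairs
#'
#' Loads the packaged transcription of the published observed-vs-predicted
#' PK parameter table (healthy i.v./oral, tuberculosis oral, cirrhosis oral;
#' AUC(0-inf), CL or CL/F, Cmax per dose level).  Tuberculosis rows carry the
#' flag `tb_aggregate`: the published summary statistics for that population
#' derive from profiles the table does not print (and the 600 mg predicted
#' CL is a probable misprint), so those pairs are excluded from
#' reproduction checks by default.
#'
#' @param include_flagged Keep flagged rows (default FALSE).
#' @return A data.frame with columns `population`, `route`, `dose_label`,
#'   `parameter`, `observed`, `predicted`, `flag`.
#' @export
observed_predicted_pairs <- function(include_flagged = FALSE) {
  file <- system.file("extdata", "obs_pred_pairs.csv", package = "rifpbpk")
  df <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  df$flag[is.na(df$flag)] <- ""
  if (!include_flagged) df <- df[df$flag == "", ]
  df
}

#' Published evaluation summary anchors
#'
#' Loads the packaged transcription of the published per-population
#' evaluation summaries (mean ratio with range, AFE, RMSE) with per-cell
#' reproducibility flags.
#'
#' @return A data.frame.
#' @export
published_evaluation_summary <- function() {
  file <- system.file("extdata", "published_evaluation.csv", package = "rifpbpk")
  read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
}

#' Recompute the evaluation summary table from parameter pairs
#'
#' Groups observed/predicted pairs by population, route and parameter and
#' recomputes the mean obs/pred ratio with range and (n >= 3) 95% CI, the
#' AFE, the RMSE and the two-fold verdict — the full evaluation summary — so
#' it can be compared cell-by-cell with the published version.
#'
#' @param pairs A data.frame as from [observed_predicted_pairs()] (or the same columns
#'   built from fresh simulations).
#' @return A data.frame, one row per population/route/parameter group.
#' @export
reproduce_evaluation_summary <- function(pairs = observed_predicted_pairs()) {
  key <- interaction(pairs$population, pairs$route, pairs$parameter,
                     drop = TRUE)
  rows <- lapply(split(pairs, key), function(g) {
    r <- ratio_obs_pred(g$observed, g$predicted)
    tf <- twofold_check(g$observed, g$predicted)
    data.frame(population = g$population[1], route = g$route[1],
               parameter = g$parameter[1], n = nrow(g),
               mean_ratio = r$mean, ratio_lo = r$range[1],
               ratio_hi = r$range[2], ci95_lo = r$ci95[1],
               ci95_hi = r$ci95[2],
               afe = afe(g$observed, g$predicted),
               rmse = rmse(g$observed, g$predicted),
               within_twofold = tf$overall)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$population, out$route, out$parameter), ]
}
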