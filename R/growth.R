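# Growth-parameter extraction from optical-density time series: efficiency,
# baseline-subtracted AUC, maximum specific growth rate (mu_max), lag time
# (tangent construction) and doubling time T_d = ln(2)/mu_max.

#' Calibrate light-scattering readings to OD
#'
#' Ordinary least-squares line mapping instrument light-scattering (LS)
#' values to OD measured on anchor samples, applied to a whole series.
#'
#' @param ls Numeric LS series to convert.
#' @param anchor_ls,anchor_od Paired anchor measurements (>= 2 pairs).
#' @return Numeric OD series; the fitted `lm` is attached as attribute
#'   `"fit"`.
#' @export
calibrate_ls_to_od <- function(ls, anchor_ls, anchor_od) {
  stopifnot(length(anchor_ls) == length(anchor_od), length(anchor_ls) >= 2)
  fit <- lm(anchor_od ~ anchor_ls)
  out <- as.numeric(coef(fit)[1] + coef(fit)[2] * ls)
  attr(out, "fit") <- fit
  out
}

#' Extract growth parameters from one growth curve
#'
#' Definitions: efficiency = OD(end) - OD(start) (biomass gained from
#' inoculation to the end of the experiment); AUC = trapezoid integral of
#' OD minus the baseline (initial OD), clipped at zero; mu_max = maximum of
#' d/dt ln(OD), estimated from the first derivative of a smoothing-spline
#' fit to ln OD (`smoothing = "spline"`, GCV-selected smoothness) or as the
#' maximum sliding-window OLS slope of ln OD (`smoothing = "window"`);
#' lag time = the time where the tangent at the maximal growth rate crosses
#' the initial log-OD level, `t* - (ln OD(t*) - ln OD(0)) / mu_max`;
#' doubling time = ln(2) / mu_max.
#'
#' @param time Time points in hours, strictly increasing (>= 10 points).
#' @param od OD values (> 0).
#' @param smoothing `"spline"` or `"window"`.
#' @param window Number of points per window for `smoothing = "window"`.
#' @return List of class `growth_params`: `efficiency`, `auc`, `mu_max`,
#'   `lag_time`, `doubling_time` (the last three `NA` when no positive
#'   growth rate is found).
#' @export
growth_params <- function(time, od, smoothing = c("spline", "window"),
                          window = 7L) {
  smoothing <- match.arg(smoothing)
  stopifnot(length(time) == length(od), length(time) >= 10)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing",
                                 call. = FALSE)
  if (any(od <= 0)) stop("OD values must be positive", call. = FALSE)
  efficiency <- od[length(od)] - od[1]
  base <- od[1]
  y <- pmax(od - base, 0)
  auc <- sum(diff(time) * (head(y, -1) + tail(y, -1)) / 2)
  lo <- log(od)
  if (smoothing == "spline") {
    fit <- smooth.spline(time, lo)
    grid <- seq(min(time), max(time), length.out = 512)
    d1 <- predict(fit, grid, deriv = 1)$y
    i <- which.max(d1)
    mu <- d1[i]; t_star <- grid[i]
    lo_star <- predict(fit, t_star)$y
  } else {
    n <- length(time)
    w <- min(window, n)
    slopes <- vapply(seq_len(n - w + 1), function(i) {
      idx <- i:(i + w - 1)
      coef(lm(lo[idx] ~ time[idx]))[2]
    }, numeric(1))
    i <- which.max(slopes)
    mu <- slopes[i]
    idx <- i:(i + w - 1)
    t_star <- mean(time[idx])
    lo_star <- mean(lo[idx])
  }
  if (!is.finite(mu) || mu <= 1e-8) {  # numerically flat: no growth phase
    mu <- NA_real_; lag <- NA_real_; td <- NA_real_
  } else {
    lag <- t_star - (lo_star - lo[1]) / mu
    td <- log(2) / mu
  }
  structure(list(efficiency = efficiency, auc = auc, mu_max = mu,
                 lag_time = lag, doubling_time = td),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(paste0("growth_params: efficiency %.3f, AUC %.3f, ",
                     "mu_max %.4f /h, lag %.2f h, Td %.3f h\n"),
              x$efficiency, x$auc, x$mu_max, x$lag_time, x$doubling_time))
  invisible(x)
}

#' Growth parameters for a table of curves
#'
#' @param data Long-format data.frame with columns `strain`, `replicate`
#'   (optional), `time`, `value`.
#' @param smoothing Passed to [growth_params()].
#' @return data.frame of per-strain (averaged over replicates) growth
#'   parameters, usable directly as QTL traits.
#' @export
growth_trait_table <- function(data, smoothing = "spline") {
  if (!("replicate" %in% names(data))) data$replicate <- 1L
  keys <- unique(data[, c("strain", "replicate")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    d <- data[data$strain == keys$strain[i] &
                data$replicate == keys$replicate[i], ]
    d <- d[order(d$time), ]
    gp <- growth_params(d$time, d$value, smoothing = smoothing)
    data.frame(strain = keys$strain[i], replicate = keys$replicate[i],
               efficiency = gp$efficiency, auc = gp$auc,
               mu_max = gp$mu_max, lag_time = gp$lag_time,
               doubling_time = gp$doubling_time, stringsAsFactors = FALSE)
  })
  per_rep <- do.call(rbind, rows)
  agg <- stats::aggregate(per_rep[, c("efficiency", "auc", "mu_max",
                                      "lag_time", "doubling_time")],
                          by = list(strain = per_rep$strain),
                          FUN = mean, na.rm = TRUE)
  agg
}
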