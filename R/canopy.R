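#' Cardinal temperatures for beta thermal time
#'
#' Container for the three cardinal temperatures of the beta
#' temperature-response function. Defaults follow the potato
#' canopy-modelling literature.
#'
#' @param t_base Base temperature (deg C) below which no thermal time accrues.
#' @param t_opt Optimum temperature (deg C); one calendar day at `t_opt`
#'   contributes exactly one thermal day (td).
#' @param t_high Upper temperature (deg C) above which no thermal time accrues.
#' @return An object of class `cardinal_temperatures`.
#' @export
cardinal_temperatures <- function(t_base = 5.5, t_opt = 23.4, t_high = 34.9) {
  stopifnot(is.numeric(t_base), is.numeric(t_opt), is.numeric(t_high))
  if (!(t_base < t_opt && t_opt < t_high)) {
    stop("cardinal temperatures must satisfy t_base < t_opt < t_high")
  }
  structure(list(t_base = t_base, t_opt = t_opt, t_high = t_high),
            class = "cardinal_temperatures")
}

#' Daily thermal unit under the beta temperature response
#'
#' @param temp Vector of daily mean temperatures (deg C).
#' @param cardinals A [cardinal_temperatures()] object.
#' @return Thermal units in td/day, 0 outside `(t_base, t_high)` and 1 at
#'   `t_opt`.
#' @export
beta_thermal_unit <- function(temp, cardinals = cardinal_temperatures()) {
  if (any(!is.finite(temp))) stop("temperatures must be finite")
  tb <- cardinals$t_base; to <- cardinals$t_opt; th <- cardinals$t_high
  u <- ((th - temp) / (th - to)) *
    ((temp - tb) / (to - tb))^((to - tb) / (th - to))
  u[temp <= tb | temp >= th] <- 0
  u
}

#' Cumulative beta thermal time from emergence
#'
#' Converts a sequence of daily mean temperatures (starting at plot
#' emergence) into a cumulative thermal-day axis.
#'
#' @inheritParams beta_thermal_unit
#' @param daily_mean_temps Daily mean temperatures (deg C), one per day.
#' @return Numeric vector of cumulative thermal days, one per input day.
#' @export
beta_thermal_day <- function(daily_mean_temps, cardinals = cardinal_temperatures()) {
  cumsum(beta_thermal_unit(daily_mean_temps, cardinals))
}

#' Canopy development curve parameters
#'
#' The five parameters of the three-phase canopy development curve:
#' `tm1` (inflection point of the build-up phase, td), `t1` (thermal day at
#' which soil cover stabilises, td), `t2` (onset of senescence, td), `te`
#' (complete senescence, td) and `Vx` (maximum percent soil cover).
#'
#' @param tm1,t1,t2,te Phase boundaries in thermal days, `0 < tm1 < t1 <= t2 < te`.
#' @param Vx Maximum soil cover in percent, `0 < Vx <= 100`.
#' @return An object of class `canopy_params`.
#' @export
canopy_params <- function(tm1, t1, t2, te, Vx) {
  p <- list(tm1 = tm1, t1 = t1, t2 = t2, te = te, Vx = Vx)
  if (any(!vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), TRUE))) {
    stop("canopy parameters must be finite scalars")
  }
  if (!(0 < tm1 && tm1 < t1 && t1 <= t2 && t2 < te)) {
    stop("canopy parameters must satisfy 0 < tm1 < t1 <= t2 < te")
  }
  if (!(0 < Vx && Vx <= 100)) stop("Vx must be in (0, 100]")
  structure(p, class = "canopy_params")
}

#' @export
print.canopy_params <- function(x, ...) {
  cat(sprintf("Canopy curve: tm1=%.2f t1=%.2f t2=%.2f te=%.2f td, Vx=%.1f %%SC\n",
              x$tm1, x$t1, x$t2, x$te, x$Vx))
  invisible(x)
}

#' Evaluate the three-phase canopy development curve
#'
#' Build-up phase (beta growth curve with inflection `tm1` and maximum `Vx`
#' reached at `t1`), constant plateau between `t1` and `t2`, linear
#' senescence reaching zero at `te`.
#'
#' @param params A [canopy_params()] object.
#' @param t Thermal days since emergence (vectorised), `t >= 0`.
#' @return Percent soil cover at each `t`.
#' @export
evaluate_canopy <- function(params, t) {
  stopifnot(inherits(params, "canopy_params"))
  if (any(t < 0)) stop("thermal time t must be >= 0")
  tm1 <- params$tm1; t1 <- params$t1; t2 <- params$t2; te <- params$te
  Vx <- params$Vx
  v <- numeric(length(t))
  up <- t <= t1
  v[up] <- Vx * (1 + (t1 - t[up]) / (t1 - tm1)) * (t[up] / t1)^(t1 / (t1 - tm1))
  v[t > t1 & t <= t2] <- Vx
  sen <- t > t2 & t <= te
  v[sen] <- Vx * (te - t[sen]) / (te - t2)
  v[t > te] <- 0
  v
}

#' A per-plot canopy cover series on a thermal-time axis
#'
#' @param plot_id Plot identifier.
#' @param thermal_day Monotone non-decreasing thermal-day coordinates with
#'   origin at plot emergence.
#' @param cover Percent soil cover in `[0, 100]`, same length as `thermal_day`.
#' @return An object of class `canopy_series` (a data frame).
#' @export
canopy_series <- function(plot_id, thermal_day, cover) {
  stopifnot(length(thermal_day) == length(cover))
  if (any(thermal_day < 0)) stop("thermal days must be >= 0")
  if (is.unsorted(thermal_day)) stop("thermal days must be non-decreasing")
  if (any(cover < 0 | cover > 100)) stop("cover must be in [0, 100]")
  structure(data.frame(plot_id = plot_id, thermal_day = thermal_day,
                       cover = cover),
            class = c("canopy_series", "data.frame"))
}

## Unconstrained parameter vector <-> canopy_params. The log/logit map
## enforces 0 < tm1 < t1 <= t2 < te and 0 < Vx < 100 without constraints.
theta_to_canopy <- function(theta) {
  tm1 <- exp(theta[1])
  t1 <- tm1 + exp(theta[2])
  t2 <- t1 + exp(theta[3])
  te <- t2 + exp(theta[4])
  canopy_params(tm1, t1, t2, te, 100 * stats::plogis(theta[5]))
}

canopy_to_theta <- function(p) {
  c(log(p$tm1), log(p$t1 - p$tm1), log(max(p$t2 - p$t1, 1e-6)),
    log(p$te - p$t2), stats::qlogis(min(p$Vx, 99.9) / 100))
}

## Landmark-based starting values: tm1 near the half-max crossing of the
## rise, t1/t2 bracketing the >=95%-of-max region, te at the return below
## 5% of max.
canopy_init <- function(td, cover) {
  vx <- max(cover)
  i_max <- which.max(cover)
  rise <- seq_len(i_max)
  tm1 <- td[rise][which.min(abs(cover[rise] - vx / 2))]
  t1 <- td[min(which(cover >= 0.95 * vx))]
  t2 <- td[max(which(cover >= 0.95 * vx))]
  after <- which(td > t2 & cover <= 0.05 * vx)
  te <- if (length(after)) td[min(after)] else max(td) + 0.1 * diff(range(td))
  tm1 <- max(min(tm1, 0.8 * t1), 0.05 * t1, 1e-3)
  t2 <- max(t2, t1 + 1e-3)
  te <- max(te, t2 + 1)
  canopy_params(tm1, t1, t2, te, min(vx, 99.5))
}

#' Fit the canopy development curve to an observed cover series
#'
#' Nonlinear least squares (Levenberg-Marquardt) on a log/logit
#' reparameterization that enforces the parameter ordering
#' `0 < tm1 < t1 <= t2 < te`, `0 < Vx < 100`. Starting values come from
#' series landmarks unless `init` is supplied.
#'
#' @param series A [canopy_series()] (or data frame with columns
#'   `thermal_day` and `cover`).
#' @param init Optional [canopy_params()] starting values.
#' @return A list with elements `params` ([canopy_params()]) and
#'   `diagnostics` (list: `rss`, `n_obs`, `converged`, `n_iter`).
#' @export
fit_canopy <- function(series, init = NULL) {
  td <- series$thermal_day
  cover <- series$cover
  if (length(td) < 5) stop("at least 5 observations are required")
  if (all(cover == 0)) stop("non-convergence: cover series is all zero")
  if (!is.unsorted(cover)) {
    stop("non-convergence: cover series never declines (no senescence phase)")
  }
  start <- if (is.null(init)) canopy_init(td, cover) else init
  resid_fn <- function(theta) {
    p <- try(theta_to_canopy(theta), silent = TRUE)
    if (inherits(p, "try-error")) return(rep(1e6, length(cover)))
    r <- cover - evaluate_canopy(p, td)
    r[!is.finite(r)] <- 1e6
    r
  }
  fit <- minpack.lm::nls.lm(
    par = canopy_to_theta(start), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  params <- theta_to_canopy(fit$par)
  diagnostics <- list(rss = sum(fit$fvec^2), n_obs = length(cover),
                      converged = fit$info %in% 1:4, n_iter = fit$niter)
  list(params = params, diagnostics = diagnostics)
}

#' Derived canopy traits from fitted curve parameters
#'
#' Computes phase durations, the maximum cover progression rate and the
#' per-phase and total areas under the canopy curve. `AP1` is obtained by
#' adaptive quadrature of the build-up expression; `AP2` and `AP3` have
#' closed forms under the plateau/linear-senescence phases.
#'
#' @param params A [canopy_params()] object.
#' @return A list with elements `dur_max` (t2-t1, td), `dur_sen` (te-t2,
#'   td), `Cm` (%/td), `AP1`, `AP2`, `AP3`, `AUC` (%.td).
#' @export
derive_canopy_traits <- function(params) {
  stopifnot(inherits(params, "canopy_params"))
  tm1 <- params$tm1; t1 <- params$t1; t2 <- params$t2; te <- params$te
  Vx <- params$Vx
  ap1 <- stats::integrate(function(t) evaluate_canopy(params, t),
                          lower = 0, upper = t1, rel.tol = 1e-8,
                          subdivisions = 500L)$value
  ap2 <- Vx * (t2 - t1)
  ap3 <- Vx * (te - t2) / 2
  cm <- Vx * (2 * t1 - tm1) / (t1 * (t1 - tm1)) * (tm1 / t1)^(tm1 / (t1 - tm1))
  list(dur_max = t2 - t1, dur_sen = te - t2, Cm = cm,
       AP1 = ap1, AP2 = ap2, AP3 = ap3, AUC = ap1 + ap2 + ap3)
}

#' Fit canopy curves for a set of plots
#'
#' @param series_table Data frame with columns `plot_id`, `thermal_day`,
#'   `cover` (stacked series for many plots).
#' @return Data frame with one row per plot: the five curve parameters,
#'   the derived traits and fit diagnostics. Plots whose fit fails are
#'   returned with `converged = FALSE` and `NA` parameters.
#' @export
fit_canopy_plots <- function(series_table) {
  out <- lapply(split(series_table, series_table$plot_id), function(s) {
    fit <- try(fit_canopy(s), silent = TRUE)
    if (inherits(fit, "try-error")) {
      return(data.frame(plot_id = s$plot_id[1], tm1 = NA_real_, t1 = NA_real_,
                        t2 = NA_real_, te = NA_real_, Vx = NA_real_,
                        t2_t1 = NA_real_, te_t2 = NA_real_, Cm = NA_real_,
                        AP1 = NA_real_, AP2 = NA_real_, AP3 = NA_real_,
                        AUC = NA_real_, rss = NA_real_, converged = FALSE))
    }
    p <- fit$params
    d <- derive_canopy_traits(p)
    data.frame(plot_id = s$plot_id[1], tm1 = p$tm1, t1 = p$t1, t2 = p$t2,
               te = p$te, Vx = p$Vx, t2_t1 = d$dur_max, te_t2 = d$dur_sen,
               Cm = d$Cm, AP1 = d$AP1, AP2 = d$AP2, AP3 = d$AP3, AUC = d$AUC,
               rss = fit$diagnostics$rss,
               converged = fit$diagnostics$converged)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
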