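#' Tuber size-distribution curve parameters
#'
#' Parameters of the Gaussian (bell-shaped) curve describing how tuber
#' weight or tuber number is distributed across size classes:
#' `Tb(mcl) = MX * exp(-(mcl - B)^2 / A)`.
#'
#' @param A Dispersion parameter (mm^2); larger `A` gives a flatter curve.
#' @param B Size class midpoint (mm) at which the maximum occurs.
#' @param MX Curve maximum (kg for weight, count for number).
#' @param target Which variable the curve describes, `"weight"` or
#'   `"number"`.
#' @param b_range Plausible range for `B` (mm); fits outside it are
#'   rejected.
#' @return An object of class `tuber_curve_params`.
#' @export
tuber_curve_params <- function(A, B, MX, target = c("weight", "number"),
                               b_range = c(0, 120)) {
  target <- match.arg(target)
  if (!is.finite(A) || A <= 0) stop("dispersion A must be > 0")
  if (!is.finite(MX) || MX <= 0) stop("curve maximum MX must be > 0")
  if (!is.finite(B) || B < b_range[1] || B > b_range[2]) {
    stop("B outside the plausible size range")
  }
  structure(list(A = A, B = B, MX = MX, target = target),
            class = "tuber_curve_params")
}

#' Evaluate the tuber size-distribution curve
#'
#' @param params A [tuber_curve_params()] object.
#' @param mcl Size class midpoints (mm), vectorised.
#' @return Curve value at each midpoint; symmetric about `B` with maximum
#'   `MX` at `mcl = B`.
#' @export
evaluate_bell <- function(params, mcl) {
  stopifnot(inherits(params, "tuber_curve_params"))
  params$MX * exp(-(mcl - params$B)^2 / params$A)
}

#' Size-class midpoints for the standard grading classes
#'
#' @param class_low_mm,class_high_mm Lower and upper bounds of each size
#'   class in mm; the open top class (upper bound `Inf` or `NA`) is
#'   assigned `open_class_midpoint`.
#' @param open_class_midpoint Midpoint for the open top class (mm).
#' @return Numeric vector of midpoints.
#' @export
class_midpoints <- function(class_low_mm, class_high_mm,
                            open_class_midpoint = 75) {
  mid <- (class_low_mm + class_high_mm) / 2
  open <- !is.finite(class_high_mm)
  mid[open] <- open_class_midpoint
  mid
}

#' Fit the tuber size-distribution curve to one plot's class table
#'
#' Least-squares fit of [evaluate_bell()] over size-class midpoints, with
#' a log parameterization of `A` and `MX` that keeps both positive.
#'
#' @param table Data frame with columns `class_low_mm`, `class_high_mm`
#'   and the target columns `weight_kg` and/or `number`.
#' @param target Fit the `"weight"` or the `"number"` distribution.
#' @param open_class_midpoint Midpoint assigned to the open top class (mm).
#' @param b_range Plausible range for `B` (mm).
#' @return A list with elements `params` ([tuber_curve_params()]) and
#'   `diagnostics` (`rss`, `n_obs`, `converged`, `n_iter`).
#' @export
fit_bell <- function(table, target = c("weight", "number"),
                     open_class_midpoint = 75, b_range = c(0, 120)) {
  target <- match.arg(target)
  col <- if (target == "weight") "weight_kg" else "number"
  if (!col %in% names(table)) stop("column '", col, "' not found")
  values <- table[[col]]
  mid <- class_midpoints(table$class_low_mm, table$class_high_mm,
                         open_class_midpoint)
  if (any(values < 0)) stop("class values must be non-negative")
  if (all(values == 0)) stop("all-zero class table")
  if (sum(values > 0) < 3) {
    stop("non-convergence: fewer than 3 informative size classes")
  }
  w <- values / sum(values)
  b0 <- sum(w * mid)
  a0 <- max(2 * sum(w * (mid - b0)^2), 1)
  theta0 <- c(log(a0), b0, log(max(values)))
  resid_fn <- function(theta) {
    values - exp(theta[3]) * exp(-(mid - theta[2])^2 / exp(theta[1]))
  }
  fit <- minpack.lm::nls.lm(
    par = theta0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  params <- tuber_curve_params(exp(fit$par[1]), fit$par[2], exp(fit$par[3]),
                               target = target, b_range = b_range)
  list(params = params,
       diagnostics = list(rss = sum(fit$fvec^2), n_obs = length(values),
                          converged = fit$info %in% 1:4, n_iter = fit$niter))
}

#' Fit tuber weight and number curves for a set of plots
#'
#' @param class_table Data frame with columns `plot_id`, `class_low_mm`,
#'   `class_high_mm`, `weight_kg`, `number` (stacked per-plot class
#'   tables).
#' @param open_class_midpoint Midpoint for the open top class (mm).
#' @return Data frame with one row per plot and columns `TbwA`, `TbwB`,
#'   `TbwMX`, `TbnA`, `TbnB`, `TbnMX`, `rss_w`, `rss_n`, `converged`.
#'   Plots whose fit fails carry `NA` and `converged = FALSE`.
#' @export
fit_bell_plots <- function(class_table, open_class_midpoint = 75) {
  out <- lapply(split(class_table, class_table$plot_id), function(s) {
    fw <- try(fit_bell(s, "weight", open_class_midpoint), silent = TRUE)
    fn <- try(fit_bell(s, "number", open_class_midpoint), silent = TRUE)
    ok_w <- !inherits(fw, "try-error")
    ok_n <- !inherits(fn, "try-error")
    data.frame(
      plot_id = s$plot_id[1],
      TbwA = if (ok_w) fw$params$A else NA_real_,
      TbwB = if (ok_w) fw$params$B else NA_real_,
      TbwMX = if (ok_w) fw$params$MX else NA_real_,
      TbnA = if (ok_n) fn$params$A else NA_real_,
      TbnB = if (ok_n) fn$params$B else NA_real_,
      TbnMX = if (ok_n) fn$params$MX else NA_real_,
      rss_w = if (ok_w) fw$diagnostics$rss else NA_real_,
      rss_n = if (ok_n) fn$diagnostics$rss else NA_real_,
      converged = ok_w && ok_n &&
        fw$diagnostics$converged && fn$diagnostics$converged)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
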