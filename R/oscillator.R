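# ---- model form -----------------------------------------------------------
# Blood glucose after a bolus is modelled as a damped harmonic return to a
# setpoint:
#   G(t) = G0 + A * exp(-alpha * t) * sin(2*pi*t/T + phi),  t in hours.
# This is the minimal form generating the full derived parameter set used in
# tolerance-test phenotyping (setpoint G0, amplitude A, damping alpha, basic
# period T, phase phi).

#' Evaluate the damped-oscillation glucose model
#'
#' \eqn{G(t) = G_0 + A e^{-\alpha t} \sin(2\pi t/T + \phi)} with \code{t} in
#' hours and glucose in mg/dL.
#'
#' @param t time in hours (vector).
#' @param G0 setpoint (asymptote), mg/dL.
#' @param A amplitude, mg/dL.
#' @param alpha damping coefficient, 1/h.
#' @param T_period basic period, h (> 0).
#' @param phi phase, radians.
#' @return Glucose values, mg/dL.
#' @export
osc_eval <- function(t, G0, A, alpha, T_period, phi) {
  if (T_period <= 0) stop("T_period must be > 0")
  G0 + A * exp(-alpha * t) * sin(2 * pi * t / T_period + phi)
}

#' First derivative of the damped-oscillation model
#'
#' \eqn{G'(t) = A e^{-\alpha t} [\omega \cos(\omega t+\phi) - \alpha
#' \sin(\omega t+\phi)]}, \eqn{\omega = 2\pi/T}.
#'
#' @inheritParams osc_eval
#' @return dG/dt in mg/dL/h.
#' @export
osc_deriv <- function(t, G0, A, alpha, T_period, phi) {
  w <- 2 * pi / T_period
  A * exp(-alpha * t) * (w * cos(w * t + phi) - alpha * sin(w * t + phi))
}

#' Closed-form area under the model curve
#'
#' \eqn{\int_0^h G(t)\,dt = G_0 h + A\left[\frac{e^{-\alpha t}(-\alpha
#' \sin(\omega t+\phi) - \omega\cos(\omega t+\phi))}{\alpha^2+\omega^2}
#' \right]_0^h}.
#'
#' @inheritParams osc_eval
#' @param horizon upper limit of integration, h.
#' @return Area in mg/dL * h.
#' @export
osc_auc <- function(G0, A, alpha, T_period, phi, horizon) {
  if (horizon <= 0) stop("horizon must be > 0")
  w <- 2 * pi / T_period
  antider <- function(t) {
    exp(-alpha * t) * (-alpha * sin(w * t + phi) - w * cos(w * t + phi)) /
      (alpha^2 + w^2)
  }
  G0 * horizon + A * (antider(horizon) - antider(0))
}

# ---- series container -----------------------------------------------------

#' Construct a tolerance-test series
#'
#' One glucose time series from a glucose (GTT) or insulin (ITT) tolerance
#' test. Times are stored in hours internally; use [read_tolerance_csv()] to
#' ingest minute-labelled files.
#'
#' @param id subject or group identifier.
#' @param test_kind "GTT" or "ITT".
#' @param week study week of the test.
#' @param time_h sampling times in hours, strictly increasing, first = 0.
#' @param glucose glucose values in mg/dL, all > 0.
#' @return Object of class \code{tolerance_series}.
#' @export
tolerance_series <- function(id, test_kind, week, time_h, glucose) {
  test_kind <- match.arg(test_kind, c("GTT", "ITT"))
  time_h <- as.numeric(time_h); glucose <- as.numeric(glucose)
  if (length(time_h) != length(glucose)) stop("time_h and glucose lengths differ")
  if (length(time_h) < 2L) stop("need at least two points")
  if (time_h[1] != 0) stop("times must start at 0 (fasting value present)")
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(glucose)) || any(glucose <= 0)) {
    stop("glucose values must be finite and > 0")
  }
  structure(
    list(id = id, test_kind = test_kind, week = week,
         time_h = time_h, glucose = glucose),
    class = "tolerance_series"
  )
}

#' @export
print.tolerance_series <- function(x, ...) {
  cat(sprintf("<tolerance_series> %s week %s, id %s: %d points over %.2g h\n",
              x$test_kind, format(x$week), format(x$id),
              length(x$time_h), max(x$time_h)))
  invisible(x)
}

#' Trapezoid area under measured points
#'
#' Composite trapezoid rule over the measured (time, glucose) points, with
#' time in hours, matching the conventional tolerance-test AUC.
#'
#' @param series a [tolerance_series()].
#' @return AUC in mg/dL * h.
#' @export
auc_trapezoid <- function(series) {
  stopifnot(inherits(series, "tolerance_series"))
  t <- series$time_h; g <- series$glucose
  if (length(t) < 2L) stop("need at least two points for a trapezoid AUC")
  sum(diff(t) * (head(g, -1) + tail(g, -1)) / 2)
}

# ---- fitting --------------------------------------------------------------

osc_residuals <- function(par, t, g) {
  g - (par[1] + par[2] * exp(-par[3] * t) * sin(2 * pi * t / par[4] + par[5]))
}

wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  # map the right-open convention [-pi, pi)
  out[out >= pi] <- out[out >= pi] - 2 * pi
  out
}

# Low-level multi-start bounded Levenberg-Marquardt fit on raw (t, g) points.
# Start heuristics: G0 from the tail of the series, A from the range, T from
# four times the time of the extremum with a fallback grid, alpha on a coarse
# log grid, phi solved from the t = 0 residual (both asin branches). The
# objective is multi-modal in (T, phi), hence the breadth of starts.
fit_osc_points <- function(t, g, test_kind = "GTT",
                           alpha_bounds = c(0, 20),
                           T_bounds = c(0.5, 24),
                           extra_T_starts = numeric(0)) {
  n <- length(t)
  if (n < 6L) stop("insufficient points: need at least 6, got ", n)
  if (stats::sd(g) == 0) {
    # degenerate flat series: setpoint fit with no oscillation
    return(list(par = c(G0 = g[1], A = 0, alpha = 0, T_period = 4, phi = 0),
                ssr = 0, converged = TRUE, degenerate = TRUE))
  }
  G0_init <- mean(tail(g, 2))
  A_init <- max((max(g) - min(g)) / 2, 1e-6)
  t_ext <- if (test_kind == "GTT") t[which.max(g)] else t[which.min(g)]
  T_starts <- unique(pmin(pmax(c(4 * t_ext, 2, 3, 4, 6, extra_T_starts),
                               T_bounds[1]), T_bounds[2]))
  alpha_starts <- c(0.3, 1, 3)
  s0 <- asin(min(max((g[1] - G0_init) / A_init, -1), 1))
  phi_starts <- unique(wrap_phase(c(s0, pi - s0)))

  lower <- c(0, 0, alpha_bounds[1], T_bounds[1], -2 * pi)
  upper <- c(Inf, Inf, alpha_bounds[2], T_bounds[2], 2 * pi)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                     ptol = 1e-14, gtol = 0)
  best <- NULL
  for (T0 in T_starts) for (a0 in alpha_starts) for (p0 in phi_starts) {
    start <- c(G0_init, A_init, a0, T0, p0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = osc_residuals, t = t, g = g, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) {
    return(list(par = c(G0 = G0_init, A = A_init, alpha = 1, T_period = 4,
                        phi = 0),
                ssr = Inf, converged = FALSE, degenerate = FALSE))
  }
  # polish the winner once more from its own solution
  fit <- tryCatch(
    minpack.lm::nls.lm(par = best$fit$par, lower = lower, upper = upper,
                       fn = osc_residuals, t = t, g = g, control = ctrl),
    error = function(e) best$fit)
  ssr <- sum(fit$fvec^2)
  if (ssr > best$ssr) { fit <- best$fit; ssr <- best$ssr }
  par <- fit$par
  par[5] <- wrap_phase(par[5])
  names(par) <- c("G0", "A", "alpha", "T_period", "phi")
  list(par = par, ssr = ssr,
       converged = fit$info %in% 1:4 || ssr < 1e-12 * sum((g - mean(g))^2),
       degenerate = FALSE)
}

#' Fit the damped-oscillation model to a tolerance-test series
#'
#' Multi-start bounded nonlinear least squares (Levenberg-Marquardt). The
#' amplitude is constrained non-negative and the phase wrapped to
#' \eqn{[-\pi,\pi)} to remove the (A, phi) sign ambiguity; damping and period
#' are bounded (defaults \code{alpha} in \eqn{[0, 20]} 1/h, \code{T} in
#' \eqn{[0.5, 24]} h).
#'
#' @param series a [tolerance_series()] with at least 6 points.
#' @param alpha_bounds,T_bounds fitting bounds.
#' @return Object of class \code{damped_osc}: the parameter estimates plus
#'   \code{r_squared}, \code{residual_sd} (dof = n - 5), \code{converged} and
#'   \code{degenerate} flags, and the fitted series.
#' @export
fit_damped_oscillator <- function(series, alpha_bounds = c(0, 20),
                                  T_bounds = c(0.5, 24)) {
  stopifnot(inherits(series, "tolerance_series"))
  t <- series$time_h; g <- series$glucose
  res <- fit_osc_points(t, g, series$test_kind, alpha_bounds, T_bounds)
  osc_model_from_fit(res, t, g, series$test_kind, series$id, series$week)
}

osc_model_from_fit <- function(res, t, g, test_kind, id = NA, week = NA) {
  p <- res$par
  fitted <- osc_eval(t, p[["G0"]], p[["A"]], p[["alpha"]], p[["T_period"]],
                     p[["phi"]])
  sst <- sum((g - mean(g))^2)
  n <- length(g)
  r2 <- if (res$degenerate || sst == 0) NA_real_ else 1 - res$ssr / sst
  structure(
    list(id = id, week = week, test_kind = test_kind,
         G0_setpoint = unname(p[["G0"]]), A = unname(p[["A"]]),
         alpha = unname(p[["alpha"]]), T_period = unname(p[["T_period"]]),
         phi = unname(p[["phi"]]),
         r_squared = r2,
         residual_sd = if (n > 5) sqrt(res$ssr / (n - 5)) else NA_real_,
         converged = res$converged, degenerate = res$degenerate,
         n_points = n, fitted = fitted),
    class = "damped_osc"
  )
}

#' @export
print.damped_osc <- function(x, ...) {
  cat(sprintf(
    "<damped_osc> %s fit: G0 = %.1f mg/dL, A = %.1f, alpha = %.3g /h, T = %.3g h, phi = %.3g\n",
    x$test_kind, x$G0_setpoint, x$A, x$alpha, x$T_period, x$phi))
  cat(sprintf("  R^2 = %s, residual SD = %.3g mg/dL, converged = %s\n",
              ifelse(is.na(x$r_squared), "NA (degenerate)",
                     format(x$r_squared, digits = 7)),
              x$residual_sd, x$converged))
  invisible(x)
}

#' Pooled group fit
#'
#' Pools all (time, glucose) points of the supplied series — the group-curve
#' convention for tolerance tests, where one model is fitted to the entire
#' group's measurements — and fits a single damped-oscillation model.
#'
#' @param series_list list of [tolerance_series()] of the same test kind and
#'   sampling grid.
#' @inheritParams fit_damped_oscillator
#' @return A \code{damped_osc} model.
#' @export
fit_group_curve <- function(series_list, alpha_bounds = c(0, 20),
                            T_bounds = c(0.5, 24)) {
  if (!length(series_list)) stop("need at least one series")
  stopifnot(all(vapply(series_list, inherits, TRUE, "tolerance_series")))
  kinds <- unique(vapply(series_list, `[[`, "", "test_kind"))
  if (length(kinds) > 1L) stop("mixed test kinds: ", paste(kinds, collapse = ", "))
  grids <- lapply(series_list, `[[`, "time_h")
  if (length(unique(vapply(grids, paste, "", collapse = ","))) > 1L) {
    stop("all series must share the sampling grid")
  }
  t <- unlist(grids)
  g <- unlist(lapply(series_list, `[[`, "glucose"))
  o <- order(t)
  res <- fit_osc_points(t[o], g[o], kinds, alpha_bounds, T_bounds)
  osc_model_from_fit(res, t[o], g[o], kinds,
                     id = paste0("pooled[", length(series_list), "]"),
                     week = series_list[[1]]$week)
}

# ---- derived parameters ---------------------------------------------------

# locate an extremum of f on [0, horizon]: dense grid then local refinement
refine_extremum <- function(f, horizon, maximum, dt = 1e-3) {
  grid <- seq(0, horizon, by = dt)
  vals <- f(grid)
  i <- if (maximum) which.max(vals) else which.min(vals)
  lo <- max(grid[i] - dt, 0); hi <- min(grid[i] + dt, horizon)
  if (lo == hi) return(list(t = grid[i], value = vals[i]))
  opt <- stats::optimize(f, c(lo, hi), maximum = maximum, tol = 1e-9)
  t_star <- if (maximum) opt$maximum else opt$minimum
  v_star <- opt$objective
  # keep the better of grid point and refinement (guards the boundary case)
  if ((maximum && vals[i] > v_star) || (!maximum && vals[i] < v_star)) {
    list(t = grid[i], value = vals[i])
  } else list(t = t_star, value = v_star)
}

# first local minimum of f after t = 0 (ITT convention); falls back to the
# global minimum when the curve decays monotonically to the setpoint
first_local_min <- function(f, horizon, dt = 1e-3) {
  grid <- seq(0, horizon, by = dt)
  vals <- f(grid)
  n <- length(vals)
  idx <- which(vals[2:(n - 1)] < vals[1:(n - 2)] &
                 vals[2:(n - 1)] <= vals[3:n]) + 1L
  if (!length(idx)) return(refine_extremum(f, horizon, maximum = FALSE, dt))
  i <- idx[1]
  opt <- stats::optimize(f, c(grid[i - 1], grid[i + 1]), tol = 1e-9)
  list(t = opt$minimum, value = opt$objective)
}

#' Derive glycemic parameters from a fitted model
#'
#' Evaluates the fitted damped-oscillation model and locates its extrema to
#' produce the standard tolerance-test parameter set. For a GTT fit:
#' fasting glucose G(0), maximum \code{G_max} at \code{t_max}, 2-h glucose
#' G(2), setpoint, damping, period, initial rate G'(0), the most negative
#' derivative \code{Gprime_I} at \code{t_I} with the glucose level \code{G_I}
#' there, and the closed-form model AUC. For an ITT fit the analogues are the
#' fasting value H(0), the first local minimum \code{H_min} at \code{t_min},
#' the setpoint \code{H0} and initial rate H'(0).
#'
#' Extrema are located on a dense grid (step \code{1e-3} h) followed by local
#' refinement, which handles horizon truncation uniformly.
#'
#' @param model a converged \code{damped_osc} fit.
#' @param horizon evaluation horizon in hours; defaults to 4 for GTT and 3
#'   for ITT (the last sampling time of the respective grid).
#' @return One-row data.frame of derived parameters.
#' @export
derive_parameters <- function(model, horizon = NULL) {
  stopifnot(inherits(model, "damped_osc"))
  if (!isTRUE(model$converged)) stop("model did not converge; refusing to derive parameters")
  if (is.null(horizon)) horizon <- if (model$test_kind == "GTT") 4 else 3
  if (horizon <= 0) stop("horizon must be > 0")
  G <- function(t) osc_eval(t, model$G0_setpoint, model$A, model$alpha,
                            model$T_period, model$phi)
  dG <- function(t) osc_deriv(t, model$G0_setpoint, model$A, model$alpha,
                              model$T_period, model$phi)
  auc <- osc_auc(model$G0_setpoint, model$A, model$alpha, model$T_period,
                 model$phi, horizon)
  base <- data.frame(
    id = model$id, week = model$week, test_kind = model$test_kind,
    G0_setpoint = model$G0_setpoint, alpha = model$alpha,
    T_period = model$T_period, phi = model$phi,
    r_squared = model$r_squared, AUC_model = auc,
    stringsAsFactors = FALSE
  )
  if (model$test_kind == "GTT") {
    mx <- refine_extremum(G, horizon, maximum = TRUE)
    dn <- refine_extremum(dG, horizon, maximum = FALSE)
    cbind(base, data.frame(
      G_fasting = G(0), G_max = mx$value, t_max = mx$t, G_2h = G(2),
      Gprime_0 = dG(0), Gprime_I = dn$value, t_I = dn$t, G_I = G(dn$t)))
  } else {
    mn <- first_local_min(G, horizon)
    cbind(base, data.frame(
      H_fasting = G(0), H_min = mn$value, t_min = mn$t,
      Hprime_0 = dG(0)))
  }
}
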