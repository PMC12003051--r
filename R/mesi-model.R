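# The multi-exposure speckle imaging (MESI) forward model.

# h(u) = (exp(-u) - 1 + u) / u^2, the time-integration kernel of an
# exponentially decorrelating field. Series branch below u = 0.01 avoids the
# catastrophic cancellation of exp(-u) - 1 + u; the two branches agree to
# ~1e-16 relative at the switchover.
.mesi_h <- function(u) {
  out <- u
  small <- u < 0.01
  us <- u[small]
  out[small] <- 1 / 2 - us / 6 + us^2 / 24 - us^3 / 120 + us^4 / 720 -
    us^5 / 5040
  ub <- u[!small]
  out[!small] <- (expm1(-ub) + ub) / ub^2
  out
}

#' MESI model: speckle contrast as a function of exposure time
#'
#' Evaluates
#' \deqn{K(T) = \sqrt{\beta\rho^2 \frac{e^{-2x} - 1 + 2x}{2x^2}
#'   + 4\beta\rho(1-\rho) \frac{e^{-x} - 1 + x}{x^2} + v_{ne} + v_{noise}},}
#' with \eqn{x = T/\tau_c}, the contrast of a time-integrated speckle
#' pattern whose field decorrelates as \eqn{g_1(\tau) = e^{-\tau/\tau_c}}.
#' \eqn{\beta} is the instrumental coherence factor, \eqn{\rho} the dynamic
#' scatterer fraction, and the two v terms are additive variance offsets for
#' nonergodic (static speckle) and measurement-noise contributions.
#'
#' The evaluation is numerically stable from \eqn{x < 10^{-6}} (series
#' expansion; \eqn{K \to \sqrt{\beta}} for \eqn{\rho = 1}, v = 0) to
#' \eqn{x > 10^{3}} (the asymptote \eqn{K^2 \to \beta\rho^2/x}).
#'
#' @param T Exposure time(s) in ms, positive.
#' @param beta Coherence factor (0, 1].
#' @param rho Dynamic-scatterer fraction in \[0, 1\].
#' @param tau_c Decorrelation time in ms, positive.
#' @param v_ne,v_noise Nonergodic and noise variance offsets (>= 0).
#' @return K(T), dimensionless, same length as `T`.
#' @examples
#' mesi_model(0.3, beta = 0.3, rho = 1, tau_c = 0.3)  # x = 1: 0.41268
#' @export
mesi_model <- function(T, beta, rho = 1, tau_c, v_ne = 0, v_noise = 0) {
  if (any(T <= 0)) stop_user("`T` must be positive")
  if (!is_scalar_number(tau_c) || tau_c <= 0)
    stop_user("`tau_c` must be positive")
  if (rho < 0 || rho > 1) stop_user("`rho` must lie in [0, 1]")
  x <- T / tau_c
  k2 <- 2 * beta * rho^2 * .mesi_h(2 * x) +
    4 * beta * rho * (1 - rho) * .mesi_h(x) + v_ne + v_noise
  sqrt(pmax(k2, 0))
}

#' Default MESI parameter bounds
#'
#' Physical box bounds used by [fit_mesi()]. In `"simulation"` mode (noise
#' free, fully dynamic field) beta may take any physical value up to its
#' theoretical maximum of 1, since the simulated coherence factor is set
#' purely by the spatial speckle sampling. In `"in_vivo"` mode beta is
#' restricted to (0.05, 0.5), the instrument-typical range for experimental
#' MESI systems.
#'
#' @param mode `"simulation"` or `"in_vivo"`.
#' @return List with named numeric vectors `lower` and `upper` over
#'   `beta, rho, tau_c, v_ne, v_noise` (tau_c in ms).
#' @export
mesi_bounds <- function(mode = c("simulation", "in_vivo")) {
  mode <- match.arg(mode)
  beta_hi <- if (mode == "simulation") 1 else 0.5
  list(lower = c(beta = 0.05, rho = 0.1, tau_c = 1e-4, v_ne = 0, v_noise = 0),
       upper = c(beta = beta_hi, rho = 1, tau_c = 10, v_ne = 0.3,
                 v_noise = 0.3))
}

#' Fit the MESI model to Ks(T) data by bounded nonlinear least squares
#'
#' Minimizes the sum of squared residuals in K (the measured observable, not
#' K^2) with the Levenberg-Marquardt algorithm under box bounds, restarting
#' from `n_starts` log-spaced initial tau_c values (the objective has shallow
#' valleys in the beta-tau_c plane). The result is deterministic given the
#' data, bounds and start grid.
#'
#' @param T Exposure times in ms, distinct and positive.
#' @param Ks Measured mean speckle contrast at each exposure.
#' @param fixed Named numeric vector of parameters to hold fixed, e.g.
#'   `c(rho = 1, v_ne = 0, v_noise = 0)` (the noise-free simulation mode,
#'   also the default).
#' @param bounds Box bounds as returned by [mesi_bounds()].
#' @param n_starts Number of log-spaced tau_c starting values in
#'   \[0.01, 10\] ms.
#' @return An object of class `"mesi_fit"`: fitted `parameters` (all five),
#'   `residual_rms`, `n_points`, `fixed_mask`, `bounds`,
#'   `non_identifiable` flag, and the data.
#' @examples
#' T <- mesi_exposures("simulation")
#' fit <- fit_mesi(T, mesi_model(T, beta = 0.3, tau_c = 0.5))
#' fit$parameters[["tau_c"]]
#' @export
fit_mesi <- function(T, Ks, fixed = c(rho = 1, v_ne = 0, v_noise = 0),
                     bounds = mesi_bounds("simulation"), n_starts = 8L) {
  if (length(T) != length(Ks)) stop_user("`T` and `Ks` lengths differ")
  if (any(T <= 0) || anyDuplicated(T))
    stop_user("`T` values must be distinct and positive")
  par_names <- c("beta", "rho", "tau_c", "v_ne", "v_noise")
  if (length(fixed) && (is.null(names(fixed)) ||
                        !all(names(fixed) %in% par_names)))
    stop_user("`fixed` must be named among: ", paste(par_names, collapse = ", "))
  free <- setdiff(par_names, names(fixed))
  if (length(free) == 0L) stop_user("at least one parameter must be free")
  if (length(T) < max(2L, length(free)))
    stop_user("need at least max(2, number of free parameters) points")
  non_identifiable <- stats::sd(Ks) == 0

  model_k <- function(p) {
    full <- c(p, fixed)[par_names]
    mesi_model(T, beta = full[["beta"]], rho = full[["rho"]],
               tau_c = full[["tau_c"]], v_ne = full[["v_ne"]],
               v_noise = full[["v_noise"]])
  }
  lower <- bounds$lower[free]
  upper <- bounds$upper[free]
  init_base <- c(beta = 0.25, rho = 0.9, tau_c = 1, v_ne = 0.01,
                 v_noise = 0.01)
  tau_grid <- if ("tau_c" %in% free)
    exp(seq(log(0.01), log(10), length.out = n_starts)) else NA_real_

  best <- NULL
  for (t0 in tau_grid) {
    p0 <- init_base[free]
    if (!is.na(t0) && "tau_c" %in% free) p0[["tau_c"]] <- t0
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- try(minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper,
      fn = function(p) model_k(p) - Ks,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop_user("MESI fit failed from every starting point")

  pars <- c(stats::setNames(as.numeric(best$par), free), fixed)[par_names]
  structure(list(
    parameters = pars,
    residual_rms = sqrt(best$deviance / length(T)),
    n_points = length(T),
    fixed_mask = stats::setNames(par_names %in% names(fixed), par_names),
    bounds = bounds,
    non_identifiable = non_identifiable,
    deviance = best$deviance,
    data = tibble::tibble(T_ms = T, Ks = Ks,
                          fitted = model_k(best$par))),
    class = "mesi_fit")
}

#' @export
print.mesi_fit <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "<mesi_fit> tau_c=%.4g ms, beta=%.3g, rho=%.3g, v_ne=%.3g, v_noise=%.3g\n",
    p[["tau_c"]], p[["beta"]], p[["rho"]], p[["v_ne"]], p[["v_noise"]]))
  fixed <- names(p)[x$fixed_mask]
  if (length(fixed)) cat("  fixed:", paste(fixed, collapse = ", "), "\n")
  cat(sprintf("  residual rms %.3g over %d exposures%s\n", x$residual_rms,
              x$n_points,
              if (x$non_identifiable) " [non-identifiable: constant Ks]" else ""))
  invisible(x)
}
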