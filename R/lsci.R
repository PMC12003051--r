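# Single-exposure (LSCI) asymptotic estimators.

#' Blood flow index from a single-exposure contrast
#'
#' The asymptotic blood flow index `BFI = 1/(T * Ks^2)`, valid when
#' `T/tau_c > 100`. `Ks = 0` yields `NA` (undefined, no division).
#'
#' @param Ks Speckle contrast value(s), > 0.
#' @param T Exposure time(s) in ms.
#' @return BFI in 1/ms, same length as the inputs.
#' @export
bfi <- function(Ks, T) {
  if (any(T <= 0)) stop_user("`T` must be positive")
  out <- 1 / (T * Ks^2)
  out[Ks == 0] <- NA_real_
  out
}

#' Decorrelation time via the LSCI asymptotic approximation
#'
#' Inverts the large-`T/tau_c` limit `Ks^2 = beta * tau_c / T` to
#' `tau_c = T * Ks^2 / beta`. The estimate is flagged unreliable whenever
#' the validity condition `T / tau_c_est >= 100` fails; by construction the
#' estimate improves as `T/tau_c` grows.
#'
#' @param Ks Speckle contrast value(s), > 0.
#' @param T Exposure time(s) in ms.
#' @param beta Coherence factor used for normalization (for example, the
#'   beta fitted by [fit_mesi()] on the same data).
#' @return A [tibble::tibble] with columns `T_ms`, `tau_c_ms`, `bfi` and
#'   `reliable`.
#' @examples
#' lsci_asymptotic_tau(Ks = sqrt(0.3 * 0.1 / 60), T = 60, beta = 0.3)
#' @export
lsci_asymptotic_tau <- function(Ks, T, beta) {
  if (any(T <= 0)) stop_user("`T` must be positive")
  if (!is_scalar_number(beta) || beta <= 0) stop_user("`beta` must be > 0")
  tau <- T * Ks^2 / beta
  tau[Ks == 0] <- NA_real_
  tibble::tibble(T_ms = T, tau_c_ms = tau, bfi = bfi(Ks, T),
                 reliable = !is.na(tau) & (T / tau >= 100))
}
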