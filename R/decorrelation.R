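#' Temporal field decorrelation specification
#'
#' Describes the normalized field autocorrelation function g1(tau) of the
#' dynamic speckle field. The negative-exponential form,
#' g1(tau) = exp(-tau/tau_c), corresponds to multiple photon scattering in
#' ordered flow and is the regime relevant for arterioles in the rodent brain;
#' the Gaussian form exp(-(tau/tau_c)^2) corresponds to single scattering in
#' ordered flow and the square-root exponential exp(-sqrt(tau/tau_c)) to
#' multiple scattering in unordered (Brownian) motion.
#'
#' `tau_c = Inf` is the static-field limit (g1 identically 1): every frame of
#' a generated sequence is the same frozen speckle pattern.
#'
#' @param form One of `"neg_exponential"`, `"gaussian"`, `"sqrt_exponential"`.
#' @param tau_c Decorrelation time in ms; strictly positive (may be `Inf`).
#' @return An object of class `"decorrelation_spec"`.
#' @examples
#' dc <- decorrelation_spec("neg_exponential", tau_c = 0.1)
#' g1_value(dc, c(0, 0.1, 1))
#' @export
decorrelation_spec <- function(form = c("neg_exponential", "gaussian",
                                        "sqrt_exponential"),
                               tau_c) {
  form <- match.arg(form)
  if (!is.numeric(tau_c) || length(tau_c) != 1L || is.na(tau_c) || tau_c <= 0)
    stop_user("`tau_c` must be a single positive number (ms)")
  structure(list(form = form, tau_c = as.double(tau_c)),
            class = "decorrelation_spec")
}

#' Evaluate the field autocorrelation g1 at given lags
#'
#' @param spec A [decorrelation_spec()].
#' @param tau Non-negative lag(s) in ms.
#' @return Numeric vector of g1 values; g1(0) = 1 and g1 is non-increasing.
#' @export
g1_value <- function(spec, tau) {
  stopifnot(inherits(spec, "decorrelation_spec"))
  if (any(tau < 0)) stop_user("lags must be non-negative")
  if (!is.finite(spec$tau_c)) return(rep(1, length(tau)))
  u <- tau / spec$tau_c
  switch(spec$form,
    neg_exponential  = exp(-u),
    gaussian         = exp(-u^2),
    sqrt_exponential = exp(-sqrt(u)))
}

#' @export
print.decorrelation_spec <- function(x, ...) {
  cat(sprintf("<decorrelation_spec> form=%s tau_c=%g ms\n", x$form, x$tau_c))
  invisible(x)
}
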