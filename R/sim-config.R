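#' Standard MESI exposure-time ladders
#'
#' `"simulation"` returns the 15-exposure ladder from 0.05 to 60 ms used for
#' the noise-free simulation study; `"in_vivo"` the 6-exposure cycle
#' (1 to 20 ms) typical of in vivo MESI acquisition.
#'
#' @param set Which ladder to return.
#' @return Numeric vector of exposure times in ms, ascending.
#' @export
mesi_exposures <- function(set = c("simulation", "in_vivo")) {
  set <- match.arg(set)
  switch(set,
    simulation = c(0.05, 0.1, 0.2, 0.5, 0.8, 1, 2, 3.5, 5, 10, 15, 20, 30,
                   40, 60),
    in_vivo    = c(1, 2, 5, 10, 15, 20))
}

#' Configuration of a dynamic speckle simulation
#'
#' Collects every knob of the synthetic-data generator. Defaults describe the
#' noise-free study conditions: negative-exponential field decorrelation,
#' 3 pixels per speckle (better than the Shannon-Nyquist minimum of 2), the
#' 15-exposure MESI ladder, 12-bit quantization with the frame mean placed at
#' a quarter of full scale, and sub-frame integration step dt = tau_c/20.
#'
#' @param image_shape Integer vector `c(rows, cols)` of the simulated frames.
#' @param px_per_speckle Speckle grain size in pixels (grid size over pupil
#'   diameter); must be >= 2 so the speckle is not aliased.
#' @param exposure_times Exposure times T in ms, strictly positive, ascending.
#' @param decorrelation A [decorrelation_spec()].
#' @param bit_depth Bit depth used by [quantize_frame()] (e.g. 12).
#' @param mean_fill_fraction Fraction of the quantizer's dynamic range at
#'   which the frame mean is placed, in (0, 1).
#' @param dt_rule Sub-frame step as a fraction of `tau_c` (default 1/20,
#'   keeping the time-integration error of K(T) below the percent level).
#' @param max_subframes Safety cap on sub-frames per exposure; exceeding it is
#'   an error (resource exhaustion is signalled, never silently subsampled).
#' @param seed Master seed; all per-exposure streams derive from it.
#' @return An object of class `"simulation_config"`.
#' @examples
#' cfg <- simulation_config(image_shape = c(64, 64),
#'                          decorrelation = decorrelation_spec("neg_exponential", 1),
#'                          exposure_times = c(1, 5, 20), seed = 1)
#' @export
simulation_config <- function(image_shape = c(256, 256),
                              px_per_speckle = 3,
                              exposure_times = mesi_exposures("simulation"),
                              decorrelation,
                              bit_depth = 12,
                              mean_fill_fraction = 0.25,
                              dt_rule = 1 / 20,
                              max_subframes = 20000,
                              seed = 1L) {
  if (length(image_shape) != 2L || any(image_shape < 8))
    stop_user("`image_shape` must be c(rows, cols) with both >= 8")
  if (!is_scalar_number(px_per_speckle) || px_per_speckle < 2)
    stop_user("`px_per_speckle` must be >= 2: fewer than 2 pixels per speckle ",
              "aliases the speckle grains (Shannon-Nyquist)")
  if (!is.numeric(exposure_times) || length(exposure_times) < 1L ||
      any(exposure_times <= 0) || is.unsorted(exposure_times, strictly = TRUE))
    stop_user("`exposure_times` must be strictly positive and ascending")
  if (!inherits(decorrelation, "decorrelation_spec"))
    stop_user("`decorrelation` must be a decorrelation_spec()")
  if (!is_scalar_number(mean_fill_fraction) ||
      mean_fill_fraction <= 0 || mean_fill_fraction >= 1)
    stop_user("`mean_fill_fraction` must lie in (0, 1)")
  if (!is_scalar_number(bit_depth) || bit_depth < 1 || bit_depth > 16)
    stop_user("`bit_depth` must be in 1..16")
  if (!is_scalar_number(dt_rule) || dt_rule <= 0 || dt_rule > 1)
    stop_user("`dt_rule` must be in (0, 1]")
  structure(list(
    image_shape        = as.integer(image_shape),
    px_per_speckle     = as.double(px_per_speckle),
    exposure_times     = as.double(exposure_times),
    decorrelation      = decorrelation,
    bit_depth          = as.integer(bit_depth),
    mean_fill_fraction = as.double(mean_fill_fraction),
    dt_rule            = as.double(dt_rule),
    max_subframes      = as.integer(max_subframes),
    seed               = as.integer(seed)),
    class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %dx%d px, %.3g px/speckle, %d exposures (%g..%g ms)\n",
    x$image_shape[1], x$image_shape[2], x$px_per_speckle,
    length(x$exposure_times), min(x$exposure_times), max(x$exposure_times)))
  cat(sprintf("  g1: %s, tau_c=%g ms | %d-bit, fill=%.2f, dt=tau_c*%.3g, seed=%d\n",
              x$decorrelation$form, x$decorrelation$tau_c, x$bit_depth,
              x$mean_fill_fraction, x$dt_rule, x$seed))
  invisible(x)
}
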