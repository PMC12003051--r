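# Dynamic speckle synthesis.
#
# A fully developed, polarized speckle field is drawn as a complex circular
# Gaussian random field whose spatial-frequency support is a circular pupil;
# the pupil radius sets the speckle grain size (grid size / pupil diameter =
# pixels per speckle, so the frequency cutoff is 1/(2*px_per_speckle)
# cycles/px and a ratio >= 2 keeps the field below Nyquist). Temporal
# decorrelation is imposed by an autoregressive update on the pupil-plane
# field: the per-step coefficient is chosen so that the correlation between
# any frame and the start of the sequence is exactly g1(t). For the
# negative-exponential form the update is stationary and every pairwise lag
# obeys g1 exactly; for the other forms pairwise correlations are
# approximated by the ratio g1(t2)/g1(t1).

# Pupil support in the discrete frequency plane.
pupil_mask <- function(shape, px_per_speckle) {
  freq_axis <- function(n) {
    half <- floor(n / 2)
    c(0:half, if (n > 1) -(n - half - 1):-1) / n
  }
  fr <- freq_axis(shape[1])
  fc <- freq_axis(shape[2])
  cutoff <- 1 / (2 * px_per_speckle)
  outer(fr^2, fc^2, "+") <= cutoff^2
}

# Stateful field evolver. Returns a function(step_index) yielding the next
# intensity frame; step k corresponds to time k*dt from the sequence start.
.field_stepper <- function(config, dt) {
  shape <- config$image_shape
  mask <- pupil_mask(shape, config$px_per_speckle)
  idx <- which(mask)
  npup <- length(idx)
  dc <- config$decorrelation
  Fplane <- matrix(0 + 0i, shape[1], shape[2])
  pupil <- complex(real = stats::rnorm(npup),
                   imaginary = stats::rnorm(npup)) / sqrt(2)
  t_prev <- 0
  first <- TRUE
  function() {
    if (!first) {
      t_now <- t_prev + dt
      a <- if (!is.finite(dc$tau_c)) 1 else {
        g_prev <- g1_value(dc, t_prev)
        if (g_prev <= 0) 0 else min(1, g1_value(dc, t_now) / g_prev)
      }
      innov <- complex(real = stats::rnorm(npup),
                       imaginary = stats::rnorm(npup)) / sqrt(2)
      pupil <<- a * pupil + sqrt(1 - a^2) * innov
      t_prev <<- t_now
    }
    first <<- FALSE
    Fplane[idx] <- pupil
    E <- stats::fft(Fplane, inverse = TRUE)
    Re(E)^2 + Im(E)^2
  }
}

# Sub-frame step for a config: dt = tau_c * dt_rule (finite tau_c required).
.sim_dt <- function(config, dt = NULL) {
  if (!is.null(dt)) {
    if (!is_scalar_number(dt) || dt <= 0) stop_user("`dt` must be positive")
    return(dt)
  }
  tau_c <- config$decorrelation$tau_c
  if (!is.finite(tau_c))
    stop_user("static field (tau_c = Inf): supply `dt` explicitly")
  tau_c * config$dt_rule
}

#' Generate a sequence of raw (un-integrated) speckle frames
#'
#' Produces fully developed speckle frames at a sub-frame time step `dt`.
#' Each frame's per-pixel intensity is exponentially distributed (global
#' contrast sd/mean = 1), the spatial autocorrelation width is set by
#' `px_per_speckle`, and the temporal field correlation follows the
#' configured g1, so the intensity autocorrelation obeys the Siegert
#' relation g2(tau) - 1 = |g1(tau)|^2.
#'
#' @param config A [simulation_config()].
#' @param duration Total duration in ms; `ceiling(duration/dt)` frames are
#'   produced.
#' @param dt Optional explicit sub-frame step (ms); defaults to
#'   `tau_c * dt_rule`. Required when `tau_c = Inf` (static field).
#' @return A [speckle_stack()] of raw frames; `exposure_times` records the
#'   step `dt` actually used.
#' @examples
#' cfg <- simulation_config(image_shape = c(32, 32),
#'   decorrelation = decorrelation_spec("neg_exponential", 1),
#'   exposure_times = 1, seed = 7)
#' raw <- generate_field_sequence(cfg, duration = 0.25)
#' n_frames(raw)
#' @export
generate_field_sequence <- function(config, duration, dt = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  dt <- .sim_dt(config, dt)
  if (!is_scalar_number(duration) || duration < dt)
    stop_user("`duration` must be >= dt")
  n <- ceiling(duration / dt)
  if (n > config$max_subframes)
    stop_user(sprintf(
      "duration %g ms at dt %g ms needs %d frames, above the cap of %d; ",
      duration, dt, n, config$max_subframes),
      "raise `max_subframes` or coarsen `dt_rule`")
  frames <- array(0, c(config$image_shape, n))
  with_seed(config$seed, {
    step <- .field_stepper(config, dt)
    for (k in seq_len(n)) frames[, , k] <- step()
  })
  speckle_stack(frames, exposure_times = dt, quantized = FALSE,
                provenance = sprintf(
                  "raw field sequence: g1=%s tau_c=%g ms, dt=%g ms, seed=%d",
                  config$decorrelation$form, config$decorrelation$tau_c, dt,
                  config$seed))
}

#' Integrate one exposure into a single time-averaged frame
#'
#' Averages `n = ceiling(T/dt)` consecutive correlated raw frames (the step
#' is refined to `dt = T/n` so the integration window is exactly `T`). The
#' mean spatial contrast of the result decreases with `T` and follows the
#' multi-exposure model K(T) for the configured g1.
#'
#' @param config A [simulation_config()].
#' @param T Exposure time in ms.
#' @param seed Seed for this exposure's random stream (default: derived from
#'   the config's master seed).
#' @return A numeric matrix of time-integrated intensities (mean of the
#'   sub-frames; not quantized). Attribute `"n_subframes"` records n.
#' @export
integrate_exposure <- function(config, T, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is_scalar_number(T) || T <= 0) stop_user("`T` must be positive (ms)")
  dt <- .sim_dt(config)
  n <- max(1L, as.integer(ceiling(T / dt)))
  if (n > config$max_subframes)
    stop_user(sprintf(
      "exposure %g ms at dt %g ms needs %d sub-frames, above the cap of %d",
      T, dt, n, config$max_subframes))
  dt_eff <- T / n
  seed <- seed %||% derive_seed(config$seed, 1L)
  acc <- NULL
  with_seed(seed, {
    step <- .field_stepper(config, dt_eff)
    acc <- step()
    if (n > 1L) for (k in 2:n) acc <- acc + step()
  })
  out <- acc / n
  attr(out, "n_subframes") <- n
  out
}

#' Quantize an intensity frame to integer gray levels
#'
#' Linearly rescales the frame so its mean sits at `mean_fill_fraction` of
#' full scale, clips at `2^bit_depth - 1` and rounds to the nearest integer.
#'
#' @param frame Non-negative numeric matrix.
#' @param bit_depth Target bit depth (12 gives a maximum level of 4095).
#' @param mean_fill_fraction Where the mean lands within the dynamic range.
#' @return Integer-valued matrix with attribute `"saturated_fraction"`, the
#'   fraction of clipped pixels.
#' @examples
#' q <- quantize_frame(matrix(1, 4, 4), bit_depth = 12,
#'                     mean_fill_fraction = 0.25)
#' q[1, 1]  # 1024
#' @export
quantize_frame <- function(frame, bit_depth = 12, mean_fill_fraction = 0.25) {
  if (any(frame < 0)) stop_user("`frame` must be non-negative")
  mu <- mean(frame)
  if (mu == 0) stop_user("all-zero frame cannot be scaled for quantization")
  full <- 2^bit_depth - 1
  scaled <- frame * (mean_fill_fraction * full / mu)
  sat <- mean(scaled > full)
  out <- round(pmin(scaled, full))
  attr(out, "saturated_fraction") <- sat
  out
}

#' Simulate one time-integrated frame per configured exposure
#'
#' The study-condition generator: for each exposure time of the config it
#' integrates an independent field sequence (seed derived deterministically
#' from the master seed) and, optionally, quantizes the result to the
#' configured bit depth.
#'
#' @param config A [simulation_config()].
#' @param quantize Quantize each integrated frame (default `TRUE`, matching
#'   camera-like integer data).
#' @return A [speckle_stack()] with one frame per exposure time.
#' @export
simulate_mesi_stack <- function(config, quantize = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  Ts <- config$exposure_times
  frames <- array(0, c(config$image_shape, length(Ts)))
  for (i in seq_along(Ts)) {
    fr <- integrate_exposure(config, Ts[i], seed = derive_seed(config$seed, i))
    if (quantize)
      fr <- quantize_frame(fr, config$bit_depth, config$mean_fill_fraction)
    frames[, , i] <- fr
  }
  speckle_stack(frames, exposure_times = Ts, quantized = quantize,
                bit_depth = config$bit_depth,
                provenance = sprintf(
                  "simulated MESI stack: g1=%s tau_c=%g ms, %g px/speckle, seed=%d",
                  config$decorrelation$form, config$decorrelation$tau_c,
                  config$px_per_speckle, config$seed))
}
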