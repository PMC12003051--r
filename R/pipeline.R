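# Orchestration of the implementation-comparison study.

#' Run the simulated implementation-comparison study
#'
#' For each configured exposure time, simulates a time-integrated speckle
#' frame, computes the cropped contrast map of every requested kernel
#' variant, and records the spatial mean Ks and its relative error against
#' the direct reference of the same window size and divisor. Each variant's
#' mean Ks(T) is then fitted with the MESI model (noise-free mode: rho = 1,
#' v terms 0, beta and tau_c free), and a per-exposure asymptotic tau_c is
#' derived using that variant's own fitted beta.
#'
#' The reference is the direct square kernel of matching size; by default it
#' is evaluated with the sums engine, which is identical to the nested-loop
#' reference on the cropped region to within 1e-9 but orders of magnitude
#' faster (set `reference_engine = "direct"` for the literal loop).
#'
#' @param config A [simulation_config()] (needs >= 2 exposures for fitting).
#' @param variants List of [kernel_spec()]s to compare.
#' @param quantize Quantize simulated frames before contrast computation
#'   (default `TRUE`, the camera-like study condition).
#' @param reference_engine `"sums"` (default) or `"direct"`.
#' @return An object of class `"speckle_comparison"`: a long-format `table`
#'   ([tibble::tibble] with columns `engine`, `shape`, `size`, `padding`,
#'   `divisor`, `T_ms`, `mean_Ks`, `rel_err_pct`, `lsci_tau_ms`,
#'   `mesi_tau_ms`), per-variant `fits`, and the `config`.
#' @export
run_simulated_comparison <- function(config, variants, quantize = TRUE,
                                     reference_engine = c("sums", "direct")) {
  stopifnot(inherits(config, "simulation_config"))
  reference_engine <- match.arg(reference_engine)
  if (!is.list(variants) || length(variants) == 0L)
    stop_user("`variants` must be a non-empty list of kernel_spec()s")
  if (!all(vapply(variants, inherits, logical(1), "kernel_spec")))
    stop_user("every variant must be a kernel_spec()")
  Ts <- config$exposure_times
  if (length(Ts) < 2L) stop_user("need >= 2 exposures for MESI fitting")

  labels <- vapply(variants, kernel_label, character(1))
  mean_ks <- matrix(NA_real_, length(Ts), length(variants),
                    dimnames = list(NULL, labels))
  rel_err <- mean_ks

  ref_key <- function(k) sprintf("s%d_%s", k$size, k$divisor)
  for (i in seq_along(Ts)) {
    frame <- integrate_exposure(config, Ts[i],
                                seed = derive_seed(config$seed, i))
    if (quantize)
      frame <- quantize_frame(frame, config$bit_depth,
                              config$mean_fill_fraction)
    ref_means <- list()
    for (v in seq_along(variants)) {
      kv <- variants[[v]]
      cm <- crop_edges(contrast_variant(frame, kv, exposure_time = Ts[i]))
      mean_ks[i, v] <- mean(cm$values, na.rm = TRUE)
      key <- ref_key(kv)
      if (is.null(ref_means[[key]])) {
        ref_kernel <- kernel_spec(
          "square", kv$size, padding = "none_crop", divisor = kv$divisor,
          engine = if (reference_engine == "direct") "direct" else
            "sums_uniform")
        # none_crop + sums equals the direct loop exactly on the interior
        ref_cm <- if (reference_engine == "direct")
          contrast_direct(frame, ref_kernel, Ts[i])
        else contrast_sums(frame, ref_kernel, Ts[i])
        ref_means[[key]] <- mean_contrast(ref_cm)
      }
      rel_err[i, v] <- 100 * (mean_ks[i, v] - ref_means[[key]]) /
        ref_means[[key]]
    }
  }

  fits <- vector("list", length(variants))
  names(fits) <- labels
  rows <- vector("list", length(variants))
  for (v in seq_along(variants)) {
    kv <- variants[[v]]
    fit <- fit_mesi(Ts, mean_ks[, v],
                    fixed = c(rho = 1, v_ne = 0, v_noise = 0),
                    bounds = mesi_bounds("simulation"))
    fits[[v]] <- fit
    lsci <- lsci_asymptotic_tau(mean_ks[, v], Ts,
                                beta = fit$parameters[["beta"]])
    rows[[v]] <- tibble::tibble(
      engine = kv$engine, shape = kv$shape, size = kv$size,
      padding = kv$padding, divisor = kv$divisor, T_ms = Ts,
      mean_Ks = mean_ks[, v], rel_err_pct = rel_err[, v],
      lsci_tau_ms = lsci$tau_c_ms,
      mesi_tau_ms = fit$parameters[["tau_c"]])
  }
  structure(list(table = do.call(rbind, rows), fits = fits, config = config,
                 reference_engine = reference_engine),
            class = "speckle_comparison")
}

#' @export
print.speckle_comparison <- function(x, ...) {
  cat(sprintf("<speckle_comparison> %d variant(s) x %d exposure(s)\n",
              length(x$fits), length(x$config$exposure_times)))
  taus <- vapply(x$fits, function(f) f$parameters[["tau_c"]], numeric(1))
  for (nm in names(taus))
    cat(sprintf("  %-22s MESI tau_c = %.4g ms\n", nm, taus[[nm]]))
  invisible(x)
}

#' Average exposure-cycled contrast maps into one mean map per exposure
#'
#' MESI acquisitions cycle through a fixed ladder of exposure times;
#' contrast is computed frame by frame first, and then the maps belonging to
#' the same position in the repeating cycle are averaged (contrast-then-
#' average order, never the reverse).
#'
#' @param maps List of [contrast_map()]s in acquisition order; the frame
#'   count must be an exact multiple of the cycle length.
#' @param exposure_cycle Ordered exposure times (ms) of one cycle.
#' @return List of [contrast_map()]s, one per cycle position, in cycle
#'   order; each carries its exposure time.
#' @export
average_mesi_sequences <- function(maps, exposure_cycle) {
  if (!is.list(maps) || !all(vapply(maps, inherits, logical(1), "contrast_map")))
    stop_user("`maps` must be a list of contrast_map()s")
  L <- length(exposure_cycle)
  n <- length(maps)
  if (L < 1L) stop_user("`exposure_cycle` must be non-empty")
  if (n %% L != 0L)
    stop_user(sprintf(
      "%d frames do not divide into cycles of %d (remainder %d)", n, L,
      n %% L))
  lapply(seq_len(L), function(pos) {
    members <- maps[seq(pos, n, by = L)]
    vals <- Reduce(`+`, lapply(members, `[[`, "values")) / length(members)
    proto <- members[[1]]
    contrast_map(vals, exposure_cycle[pos], proto$kernel, proto$valid_margin)
  })
}

#' Mean contrast per region of interest and exposure
#'
#' Averages the defined Ks values inside each ROI mask for every exposure's
#' map. The resulting per-ROI Ks(T) series feed [fit_mesi()] (for in vivo
#' data: rho, tau_c, beta and v_noise free within bounds, v_ne pooled into
#' v_noise).
#'
#' @param maps List of [contrast_map()]s, one per exposure.
#' @param rois Named list of logical matrices matching the map dimensions;
#'   each mask must be non-empty.
#' @return A [tibble::tibble] with columns `roi`, `T_ms`, `mean_Ks`.
#' @export
roi_mean_contrast <- function(maps, rois) {
  if (!is.list(maps) || !all(vapply(maps, inherits, logical(1), "contrast_map")))
    stop_user("`maps` must be a list of contrast_map()s")
  if (!is.list(rois) || is.null(names(rois)) || any(!nzchar(names(rois))))
    stop_user("`rois` must be a named list of logical masks")
  dm <- dim(maps[[1]]$values)
  rows <- list()
  for (nm in names(rois)) {
    mask <- rois[[nm]]
    if (!is.logical(mask) || !identical(dim(mask), dm))
      stop_user(sprintf("ROI '%s' does not match the map dimensions", nm))
    if (!any(mask)) stop_user(sprintf("ROI '%s' is empty", nm))
    for (mp in maps) {
      vals <- mp$values[mask]
      if (all(is.na(vals)))
        stop_user(sprintf(
          "ROI '%s' falls entirely in the undefined margin at T=%g ms", nm,
          mp$exposure_time))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        roi = nm, T_ms = mp$exposure_time, mean_Ks = mean(vals, na.rm = TRUE))
    }
  }
  do.call(rbind, rows)
}

#' Fit the MESI model per ROI
#'
#' Convenience wrapper running [fit_mesi()] on each ROI's Ks(T) series from
#' [roi_mean_contrast()].
#'
#' @param roi_series Tibble with columns `roi`, `T_ms`, `mean_Ks`.
#' @param fixed,bounds Passed to [fit_mesi()]; defaults are the experimental
#'   mode (v_ne pooled into v_noise, instrument beta bounds).
#' @return Named list of `"mesi_fit"` objects, one per ROI.
#' @export
fit_mesi_rois <- function(roi_series, fixed = c(v_ne = 0),
                          bounds = mesi_bounds("in_vivo")) {
  stopifnot(all(c("roi", "T_ms", "mean_Ks") %in% names(roi_series)))
  rois <- unique(roi_series$roi)
  fits <- lapply(rois, function(r) {
    d <- roi_series[roi_series$roi == r, ]
    fit_mesi(d$T_ms, d$mean_Ks, fixed = fixed, bounds = bounds)
  })
  stats::setNames(fits, rois)
}
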