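# Spatial speckle contrast Ks = sd/mean over sliding windows.
#
# All accumulation is in double precision regardless of input type: squared
# 12-bit values overflow 32-bit accumulators on large kernels.

# --- contrast_map container ------------------------------------------------

#' Construct a contrast map
#'
#' Holds a 2D image of Ks values together with the kernel that produced it
#' and the width of the border region that is not covered by full windows.
#' Undefined windows (outside the valid region, or with zero mean) are `NA`,
#' never infinite.
#'
#' @param values Numeric matrix of Ks values (NA where undefined).
#' @param exposure_time Exposure time in ms of the underlying frame.
#' @param kernel The [kernel_spec()] used.
#' @param valid_margin Pixels per side affected by the border (equal to
#'   `floor(size/2)`; 0 after cropping).
#' @param n_clamped Number of windows whose variance was clamped to zero
#'   because floating-point cancellation made it negative.
#' @return An object of class `"contrast_map"`.
#' @export
contrast_map <- function(values, exposure_time, kernel, valid_margin,
                         n_clamped = 0L) {
  stopifnot(is.matrix(values), inherits(kernel, "kernel_spec"))
  if (any(values < 0, na.rm = TRUE))
    stop_user("contrast values must be >= 0 or NA")
  structure(list(values = values,
                 exposure_time = as.double(exposure_time),
                 kernel = kernel,
                 valid_margin = as.integer(valid_margin),
                 n_clamped = as.integer(n_clamped)),
            class = "contrast_map")
}

#' @export
print.contrast_map <- function(x, ...) {
  cat(sprintf("<contrast_map> %dx%d px, T=%g ms, margin=%d px [%s]\n",
              nrow(x$values), ncol(x$values), x$exposure_time, x$valid_margin,
              kernel_label(x$kernel)))
  cat(sprintf("  mean Ks (valid region): %.5g\n", mean_contrast(x)))
  invisible(x)
}

# --- padding ---------------------------------------------------------------

# Index-based border padding. "reflect" duplicates the edge pixel
# (c b a | a b c), "symmetric" mirrors without duplicating it (c b | a b c),
# "constant_zero" pads zeros.
pad_image <- function(image, margin, mode) {
  if (margin == 0L) return(image)
  n <- nrow(image); p <- ncol(image)
  if (mode == "constant_zero") {
    out <- matrix(0, n + 2L * margin, p + 2L * margin)
    out[margin + seq_len(n), margin + seq_len(p)] <- image
    return(out)
  }
  mirror_idx <- function(len, dup) {
    if (dup) c(margin:1, 1:len, len:(len - margin + 1L))
    else c((margin + 1L):2, 1:len, (len - 1L):(len - margin))
  }
  dup <- (mode == "reflect")
  image[mirror_idx(n, dup), mirror_idx(p, dup)]
}

# --- local window sums -----------------------------------------------------

# Local sums of I and I^2 over the kernel's member pixels for every center
# whose window fits inside `P`; outputs are (nrow(P)-2m) x (ncol(P)-2m).
# Windows are decomposed into per-row chords (contiguous runs for both
# square and disc kernels) taken from row prefix sums in compiled code.
.local_sums12 <- function(P, kernel) {
  m <- (kernel$size - 1L) %/% 2L
  if (nrow(P) < kernel$size || ncol(P) < kernel$size)
    stop_user("image smaller than the kernel")
  half <- if (kernel$shape == "square") rep(m, 2L * m + 1L)
          else floor(sqrt(pmax(.disc_r2(kernel) - (-m:m)^2, 0)))
  storage.mode(P) <- "double"
  .chord_local_sums(P, as.integer(half), m)
}

# Shared Ks computation from local sums of I and I^2.
.ks_from_sums <- function(s1, s2, M, divisor) {
  mu <- s1 / M
  v <- if (divisor == "population_n") s2 / M - mu^2
       else (s2 - s1^2 / M) / (M - 1)
  n_clamped <- sum(v < 0 & is.finite(v))
  v[v < 0] <- 0
  ks <- sqrt(v) / mu
  ks[mu == 0] <- NA_real_
  list(ks = ks, n_clamped = n_clamped)
}

# Place an interior-only matrix into a full-size NA frame.
.with_na_margin <- function(inner, full_dim, m) {
  out <- matrix(NA_real_, full_dim[1], full_dim[2])
  out[m + seq_len(nrow(inner)), m + seq_len(ncol(inner))] <- inner
  out
}

# --- engines ---------------------------------------------------------------

#' Direct (nested-loop) spatial contrast: the reference implementation
#'
#' Computes, for each interior pixel, `Ks = sqrt(Var(window))/Mean(window)`
#' by explicit summation over the window's member pixels, using the
#' mathematical definitions of the mean and variance. Deliberately naive and
#' slow; every vectorized engine is validated against it. Border pixels whose
#' window does not fit are `NA` (the map carries `valid_margin =
#' floor(size/2)`).
#'
#' @param image 2D non-negative numeric matrix.
#' @param kernel A [kernel_spec()]; its `padding` is ignored (the direct
#'   reference is computed on full interior windows only).
#' @param exposure_time Exposure time in ms recorded on the output map.
#' @return A [contrast_map()].
#' @examples
#' img <- matrix(1, 9, 9); img[5, 5] <- 26
#' cm <- contrast_direct(img, kernel_spec("square", 5))
#' cm$values[5, 5]  # sqrt(24)/2
#' @export
contrast_direct <- function(image, kernel, exposure_time = NA_real_) {
  stopifnot(is.matrix(image), inherits(kernel, "kernel_spec"))
  if (any(image < 0)) stop_user("`image` must be non-negative")
  m <- (kernel$size - 1L) %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  if (nr < kernel$size || nc < kernel$size)
    stop_user("image smaller than the kernel")
  off <- kernel_offsets(kernel)
  dy <- off[, "dy"]; dx <- off[, "dx"]
  M <- nrow(off)
  ddof <- if (kernel$divisor == "population_n") M else M - 1L
  vals <- matrix(NA_real_, nr, nc)
  for (j in (m + 1L):(nc - m)) {
    for (i in (m + 1L):(nr - m)) {
      s <- 0
      for (t in seq_len(M)) s <- s + image[i + dy[t], j + dx[t]]
      mu <- s / M
      if (mu == 0) next
      ss <- 0
      for (t in seq_len(M)) {
        d <- image[i + dy[t], j + dx[t]] - mu
        ss <- ss + d * d
      }
      vals[i, j] <- sqrt(ss / ddof) / mu
    }
  }
  contrast_map(vals, exposure_time, kernel, valid_margin = m)
}

#' Vectorized "sums algorithm" spatial contrast
#'
#' Computes local means of I and I^2 in a single pass (cumulative-sum box or
#' disc filtering) and forms `Ks = sqrt(max(E[I^2] - E[I]^2, 0)) / E[I]`. On
#' the valid interior this equals [contrast_direct()] to within 1e-9 for the
#' same kernel and divisor; the padding mode only affects pixels within
#' `floor(size/2)` of the border. Negative variances arising from
#' floating-point cancellation are clamped to zero and counted in the map's
#' `n_clamped` field.
#'
#' @inheritParams contrast_direct
#' @param kernel A [kernel_spec()]; `padding = "none_crop"` leaves the border
#'   `NA`, any other mode fills it using padded windows.
#' @return A [contrast_map()].
#' @export
contrast_sums <- function(image, kernel, exposure_time = NA_real_) {
  stopifnot(is.matrix(image), inherits(kernel, "kernel_spec"))
  if (any(image < 0)) stop_user("`image` must be non-negative")
  m <- (kernel$size - 1L) %/% 2L
  if (nrow(image) < kernel$size || ncol(image) < kernel$size)
    stop_user("image smaller than the kernel")
  M <- nrow(kernel_offsets(kernel))
  P <- if (kernel$padding == "none_crop") image
       else pad_image(image, m, kernel$padding)
  s12 <- .local_sums12(P, kernel)
  r <- .ks_from_sums(s12$s1, s12$s2, M, kernel$divisor)
  vals <- if (kernel$padding == "none_crop")
    .with_na_margin(r$ks, dim(image), m) else r$ks
  contrast_map(vals, exposure_time, kernel, valid_margin = m,
               n_clamped = r$n_clamped)
}

#' Dispatch a contrast computation on the kernel's engine
#'
#' Applies the engine conventions: `sums_uniform` forces a square kernel with
#' reflect padding, `sums_correlate_pad` a square kernel with constant-zero
#' padding, `sums_disc` a disc kernel (constant-zero padding unless the spec
#' asks for reflect), and `direct` the nested-loop reference. The returned
#' map's kernel records the variant actually applied.
#'
#' @inheritParams contrast_direct
#' @return A [contrast_map()].
#' @export
contrast_variant <- function(image, kernel, exposure_time = NA_real_) {
  stopifnot(inherits(kernel, "kernel_spec"))
  eff <- kernel
  switch(kernel$engine,
    direct = return(contrast_direct(image, kernel, exposure_time)),
    sums_uniform = {
      eff$shape <- "square"
      if (eff$padding == "none_crop") eff$padding <- "reflect"
    },
    sums_correlate_pad = {
      eff$shape <- "square"
      eff$padding <- "constant_zero"
    },
    sums_disc = {
      eff$shape <- "disc"
      if (!eff$padding %in% c("constant_zero", "reflect"))
        eff$padding <- "constant_zero"
    },
    stop_user("unknown engine: ", kernel$engine))
  contrast_sums(image, eff, exposure_time)
}

# --- map post-processing ---------------------------------------------------

#' Crop the border region of a contrast map
#'
#' Removes `valid_margin = floor(size/2)` pixels per side, discarding every
#' pixel whose window involved the image border (or padding). Cropping an
#' already-cropped map is a no-op.
#'
#' @param map A [contrast_map()].
#' @return A [contrast_map()] with updated dimensions and `valid_margin = 0`.
#' @export
crop_edges <- function(map) {
  stopifnot(inherits(map, "contrast_map"))
  m <- map$valid_margin
  if (m == 0L) return(map)
  if (nrow(map$values) < 2L * m + 1L || ncol(map$values) < 2L * m + 1L)
    stop_user("map smaller than 2*margin+1: nothing left after cropping")
  vals <- map$values[(m + 1L):(nrow(map$values) - m),
                     (m + 1L):(ncol(map$values) - m), drop = FALSE]
  contrast_map(vals, map$exposure_time, map$kernel, valid_margin = 0L,
               n_clamped = map$n_clamped)
}

#' Mean contrast of the valid (cropped) region
#'
#' @param map A [contrast_map()].
#' @return Mean of the defined Ks values after border cropping.
#' @export
mean_contrast <- function(map) {
  mean(crop_edges(map)$values, na.rm = TRUE)
}

#' Pixelwise relative error of one contrast map against a reference
#'
#' Elementwise `100 * (test - reference) / reference`, in percent. Undefined
#' (NA) wherever the reference is undefined or zero - never infinite.
#'
#' @param test,reference [contrast_map()]s of identical dimensions (crop
#'   both to the common valid region first).
#' @return A list of class `"relative_error_map"` with `values` (matrix, %),
#'   `mean`, `min` and `max` over the defined pixels.
#' @export
relative_error_map <- function(test, reference) {
  stopifnot(inherits(test, "contrast_map"), inherits(reference, "contrast_map"))
  if (!identical(dim(test$values), dim(reference$values)))
    stop_user("test and reference maps differ in shape")
  ref <- reference$values
  vals <- 100 * (test$values - ref) / ref
  vals[is.na(ref) | ref == 0] <- NA_real_
  structure(list(values = vals,
                 mean = mean(vals, na.rm = TRUE),
                 min = suppressWarnings(min(vals, na.rm = TRUE)),
                 max = suppressWarnings(max(vals, na.rm = TRUE))),
            class = "relative_error_map")
}

#' @export
print.relative_error_map <- function(x, ...) {
  cat(sprintf("<relative_error_map> mean %.3g%%, range [%.3g%%, %.3g%%]\n",
              x$mean, x$min, x$max))
  invisible(x)
}
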