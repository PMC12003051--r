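#' Container for a stack of speckle frames
#'
#' Frames are stored as a 3D array `[row, col, frame]` of non-negative
#' intensities, with one exposure time per frame. Quantized stacks hold
#' integer-valued intensities bounded by `2^bit_depth - 1`.
#'
#' @param frames 3D numeric array `[row, col, frame]`, all values >= 0. A
#'   single matrix is promoted to a one-frame stack.
#' @param exposure_times Exposure time in ms for each frame (length 1 is
#'   recycled).
#' @param quantized Logical; if `TRUE` values must be integers within the bit
#'   depth.
#' @param bit_depth Bit depth of quantized data (ignored when not quantized).
#' @param provenance Free-text origin (simulator config summary or file path).
#' @return An object of class `"speckle_stack"`.
#' @export
speckle_stack <- function(frames, exposure_times, quantized = FALSE,
                          bit_depth = NA_integer_, provenance = "") {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_user("`frames` must be a matrix or a 3D array [row, col, frame]")
  if (any(frames < 0)) stop_user("intensities must be non-negative")
  nf <- dim(frames)[3]
  if (length(exposure_times) == 1L) exposure_times <- rep(exposure_times, nf)
  if (length(exposure_times) != nf)
    stop_user("`exposure_times` must have one value per frame")
  if (any(exposure_times <= 0)) stop_user("exposure times must be positive")
  if (isTRUE(quantized)) {
    if (is.na(bit_depth)) stop_user("quantized stacks need a `bit_depth`")
    if (any(frames != round(frames)) || any(frames > 2^bit_depth - 1))
      stop_user("quantized intensities must be integers <= 2^bit_depth - 1")
  }
  structure(list(frames = frames,
                 exposure_times = as.double(exposure_times),
                 quantized = isTRUE(quantized),
                 bit_depth = as.integer(bit_depth),
                 provenance = as.character(provenance)),
            class = "speckle_stack")
}

#' Number of frames in a stack
#' @param stack A [speckle_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "speckle_stack"))
  dim(stack$frames)[3]
}

#' Extract one frame of a stack as a matrix
#' @param stack A [speckle_stack()].
#' @param i Frame index.
#' @return Numeric matrix.
#' @export
get_frame <- function(stack, i) {
  stopifnot(inherits(stack, "speckle_stack"))
  stack$frames[, , i]
}

#' @export
print.speckle_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<speckle_stack> %d frame(s) of %dx%d px, %s\n", d[3], d[1], d[2],
              if (x$quantized) sprintf("%d-bit integer", x$bit_depth)
              else "floating point"))
  Ts <- unique(x$exposure_times)
  cat(sprintf("  exposures (ms): %s\n",
              paste(signif(utils::head(Ts, 8), 4), collapse = ", ")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
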