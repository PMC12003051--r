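#' Specification of one sliding-window contrast implementation
#'
#' A `kernel_spec` fully describes a numerical variant of the spatial speckle
#' contrast: window shape and size, border handling, variance divisor and the
#' computational engine. The `direct` engine is the nested-loop reference
#' against which every other engine is validated.
#'
#' Engines mirror the numerically distinct implementations found in common
#' image-processing stacks:
#' * `direct` - explicit summation over window members (reference).
#' * `sums_uniform` - square kernel, local sums by cumulative-sum box
#'   filtering, `reflect` border (uniform-filter style).
#' * `sums_correlate_pad` - square kernel, `constant_zero` border
#'   (2D-correlation style).
#' * `sums_disc` - disc kernel (zero or reflect border per the spec), the
#'   circular-kernel convolution style.
#'
#' Disc membership follows `disc_rule`. The `"euclidean"` rule admits pixels
#' whose center distance from the window center is at most `r = (size-1)/2`
#' (13 members for diameter 5, 29 for diameter 7). The `"inclusive"` rule is
#' the ImageJ rank-filter convention `d^2 <= r^2 + 1` (21 members for
#' diameter 5, 37 for diameter 7), the mask actually applied by ImageJ's
#' built-in circular filters of radius 2 and 3.
#'
#' @param shape `"square"` or `"disc"`.
#' @param size Window side (square) or diameter (disc) in pixels; odd, >= 3.
#' @param padding `"none_crop"`, `"reflect"` (edge pixel duplicated),
#'   `"constant_zero"`, or `"symmetric"` (mirror without duplicating the
#'   edge). Padding only ever affects pixels within `floor(size/2)` of the
#'   border.
#' @param divisor `"population_n"` (sigma as the plain RMS deviation, the
#'   default) or `"sample_n_minus_1"`.
#' @param engine One of the engines above.
#' @param disc_rule Disc membership rule, `"euclidean"` (default) or
#'   `"inclusive"` (ImageJ convention); ignored for square kernels.
#' @return An object of class `"kernel_spec"`.
#' @examples
#' kernel_spec("square", 7)
#' kernel_spec("disc", 5, engine = "sums_disc")
#' @export
kernel_spec <- function(shape = c("square", "disc"),
                        size = 5L,
                        padding = c("none_crop", "reflect", "constant_zero",
                                    "symmetric"),
                        divisor = c("population_n", "sample_n_minus_1"),
                        engine = c("direct", "sums_uniform",
                                   "sums_correlate_pad", "sums_disc"),
                        disc_rule = c("euclidean", "inclusive")) {
  shape <- match.arg(shape)
  padding <- match.arg(padding)
  divisor <- match.arg(divisor)
  engine <- match.arg(engine)
  disc_rule <- match.arg(disc_rule)
  if (!is_scalar_number(size) || size < 3 || size %% 2 != 1)
    stop_user("`size` must be an odd integer >= 3")
  structure(list(shape = shape, size = as.integer(size), padding = padding,
                 divisor = divisor, engine = engine, disc_rule = disc_rule),
            class = "kernel_spec")
}

# Squared-radius threshold for disc membership under the kernel's rule.
.disc_r2 <- function(kernel) {
  m <- (kernel$size - 1L) %/% 2L
  if (identical(kernel$disc_rule, "inclusive")) m^2 + 1L else m^2
}

#' Member-pixel offsets of a kernel
#'
#' @param kernel A [kernel_spec()].
#' @return Two-column integer matrix of (dy, dx) offsets from the window
#'   center.
#' @export
kernel_offsets <- function(kernel) {
  stopifnot(inherits(kernel, "kernel_spec"))
  m <- (kernel$size - 1L) %/% 2L
  g <- expand.grid(dy = -m:m, dx = -m:m)
  if (kernel$shape == "disc")
    g <- g[g$dy^2 + g$dx^2 <= .disc_r2(kernel), , drop = FALSE]
  out <- as.matrix(g)
  dimnames(out) <- list(NULL, c("dy", "dx"))
  out
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s %d (%d px), padding=%s, divisor=%s, engine=%s\n",
              x$shape, x$size, nrow(kernel_offsets(x)), x$padding, x$divisor,
              x$engine))
  invisible(x)
}

# Short human label used in comparison tables.
kernel_label <- function(kernel) {
  sprintf("%s_%s%d", kernel$engine, substr(kernel$shape, 1, 2), kernel$size)
}
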