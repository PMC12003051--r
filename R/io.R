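# Stack and report serialization.
#
# Multi-page TIFF is the container for frame stacks (the modality's de facto
# standard); 12-bit camera data live in 16-bit pages. A JSON sidecar
# (<path>.json) carries the acquisition metadata the TIFF cannot:
# per-frame exposure times, bit depth and provenance.

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a speckle stack as multi-page TIFF with a JSON sidecar
#'
#' Quantized stacks are stored as 16-bit integer pages (bit-exact round
#' trip); floating-point stacks as 32-bit float pages normalized to \[0, 1\],
#' with the normalization factor recorded in the sidecar (float stacks
#' therefore need the sidecar to recover their scale). The sidecar records
#' exposure times, quantization, bit depth, provenance and package version.
#'
#' @param stack A [speckle_stack()].
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @param sidecar Write the sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "speckle_stack"))
  nf <- n_frames(stack)
  pages <- lapply(seq_len(nf), function(i) get_frame(stack, i))
  float_scale <- 1
  if (stack$quantized) {
    pages <- lapply(pages, function(p) p / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    float_scale <- max(1e-300, max(vapply(pages, max, numeric(1))))
    pages <- lapply(pages, function(p) p / float_scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  if (sidecar) {
    meta <- list(exposure_times_ms = stack$exposure_times,
                 float_scale = float_scale,
                 quantized = stack$quantized,
                 # NA has no stable JSON form; omit when absent
                 bit_depth = if (!is.na(stack$bit_depth)) stack$bit_depth,
                 provenance = stack$provenance,
                 package_version = as.character(utils::packageVersion(
                   "speckleflow")))
    jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Exposure times come from the JSON sidecar written by [write_stack()], or
#' from the `exposure_times` override; if neither is available this is an
#' error (never silent defaults).
#'
#' @param path TIFF path.
#' @param exposure_times Optional override (ms): one value per frame, or one
#'   cycle recycled across frames.
#' @return A [speckle_stack()].
#' @export
read_stack <- function(path, exposure_times = NULL) {
  if (!file.exists(path)) stop_user("no such file: ", path)
  probe <- tiff::readTIFF(path, info = TRUE)
  # container convention: 16-bit pages hold integer data, 32-bit pages float
  is_float <- identical(attr(probe, "bits.per.sample"), 32L)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_user("ragged multi-page TIFF: pages differ in size")
  meta <- NULL
  if (file.exists(.sidecar_path(path)))
    meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  if (is.null(exposure_times)) exposure_times <- meta$exposure_times_ms
  if (is.null(exposure_times))
    stop_user("no exposure metadata: missing sidecar ", .sidecar_path(path),
              " and no `exposure_times` override")
  nf <- length(pages)
  if (length(exposure_times) != nf) {
    if (nf %% length(exposure_times) == 0L)
      exposure_times <- rep(exposure_times, length.out = nf)
    else stop_user("exposure_times length does not match the frame count")
  }
  quantized <- if (!is.null(meta$quantized)) isTRUE(meta$quantized)
               else !is_float
  frames <- array(0, c(dims[1, 1], dims[2, 1], nf))
  scale <- if (is_float) (meta$float_scale %||% 1) else 1
  for (i in seq_len(nf)) frames[, , i] <- pages[[i]] * scale
  speckle_stack(frames, exposure_times, quantized = quantized,
                bit_depth = meta$bit_depth %||%
                  (if (quantized) 16L else NA_integer_),
                provenance = meta$provenance %||% path)
}

#' Write a comparison table or MESI fit report
#'
#' Comparison tables become long-format CSV (fixed column order, 6
#' significant digits); MESI fits become JSON carrying the package version
#' and a hash of the generating configuration. Output is deterministic:
#' writing the same object twice gives byte-identical files.
#'
#' @param x A `"speckle_comparison"` or `"mesi_fit"` object.
#' @param path Output file path (`.csv` or `.json` by object type).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "speckle_comparison")) {
    tab <- x$table
    if (is.null(tab) || nrow(tab) == 0L) stop_user("empty comparison table")
    cols <- c("engine", "shape", "size", "padding", "divisor", "T_ms",
              "mean_Ks", "rel_err_pct", "lsci_tau_ms", "mesi_tau_ms")
    tab <- tab[, cols]
    num <- vapply(tab, is.double, logical(1))
    tab[num] <- lapply(tab[num], function(v) signif(v, 6))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "mesi_fit")) {
    report <- list(
      parameters = as.list(x$parameters),
      residual_rms = x$residual_rms,
      n_points = x$n_points,
      fixed = names(x$parameters)[x$fixed_mask],
      non_identifiable = x$non_identifiable,
      data = as.list(x$data),
      package_version = as.character(utils::packageVersion("speckleflow")),
      config_hash = rlang::hash(x[c("fixed_mask", "bounds")]))
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10)
  } else stop_user("`x` must be a speckle_comparison or mesi_fit")
  invisible(path)
}

#' Read a two-column Ks(T) CSV
#'
#' Expects columns `T_ms` and `Ks` (additional columns are ignored), as
#' consumed by the command-line `fit` entry point.
#'
#' @param path CSV path.
#' @return A [tibble::tibble] with `T_ms` and `Ks`.
#' @export
read_ks_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("T_ms", "Ks") %in% names(d)))
    stop_user("CSV must have columns T_ms and Ks")
  tibble::tibble(T_ms = as.double(d$T_ms), Ks = as.double(d$Ks))
}
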