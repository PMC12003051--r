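# Shared fixtures, all generated in code.

tiny_config <- function(tau_c = 1, shape = c(48, 48),
                        exposures = c(0.5, 2, 8), seed = 42L, ...) {
  simulation_config(
    image_shape = shape,
    decorrelation = decorrelation_spec("neg_exponential", tau_c),
    exposure_times = exposures, seed = seed, ...)
}

# Seeded positive random test image (uniform in (0.5, 1.5)).
rand_image <- function(seed, n = 48) {
  set.seed(seed)
  matrix(stats::runif(n * n, 0.5, 1.5), n, n)
}

# Valid-region (cropped) values of a contrast map.
valid_values <- function(map) crop_edges(map)$values
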