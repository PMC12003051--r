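# Statistical contracts of the dynamic speckle generator.

test_that("static field (tau_c = Inf) freezes the pattern", {
  cfg <- simulation_config(image_shape = c(32, 32),
    decorrelation = decorrelation_spec("neg_exponential", Inf),
    exposure_times = 1, seed = 5)
  raw <- generate_field_sequence(cfg, duration = 0.4, dt = 0.1)
  expect_equal(n_frames(raw), 4L)
  for (i in 2:4)
    expect_identical(get_frame(raw, i), get_frame(raw, 1))
  # any temporal statistic has zero variance
  px <- raw$frames[7, 9, ]
  expect_identical(stats::sd(px), 0)
})

test_that("raw frames are fully developed speckle: global contrast ~ 1", {
  cfg <- simulation_config(image_shape = c(256, 256),
    decorrelation = decorrelation_spec("neg_exponential", 1),
    exposure_times = 1, seed = 9)
  raw <- generate_field_sequence(cfg, duration = 0.05)
  I <- get_frame(raw, 1)
  expect_gt(sd(I) / mean(I), 0.95)
  expect_lt(sd(I) / mean(I), 1.05)
})

test_that("intensity autocorrelation obeys the Siegert relation", {
  # g2(tau) - 1 should equal |g1(tau)|^2 = exp(-2 tau / tau_c)
  tau_c <- 1
  cfg <- simulation_config(image_shape = c(128, 128),
    decorrelation = decorrelation_spec("neg_exponential", tau_c),
    exposure_times = 1, seed = 21)
  raw <- generate_field_sequence(cfg, duration = 6)   # dt = 0.05 -> 120 frames
  dt <- raw$exposure_times[1]
  fr <- raw$frames
  nt <- dim(fr)[3]
  # block the image 4x4 to get an empirical standard error across blocks
  blocks <- expand.grid(bi = 0:3, bj = 0:3)
  for (lag in c(1L, 4L, 10L, 20L)) {
    pred <- exp(-2 * lag * dt / tau_c)
    g2m1 <- mapply(function(bi, bj) {
      rows <- bi * 32 + 1:32; cols <- bj * 32 + 1:32
      A <- fr[rows, cols, 1:(nt - lag)]
      B <- fr[rows, cols, (1 + lag):nt]
      mean(A * B) / (mean(A) * mean(B)) - 1
    }, blocks$bi, blocks$bj)
    se <- stats::sd(g2m1) / sqrt(length(g2m1))
    expect_lt(abs(mean(g2m1) - pred), 3 * se + 0.01)
  }
})

test_that("identical seed and config give bit-identical stacks", {
  a <- simulate_mesi_stack(tiny_config(seed = 77, shape = c(32, 32)))
  b <- simulate_mesi_stack(tiny_config(seed = 77, shape = c(32, 32)))
  d <- simulate_mesi_stack(tiny_config(seed = 78, shape = c(32, 32)))
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, d$frames))
})

test_that("doubling the exposure halves Ks^2 deep in the asymptotic regime", {
  cfg <- simulation_config(image_shape = c(96, 96),
    decorrelation = decorrelation_spec("neg_exponential", 0.1),
    exposure_times = c(15, 30), seed = 13)
  k <- kernel_spec("square", 7, engine = "sums_uniform")
  ks2 <- vapply(seq_along(cfg$exposure_times), function(i) {
    f <- integrate_exposure(cfg, cfg$exposure_times[i], seed = 900 + i)
    mean_contrast(contrast_sums(f, k))^2
  }, numeric(1))
  expect_lt(abs(ks2[1] / ks2[2] - 2), 2 * 0.08)
})

test_that("an exposure at or below dt returns a single raw frame", {
  cfg <- tiny_config(tau_c = 1, shape = c(96, 96))
  f <- integrate_exposure(cfg, T = 0.04)   # dt = tau_c/20 = 0.05
  expect_equal(attr(f, "n_subframes"), 1L)
  expect_gt(sd(f) / mean(f), 0.9)
})

test_that("quantization scales, clips and reports saturation", {
  q <- quantize_frame(matrix(1, 8, 8), bit_depth = 12,
                      mean_fill_fraction = 0.25)
  expect_true(all(q == 1024))          # round(0.25 * 4095)
  expect_identical(attr(q, "saturated_fraction"), 0)

  # exponential intensities, mean at quarter scale: P(X > 4 mu) = e^-4
  set.seed(31)
  fr <- matrix(stats::rexp(256 * 256), 256, 256)
  q <- quantize_frame(fr, 12, 0.25)
  expect_lte(max(q), 4095)
  expect_lt(abs(attr(q, "saturated_fraction") - exp(-4)), 0.1 * exp(-4))

  expect_error(quantize_frame(matrix(0, 4, 4)), "all-zero")
})

test_that("invalid simulation requests are rejected", {
  expect_error(simulation_config(px_per_speckle = 1.5,
    decorrelation = decorrelation_spec("neg_exponential", 1)),
    "aliases")
  cfg <- tiny_config()
  expect_error(generate_field_sequence(cfg, duration = -1), "duration")
  expect_error(integrate_exposure(tiny_config(max_subframes = 10), T = 8),
    "cap")
  expect_error(decorrelation_spec("neg_exponential", -1), "positive")
})

test_that("g1 forms start at 1 and are non-increasing", {
  taus <- seq(0, 5, by = 0.25)
  for (form in c("neg_exponential", "gaussian", "sqrt_exponential")) {
    g <- g1_value(decorrelation_spec(form, 0.7), taus)
    expect_equal(g[1], 1)
    expect_true(all(diff(g) <= 0))
  }
})
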