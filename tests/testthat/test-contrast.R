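# The sliding-window contrast engines and their exact relationships.

test_that("direct contrast reproduces hand-computed windows", {
  # twenty-four 1s and a single 26: mean 2, population variance 24
  img <- matrix(1, 9, 9); img[5, 5] <- 26
  cm <- contrast_direct(img, kernel_spec("square", 5))
  expect_equal(cm$values[5, 5], sqrt(24) / 2, tolerance = 1e-12)

  # values 1..25: variance of consecutive integers (n^2-1)/12 = 52
  img2 <- matrix(1:25, 5, 5)
  cm2 <- contrast_direct(img2, kernel_spec("square", 5))
  expect_equal(cm2$values[3, 3], sqrt(52) / 13, tolerance = 1e-12)

  # constant image: zero variance everywhere
  cc <- contrast_direct(matrix(3, 12, 12), kernel_spec("square", 5))
  expect_true(all(valid_values(cc) == 0))
})

test_that("sums engines equal the direct reference on the valid interior", {
  for (seed in 1:3) {
    img <- rand_image(seed)
    for (shape in c("square", "disc")) for (size in c(5L, 7L))
      for (divisor in c("population_n", "sample_n_minus_1")) {
        k <- kernel_spec(shape, size, divisor = divisor)
        ref <- valid_values(contrast_direct(img, k))
        got <- valid_values(contrast_sums(img, k))
        expect_lt(max(abs(got - ref)), 1e-9)
      }
  }
  # inclusive-rule disc agrees with its own direct loop too
  ki <- kernel_spec("disc", 5, disc_rule = "inclusive")
  img <- rand_image(9)
  expect_lt(max(abs(valid_values(contrast_sums(img, ki)) -
                    valid_values(contrast_direct(img, ki)))), 1e-9)
})

test_that("padding affects only pixels within floor(size/2) of the border", {
  img <- rand_image(4)
  for (pad in c("reflect", "constant_zero", "symmetric")) {
    k <- kernel_spec("square", 7, padding = pad)
    padded <- contrast_sums(img, k)
    bare <- contrast_sums(img, kernel_spec("square", 7))
    expect_equal(valid_values(padded), valid_values(bare), tolerance = 1e-12)
    expect_false(anyNA(padded$values))   # border filled, not NA
  }
})

test_that("sample divisor rescales population contrast by sqrt(N/(N-1))", {
  img <- rand_image(6)
  for (shape in c("square", "disc")) {
    kp <- kernel_spec(shape, 5, divisor = "population_n")
    ks <- kernel_spec(shape, 5, divisor = "sample_n_minus_1")
    M <- nrow(kernel_offsets(kp))
    expect_equal(valid_values(contrast_sums(img, ks)),
                 valid_values(contrast_sums(img, kp)) * sqrt(M / (M - 1)),
                 tolerance = 1e-12)
  }
})

test_that("contrast is translation equivariant", {
  img <- rand_image(8, n = 40)
  k <- kernel_spec("square", 5)
  dy <- 3L; dx <- 2L
  shifted <- img[(1 + dy):40, (1 + dx):40]
  a <- valid_values(contrast_sums(img, k))
  b <- valid_values(contrast_sums(shifted, k))
  expect_equal(a[(1 + dy):nrow(a), (1 + dx):ncol(a)],
               b[1:(nrow(a) - dy), 1:(ncol(a) - dx)], tolerance = 1e-12)
})

test_that("disc membership counts follow the declared rules", {
  expect_equal(nrow(kernel_offsets(kernel_spec("disc", 5))), 13L)
  expect_equal(nrow(kernel_offsets(kernel_spec("disc", 7))), 29L)
  expect_equal(nrow(kernel_offsets(
    kernel_spec("disc", 5, disc_rule = "inclusive"))), 21L)
  expect_equal(nrow(kernel_offsets(
    kernel_spec("disc", 7, disc_rule = "inclusive"))), 37L)
  # constant image gives zero contrast whatever the membership rule
  cm <- contrast_sums(matrix(2, 10, 10), kernel_spec("disc", 5))
  expect_true(all(valid_values(cm) == 0))
})

test_that("crop_edges removes floor(size/2) per side and is idempotent", {
  img <- matrix(stats::runif(100 * 100), 100, 100)
  cm7 <- contrast_sums(img, kernel_spec("square", 7))
  cropped <- crop_edges(cm7)
  expect_equal(dim(cropped$values), c(94L, 94L))
  expect_identical(crop_edges(cropped), cropped)
  expect_equal(cropped$valid_margin, 0L)

  cm5 <- contrast_sums(img[1:40, 1:40], kernel_spec("square", 5))
  expect_equal(dim(crop_edges(cm5)$values), c(36L, 36L))

  tiny <- contrast_map(matrix(0.1, 5, 5), 1, kernel_spec("square", 7),
                       valid_margin = 3L)
  expect_error(crop_edges(tiny), "nothing left")
})

test_that("mean_contrast averages the cropped valid region only", {
  img <- rand_image(12)
  cm <- contrast_sums(img, kernel_spec("square", 5, padding = "constant_zero"))
  expect_equal(mean_contrast(cm), mean(crop_edges(cm)$values))
})

test_that("relative error maps are exact, guarded and shape-checked", {
  img <- rand_image(3)
  ref <- crop_edges(contrast_sums(img, kernel_spec("square", 5)))
  expect_true(all(relative_error_map(ref, ref)$values == 0, na.rm = TRUE))

  scaled <- ref; scaled$values <- 0.8 * ref$values
  rem <- relative_error_map(scaled, ref)
  expect_equal(rem$mean, -20, tolerance = 1e-9)
  expect_equal(rem$min, -20, tolerance = 1e-9)

  zref <- ref; zref$values[4, 4] <- 0
  rem2 <- relative_error_map(ref, zref)
  expect_true(is.na(rem2$values[4, 4]))
  expect_false(any(is.infinite(rem2$values)))

  small <- crop_edges(contrast_sums(img[1:20, 1:20], kernel_spec("square", 5)))
  expect_error(relative_error_map(small, ref), "shape")
})

test_that("engine dispatch applies each variant's conventions", {
  img <- rand_image(5)
  u <- contrast_variant(img, kernel_spec("disc", 5, engine = "sums_uniform"))
  expect_equal(u$kernel$shape, "square")
  expect_equal(u$kernel$padding, "reflect")
  cp <- contrast_variant(img, kernel_spec("square", 5, padding = "reflect",
                                          engine = "sums_correlate_pad"))
  expect_equal(cp$kernel$padding, "constant_zero")
  dv <- contrast_variant(img, kernel_spec("square", 5, engine = "sums_disc"))
  expect_equal(dv$kernel$shape, "disc")
  expect_equal(dv$kernel$padding, "constant_zero")
})

test_that("undersized images and negative inputs are rejected", {
  expect_error(contrast_direct(matrix(1, 4, 4), kernel_spec("square", 5)),
               "smaller")
  expect_error(contrast_sums(matrix(1, 4, 4), kernel_spec("square", 5)),
               "smaller")
  expect_error(contrast_direct(matrix(-1, 9, 9), kernel_spec("square", 5)),
               "non-negative")
})
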