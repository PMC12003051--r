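# MESI forward model, bounded regression and the asymptotic estimator.

test_that("mesi_model matches analytic values and limits", {
  # x -> 0, rho = 1, v = 0: K -> sqrt(beta)
  expect_equal(mesi_model(1e-9, beta = 0.25, tau_c = 1), 0.5,
               tolerance = 1e-9)
  # x = 1, beta = 0.3: K = sqrt(0.3 (1 + e^-2)/2)
  expect_equal(mesi_model(0.3, beta = 0.3, tau_c = 0.3),
               sqrt(0.3 * (1 + exp(-2)) / 2), tolerance = 1e-12)
  # large x: K^2 -> beta rho^2 / x
  x <- 1e4
  expect_equal(mesi_model(x, beta = 0.4, tau_c = 1)^2, 0.4 / x,
               tolerance = 1e-3)
  # strictly decreasing in T when v terms vanish
  K <- mesi_model(mesi_exposures("simulation"), beta = 0.3, tau_c = 0.5)
  expect_true(all(diff(K) < 0))
})

test_that("series and direct branches agree at the switchover", {
  u <- 0.01   # the branch point: direct formula from here up, series below
  direct <- speckleflow:::.mesi_h(u)
  series <- 1 / 2 - u / 6 + u^2 / 24 - u^3 / 120 + u^4 / 720 - u^5 / 5040
  expect_lt(abs(direct - series), 1e-12)
})

test_that("model rejects unphysical arguments", {
  expect_error(mesi_model(-1, beta = 0.3, tau_c = 1), "positive")
  expect_error(mesi_model(1, beta = 0.3, tau_c = 0), "positive")
  expect_error(mesi_model(1, beta = 0.3, rho = 1.5, tau_c = 1), "rho")
})

test_that("fitting exact model data recovers the parameters", {
  T <- mesi_exposures("simulation")
  for (beta in c(0.1, 0.5)) for (tau in c(0.05, 1, 5)) {
    fit <- fit_mesi(T, mesi_model(T, beta = beta, tau_c = tau))
    expect_lt(abs(fit$parameters[["tau_c"]] - tau) / tau, 1e-3)
    expect_lt(abs(fit$parameters[["beta"]] - beta) / beta, 1e-3)
  }
})

test_that("tau_c is recovered within 2% under 0.5% multiplicative noise", {
  T <- mesi_exposures("simulation")
  truth <- mesi_model(T, beta = 0.3, tau_c = 0.5)
  set.seed(2024)
  errs <- replicate(100, {
    noisy <- truth * (1 + stats::rnorm(length(T), sd = 0.005))
    fit <- fit_mesi(T, noisy)
    abs(fit$parameters[["tau_c"]] - 0.5) / 0.5
  })
  expect_lt(mean(errs), 0.02)       # typical recovery error
  expect_lt(max(errs), 0.05)        # no replicate strays far
})

test_that("refitting from a fit's own parameters is idempotent", {
  T <- mesi_exposures("simulation")
  set.seed(11)
  noisy <- mesi_model(T, beta = 0.35, tau_c = 0.2) *
    (1 + stats::rnorm(length(T), sd = 0.01))
  f1 <- fit_mesi(T, noisy)
  clean <- mesi_model(T, beta = f1$parameters[["beta"]],
                      tau_c = f1$parameters[["tau_c"]])
  f2 <- fit_mesi(T, clean)
  expect_equal(f2$parameters[["tau_c"]], f1$parameters[["tau_c"]],
               tolerance = 1e-6)
  expect_equal(f2$parameters[["beta"]], f1$parameters[["beta"]],
               tolerance = 1e-6)
})

test_that("degenerate fits are flagged or rejected", {
  T <- mesi_exposures("simulation")
  fit <- fit_mesi(T, rep(0.2, length(T)))
  expect_true(fit$non_identifiable)
  expect_error(fit_mesi(c(1, 1, 2), c(0.5, 0.4, 0.3)), "distinct")
  expect_error(fit_mesi(1, 0.5), "points")
  # fitted parameters respect the declared box bounds
  b <- mesi_bounds("simulation")
  noisy <- mesi_model(T, beta = 0.9, tau_c = 0.1)
  f <- fit_mesi(T, noisy, bounds = b)
  p <- f$parameters[c("beta", "tau_c")]
  expect_true(all(p >= b$lower[c("beta", "tau_c")] - 1e-12))
  expect_true(all(p <= b$upper[c("beta", "tau_c")] + 1e-12))
})

test_that("asymptotic estimator inverts its defining relation exactly", {
  beta <- 0.3; tau <- 0.25; T <- 40
  Ks <- sqrt(beta * tau / T)
  out <- lsci_asymptotic_tau(Ks, T, beta)
  expect_equal(out$tau_c_ms, tau, tolerance = 1e-12)
  expect_true(out$reliable)   # T/tau = 160 > 100
  expect_equal(out$bfi, 1 / (T * Ks^2), tolerance = 1e-12)
})

test_that("estimator applied to the exact model shows the known small bias", {
  # tau_c = 0.1 ms at T = 60 ms (x = 600): tau_hat = tau * (e^-2x - 1 + 2x)/(2x)
  beta <- 0.42; tau <- 0.1; T <- 60; x <- T / tau
  Ks <- mesi_model(T, beta = beta, tau_c = tau)
  out <- lsci_asymptotic_tau(Ks, T, beta)
  expect_equal(out$tau_c_ms, tau * (exp(-2 * x) - 1 + 2 * x) / (2 * x),
               tolerance = 1e-10)
  expect_equal(out$tau_c_ms, 0.0999167, tolerance = 1e-5)
})

test_that("estimates outside the validity region are flagged unreliable", {
  out <- lsci_asymptotic_tau(Ks = 0.5, T = 1, beta = 0.3)  # T/tau < 100
  expect_false(out$reliable)
  expect_true(is.na(lsci_asymptotic_tau(Ks = 0, T = 1, beta = 0.3)$tau_c_ms))
  expect_true(is.na(bfi(0, 1)))
})
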