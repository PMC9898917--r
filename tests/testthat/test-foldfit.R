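test_that("free-energy expression satisfies its closed-form anchors", {
  p <- stability_params(Tm = 52, dHm = 300, dCp = 8, m_value = 7.1,
                        baselines = list("330" = c(1, 0, 0, 0),
                                         "350" = c(1, 0, 0, 0)))
  ## midpoint definition
  expect_equal(delta_g(p, 52, 0), 0, tolerance = 1e-12)
  ## urea denaturation midpoint: c = dG(T, 0)/m
  c_mid <- delta_g(p, 37, 0) / p$m_value
  expect_equal(delta_g(p, 37, c_mid), 0, tolerance = 1e-12)
  ## hand-evaluated Gibbs-Helmholtz value (dHm 300, dCp 8, Tm 52, 37 degC)
  expect_equal(delta_g(p, 37, 0), 11.02824, tolerance = 1e-5)
  ## van't Hoff limit: dCp = 0 reduces to dHm (1 - T/Tm)
  p0 <- stability_params(Tm = 52, dHm = 300, dCp = 0, m_value = 7.1,
                         baselines = p$baselines)
  Ts <- seq(10, 90, by = 7)
  expect_equal(delta_g(p0, Ts, 0),
               300 * (1 - (Ts + 273.15) / (52 + 273.15)),
               tolerance = 1e-12)
  ## fraction unfolded is one half at the zero-urea midpoint
  expect_equal(fraction_unfolded(p, 52, 0), 0.5, tolerance = 1e-9)
})

test_that("signal model interpolates between the wavelength baselines", {
  truth <- default_stability_truth()
  ## deeply folded: signal equals the folded baseline
  expect_equal(signal_model(truth, 5, 0, 330),
               19000 - 30 * 5, tolerance = 1e-3)
  ## at the midpoint the signal is the baseline midpoint
  Tm <- truth$Tm
  b <- truth$baselines[["350"]]
  expect_equal(signal_model(truth, Tm, 0, 350),
               ((b[["f_int"]] + b[["f_slope"]] * Tm) +
                  (b[["u_int"]] + b[["u_slope"]] * Tm)) / 2,
               tolerance = 1e-9)
  expect_error(signal_model(truth, 37, 0, 340), "330 or 350")
})

test_that("global fit recovers noiseless truth with the m-value free", {
  truth <- default_stability_truth()
  cv <- gen_melt_curves(truth, T_grid = seq(20, 70, by = 2.5),
                        noise_sd = 0)
  fit <- global_fit(cv)            # m free, zero-urea curve excluded
  expect_lt(abs(fit$Tm - truth$Tm) / truth$Tm, 1e-3)
  expect_lt(abs(fit$dHm - truth$dHm) / truth$dHm, 1e-3)
  expect_lt(abs(fit$m_value - truth$m_value) / truth$m_value, 1e-3)
  expect_lt(abs(fit$dG37 - delta_g(truth, 37, 0)) /
              delta_g(truth, 37, 0), 1e-3)
  ## noiseless forward curves leave zero residuals under the fit
  expect_lt(fit$rss, 1e-6)
  ## the default exclusion dropped the zero-urea family
  expect_identical(fit$n_curves, 8L)
})

test_that("fixing the m-value removes one parameter and keeps recovery", {
  truth <- default_stability_truth()
  cv <- gen_melt_curves(truth, T_grid = seq(20, 70, by = 2.5),
                        noise_sd = 10, seed = 3)
  fit <- global_fit(cv, fix_m = 7.1)
  expect_true(fit$m_fixed)
  expect_identical(fit$m_value, 7.1)
  expect_equal(fit$dG37, delta_g(truth, 37, 0), tolerance = 0.2)
})

test_that("urea coverage below two concentrations is rejected", {
  truth <- default_stability_truth()
  cv <- gen_melt_curves(truth, urea_grid = c(0, 2), noise_sd = 0)
  expect_error(global_fit(cv), ">= 2 urea")   # exclusion leaves one
  expect_error(global_fit(list()), "melt_curve")
})

test_that("capillary bootstrap is deterministic and collapses without noise", {
  truth <- default_stability_truth()
  cv <- gen_melt_curves(truth, urea_grid = seq(0.67, 5.36, length.out = 5),
                        T_grid = seq(20, 70, by = 2.5), noise_sd = 0,
                        n_capillaries = 2)
  est1 <- bootstrap_ci(cv, n_boot = 20, seed = 42, fix_m = 7.1)
  est2 <- bootstrap_ci(cv, n_boot = 20, seed = 42, fix_m = 7.1)
  expect_equal(est1$ci_low, est2$ci_low, tolerance = 1e-12)
  expect_equal(est1$ci_high, est2$ci_high, tolerance = 1e-12)
  ## zero noise: interval width is numerically nil and brackets dG37
  expect_lt(est1$ci_high - est1$ci_low, 1e-4)
  expect_true(est1$ci_low <= est1$dG37 + 1e-6 &&
                est1$dG37 <= est1$ci_high + 1e-6)
  one_cap <- gen_melt_curves(truth, urea_grid = c(1, 2), noise_sd = 0)
  one_cap <- lapply(one_cap, function(x) { x$capillary_id <- "C1"; x })
  expect_error(bootstrap_ci(one_cap, n_boot = 5), ">= 2 capillaries")
})

test_that("fixing m at truth does not worsen average dG37 recovery", {
  truth <- default_stability_truth()
  dg <- delta_g(truth, 37, 0)
  err_free <- err_fix <- numeric(12)
  for (s in seq_along(err_free)) {
    cv <- gen_melt_curves(truth, T_grid = seq(20, 70, by = 2.5),
                          noise_sd = 10, seed = 300 + s)
    err_free[s] <- abs(global_fit(cv)$dG37 - dg)
    err_fix[s] <- abs(global_fit(cv, fix_m = truth$m_value)$dG37 - dg)
  }
  expect_lte(mean(err_fix), mean(err_free) * 1.05)
})
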