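test_that("noiseless binding fits recover the generating constant", {
  p <- kinetic_params(k_bind = 0.010, amplitude = 100, baseline = 50)
  tr <- simulate_gtpgs_trace(p, sampling_schedule(0, 600, 121))
  fit <- fit_binding_rate(tr)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$k_bind - 0.010) / 0.010, 1e-6)
  expect_lt(abs(fit$params$amplitude - 100) / 100, 1e-6)
  expect_lt(fit$rmse, 1e-8)
})

test_that("binding-rate estimator is nearly unbiased at 2% noise", {
  # light version of the full bias study (the deeper run lives in the
  # acceptance suite)
  k_hat <- vapply(1:40, function(i) {
    tr <- simulate_gtpgs_trace(kinetic_params(0.010, amplitude = 100,
                                              baseline = 50),
                               sampling_schedule(0, 600, 121),
                               noise_model(0.02, seed = i))
    fit_binding_rate(tr)$params$k_bind
  }, numeric(1))
  expect_lt(abs(mean(k_hat) - 0.010) / 0.010, 0.05)
})

test_that("fold-changes between fitted constants mirror the truth", {
  sch <- sampling_schedule(0, 600, 121)
  f1 <- fit_binding_rate(simulate_gtpgs_trace(
    kinetic_params(0.010, amplitude = 100, baseline = 50), sch))
  f2 <- fit_binding_rate(simulate_gtpgs_trace(
    kinetic_params(0.340, amplitude = 100, baseline = 50), sch),
    reference = f1$params$k_bind)
  expect_equal(f2$fold_vs_reference$fold, 34, tolerance = 1e-4)
  expect_identical(f2$fold_vs_reference$direction, "increase")
})

test_that("joint GTP fits recover both constants and branch correctly", {
  p <- kinetic_params(0.02, 0.002, 100, 10)
  # full window (5 / k_hydr): hydrolysis completes -> direct branch
  full <- fit_gtp_kinetics(simulate_gtp_trace(p, sampling_schedule(0, 2500, 1001)))
  expect_identical(full$method, "direct")
  expect_lt(abs(full$params$k_bind - 0.02) / 0.02, 1e-4)
  expect_lt(abs(full$params$k_hydr - 0.002) / 0.002, 1e-4)

  # truncated window (1 / k_hydr): projected-baseline extrapolation
  trunc <- fit_gtp_kinetics(simulate_gtp_trace(p, sampling_schedule(0, 500, 201)))
  expect_identical(trunc$method, "extrapolated")
  expect_lt(abs(trunc$params$k_hydr - 0.002) / 0.002, 0.10)
  expect_equal(trunc$params$baseline, 10)  # fixed at initial fluorescence
})

test_that("a non-hydrolysing GTP trace yields k_hydr at the zero bound", {
  p <- kinetic_params(0.01, 0, 100, 50)
  fit <- fit_gtp_kinetics(simulate_gtp_trace(p, sampling_schedule(0, 600, 121)))
  expect_lte(fit$params$k_hydr, 1e-6)
  expect_false(is.na(fit$note))  # wide-uncertainty flag, not an exception
  # and k_bind agrees with the binding-only route on the same kinetics
  fb <- fit_binding_rate(simulate_gtpgs_trace(p, sampling_schedule(0, 600, 121)))
  expect_lt(abs(fit$params$k_bind - fb$params$k_bind) / fb$params$k_bind, 1e-4)
})

test_that("activity classification applies the 3-sigma amplitude rule", {
  sch <- sampling_schedule(0, 100, 21)
  flat <- fluorescence_trace(sch$times, rep(50, 21))
  expect_identical(classify_activity(flat), "inactive")
  expect_error(fit_binding_rate(flat), "classify_activity")

  rise <- function(a) fluorescence_trace(sch$times,
                                         50 + a * (1 - exp(-0.1 * sch$times)))
  expect_identical(classify_activity(rise(10), sigma_noise = 1), "active")
  # boundary: amplitude exactly 3 sigma resolves to active
  amp3 <- max(rise(3)$values) - rise(3)$values[1]
  expect_identical(classify_activity(rise(3), sigma_noise = amp3 / 3),
                   "active")
  expect_identical(classify_activity(rise(1), sigma_noise = 1), "inactive")
  # monotone in amplitude at fixed noise
  labels <- vapply(c(0.5, 1, 2, 4, 8, 16),
                   function(a) classify_activity(rise(a), sigma_noise = 1),
                   character(1))
  expect_false(is.unsorted(match(labels, c("inactive", "active"))))
})

test_that("fold_change reports direction and magnitude", {
  fc <- fold_change(0.34, 0.01)
  expect_equal(fc$fold, 34)
  expect_identical(fc$direction, "increase")
  expect_equal(fold_change(5, 5)$fold, 1)
  dec <- fold_change(0.005, 0.01)
  expect_equal(dec$fold, 2)
  expect_identical(dec$direction, "decrease")
  expect_error(fold_change(1, 0), "reference")
})
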