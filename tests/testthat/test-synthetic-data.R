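test_that("binding-only traces match the closed-form rise", {
  p <- kinetic_params(k_bind = 0.01, amplitude = 100, baseline = 50)
  tr <- simulate_gtpgs_trace(p, sampling_schedule(0, 600, 121))
  expect_equal(tail(tr$values, 1), 50 + 100 * (1 - exp(-6)), tolerance = 1e-12)
  expect_equal(tr$values, 50 + 100 * (1 - exp(-0.01 * tr$times)),
               tolerance = 1e-12)
  expect_identical(tr$ligand, "GTPgS")
  expect_length(tr$values, 121L)
})

test_that("zero amplitude gives a flat trace at the baseline", {
  p <- kinetic_params(k_bind = 0.05, amplitude = 0, baseline = 30)
  tr <- simulate_gtpgs_trace(p, sampling_schedule(0, 100, 11))
  expect_true(all(tr$values == 30))
})

test_that("noisy generators are bitwise deterministic under a fixed seed", {
  p <- kinetic_params(0.01, 0.001, 100, 50)
  sch <- sampling_schedule(0, 300, 61)
  nz <- noise_model(sigma_rel = 0.02, seed = 42)
  expect_identical(simulate_gtpgs_trace(p, sch, nz)$values,
                   simulate_gtpgs_trace(p, sch, nz)$values)
  expect_identical(simulate_gtp_trace(p, sch, nz)$values,
                   simulate_gtp_trace(p, sch, nz)$values)
  # different seeds differ
  nz2 <- noise_model(sigma_rel = 0.02, seed = 43)
  expect_false(identical(simulate_gtp_trace(p, sch, nz)$values,
                         simulate_gtp_trace(p, sch, nz2)$values))
})

test_that("GTP traces follow the Bateman model with its analytic landmarks", {
  # no-hydrolysis limit equals the binding-only trace exactly
  p0 <- kinetic_params(0.01, 0, 100, 50)
  sch <- sampling_schedule(0, 600, 121)
  expect_identical(simulate_gtp_trace(p0, sch)$values,
                   simulate_gtpgs_trace(p0, sch)$values)

  # peak position: ln(k_bind/k_hydr) / (k_bind - k_hydr)
  p <- kinetic_params(0.02, 0.002, 100, 0)
  dense <- simulate_gtp_trace(p, sampling_schedule(0, 600, 60001))
  t_peak <- dense$times[which.max(dense$values)]
  expect_equal(t_peak, log(0.02 / 0.002) / (0.02 - 0.002), tolerance = 1e-3)

  # equal-rate limit: F(t) = A * k t exp(-k t)
  pe <- kinetic_params(0.01, 0.01, 100, 0)
  tre <- simulate_gtp_trace(pe, sampling_schedule(0, 100, 2))
  expect_equal(tail(tre$values, 1), 100 * 1 * exp(-1), tolerance = 1e-9)

  # rises then falls back toward the baseline
  expect_lt(tail(dense$values, 1), max(dense$values))
  expect_gt(max(dense$values), dense$values[1])
})

test_that("parameter validation rejects degenerate inputs", {
  expect_error(kinetic_params(k_bind = 0), "k_bind")
  expect_error(kinetic_params(k_bind = 0.01, k_hydr = -1), "k_hydr")
  expect_error(sampling_schedule(0, 0, 10), "t_end")
  expect_error(sampling_schedule(0, 10, 1), "n_points")
  expect_error(noise_model(-0.1), "sigma_rel")
})

test_that("cohort generator hits configured medians", {
  # degenerate dispersion: onsets equal the configured medians exactly
  coh0 <- simulate_cohort(tiny_cohort_spec(sigma_log = 0), seed = 7)
  expect_true(all(coh0$onset_days[coh0$mutation == "G45E"] == 5))
  expect_true(all(coh0$onset_days[coh0$mutation == "R209C"] == 500))
  expect_identical(coh0$disorder[coh0$mutation == "R209C"],
                   rep("NEDIM", 3))

  # empirical median converges to the configured median at large n
  spec <- cohort_spec(c("A1", "B1"), c("DEE17", "NEDIM"),
                      c(10000L, 10000L), c(43, 569), sigma_log = 0.5)
  coh <- simulate_cohort(spec, seed = 11)
  med <- tapply(coh$onset_days, coh$mutation, median)
  expect_lt(abs(med[["A1"]] - 43) / 43, 0.05)
  expect_lt(abs(med[["B1"]] - 569) / 569, 0.05)

  # pure function of (spec, seed)
  expect_identical(simulate_cohort(spec, seed = 11), coh)
  expect_error(simulate_cohort(tiny_cohort_spec()[0, ]), "empty")
})

test_that("phenotype generator produces the configured monotone association", {
  coh <- simulate_cohort(default_cohort_spec(sigma_log = 0), seed = 1)
  spec <- phenotype_spec(metric = c("ric8b_coip", "flat"),
                         wt_value = c(1, 1), noise_sd = 0,
                         assoc_sign = c(-1, 0))
  tab <- simulate_phenotype_table(spec, coh, seed = 1)
  sub <- tab[is.finite(tab$onset_median_days), ]
  expect_equal(spearman_test(sub$ric8b_coip, sub$onset_median_days)$r_s, -1)
  expect_true(all(sub$flat == 1))
  # WT anchor row carries the exact wild-type values
  expect_equal(unlist(tab[tab$variant == "WT", c("ric8b_coip", "flat")]),
               c(ric8b_coip = 1, flat = 1))
  # all variants at the wild-type value -> normalisation returns 1 everywhere
  norm <- normalize_to_wildtype(tab, "WT", columns = "flat")
  expect_true(all(norm$flat == 1))
  # seeded determinism
  spec_n <- phenotype_spec("m", 1, noise_sd = 0.2, assoc_sign = 1)
  expect_identical(simulate_phenotype_table(spec_n, coh, seed = 3),
                   simulate_phenotype_table(spec_n, coh, seed = 3))
  # unknown variants in explicit means are rejected
  expect_error(
    simulate_phenotype_table(spec, coh, variant_means = list(
      ric8b_coip = c(X999Z = 1))),
    "unknown variant")
})
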