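test_that("localisation ratios are plain region/total quotients", {
  expect_equal(localization_ratio(50, 100), 0.5)
  expect_equal(localization_ratio(80, 80), 1)
  # batch against a spreadsheet-style hand computation
  region <- c(12, 40, 7.5, 90, 33, 18, 60, 25, 5, 100)
  total <- c(48, 50, 30, 120, 66, 72, 75, 125, 40, 100)
  expect_equal(localization_ratio(region, total),
               c(0.25, 0.8, 0.25, 0.75, 0.5, 0.25, 0.8, 0.2, 0.125, 1))
  expect_error(localization_ratio(10, 0), "total_mean")
})

test_that("delta-BRET is the post- minus pre-injection window mean", {
  t <- seq(0, 80, by = 1.6)
  flatline <- rep(1, length(t))
  expect_equal(delta_bret(t, flatline, injection_time = 30), 0)
  step <- ifelse(t > 30, 1.05, 1.00)
  expect_equal(delta_bret(t, step, injection_time = 30), 0.05)
  # shift invariance
  expect_equal(delta_bret(t, step + 0.7, injection_time = 30), 0.05)
  expect_error(delta_bret(t, step, injection_time = 30, pre_window = 0.1),
               ">= 2 reads")
})

test_that("wild-type normalisation is exact and idempotent", {
  tab <- data.frame(variant = c("WT", "MUT"), expression = c(2.0, 0.7),
                    onset_median_days = c(NA, 100))
  norm <- normalize_to_wildtype(tab)
  expect_equal(norm$expression, c(1.0, 0.35))  # 35% of wild type
  expect_identical(normalize_to_wildtype(norm), norm)
  expect_error(normalize_to_wildtype(tab, reference = "NONE"), "exactly once")
  tab$expression[1] <- 0
  expect_error(normalize_to_wildtype(tab), "must be > 0")
})

test_that("Spearman r_s handles perfect monotone and anti-monotone inputs", {
  expect_equal(spearman_test(1:4, c(10, 20, 30, 40))$r_s, 1)
  expect_equal(spearman_test(1:4, c(40, 30, 20, 10))$r_s, -1)
  expect_error(spearman_test(1:4, rep(1, 4)), "constant")
  expect_error(spearman_test(1:2, 1:2), "n >= 3")
})

test_that("exact Spearman p matches exhaustive enumeration, ties included", {
  # tie case, n = 6: brute force over all 720 rank permutations with cor()
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.0, 2.0, 3.1, 1.0, 5.5, 4.2)   # one tie pair
  res <- spearman_test(x, y)
  expect_identical(res$method, "exact_permutation")
  ry <- rank(y)
  perms <- gnaokin:::.perm_matrix(6)
  r_all <- apply(perms, 1, function(p) cor(rank(x), ry[p]))
  expect_equal(res$r_s, cor(rank(x), ry))
  expect_equal(res$p_value, mean(abs(r_all) >= abs(res$r_s) - 1e-12))
})

test_that("Spearman is invariant under strictly monotone transforms", {
  withr::with_seed(21, {
    for (i in 1:20) {
      x <- rnorm(7); y <- rnorm(7)
      a <- spearman_test(x, y)
      b <- spearman_test(exp(x), y^3 + 2 * y)
      expect_equal(a$r_s, b$r_s)
      expect_equal(a$p_value, b$p_value)
    }
  })
})

test_that("Spearman p-value branches agree with cor.test where comparable", {
  withr::with_seed(31, {
    # exact branch vs cor.test's exact distribution (no ties)
    for (i in 1:20) {
      x <- rnorm(7); y <- rnorm(7)
      ours <- spearman_test(x, y)
      ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                       exact = TRUE))
      expect_equal(ours$r_s, unname(ref$estimate))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    }
    # t-approximation branch at larger n
    x <- rnorm(20); y <- x + rnorm(20)
    ours <- spearman_test(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = FALSE)
    expect_identical(ours$method, "t_approximation")
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("Monte-Carlo Spearman path is seeded and close to exact", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 10)
  y <- c(2, 7, 1, 8, 2.8, 1.8, 2.9, 0.2, 1.1, 6)
  a <- spearman_test(x, y)        # n = 10 -> MC branch
  b <- spearman_test(x, y)
  expect_identical(a$method, "mc_permutation")
  expect_identical(a$p_value, b$p_value)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
  expect_equal(a$p_value, ref$p.value, tolerance = 0.02)
})

test_that("Mann-Whitney U and exact p match hand enumeration", {
  res <- mann_whitney_test(c(1, 2, 3), c(10, 20, 30))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)  # 2/20 of C(6,3) assignments
  expect_identical(res$method, "exact_enumeration")
  # identical samples: p = 1 under the exchangeable null
  expect_equal(mann_whitney_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(mann_whitney_test(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney agrees with wilcox.test and the brute-force oracle", {
  withr::with_seed(41, {
    for (i in 1:25) {
      n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
      a <- rnorm(n1); b <- rnorm(n2)
      ours <- mann_whitney_test(a, b)
      ref <- wilcox.test(a, b, exact = TRUE)
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    }
    # tie-handling against the independent enumeration oracle
    for (i in 1:10) {
      a <- sample(1:4, 4, replace = TRUE)
      b <- sample(1:4, 3, replace = TRUE)
      ours <- mann_whitney_test(a, b)
      orc <- oracle_mw(a, b)
      expect_equal(ours$statistic, orc$u)
      expect_equal(ours$p_value, orc$p)
    }
    # normal-approximation branch vs wilcox.test with correction
    a <- rnorm(10); b <- rnorm(10) + 0.5
    ours <- mann_whitney_test(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_identical(ours$method, "normal_approximation")
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("biomarker ranking recovers a noiseless informative metric", {
  coh <- simulate_cohort(default_cohort_spec(sigma_log = 0), seed = 1)
  spec <- phenotype_spec(
    metric = c("ric8b_coip", "noise1", "noise2"),
    wt_value = c(1, 1, 1),
    noise_sd = c(0, 0.3, 0.3),
    assoc_sign = c(-1, 0, 0))
  tab <- simulate_phenotype_table(spec, coh, seed = 2)
  rk <- rank_biomarkers(tab)
  expect_identical(rk$metric[1], "ric8b_coip")
  expect_equal(rk$r_s[1], -1)
  # invariant to row and column order
  tab2 <- tab[sample(nrow(tab)), c(1, 4, 3, 2, 5)]
  rk2 <- rank_biomarkers(tab2)
  expect_identical(rk2$metric[1], "ric8b_coip")
  expect_equal(rk2[order(rk2$metric), c("metric", "r_s", "p_value")],
               rk[order(rk$metric), c("metric", "r_s", "p_value")],
               ignore_attr = TRUE)
  # constant metric flagged, not fatal
  tab$flatline <- 1
  rk3 <- rank_biomarkers(tab)
  expect_true(is.na(rk3$r_s[rk3$metric == "flatline"]))
  expect_match(rk3$note[rk3$metric == "flatline"], "constant")
})
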