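# Shared fixtures built in code.

# default wild-type constants used across tests; ratio 2.56 by construction
wt_params <- function() kinetic_params(k_bind = 2.56e-3, k_hydr = 1.0e-3,
                                       amplitude = 100, baseline = 50)

# tiny two-mutation cohort spec
tiny_cohort_spec <- function(sigma_log = 0) {
  cohort_spec(mutation = c("G45E", "R209C"),
              disorder = c("DEE17", "NEDIM"),
              n_patients = c(3L, 3L),
              median_onset_days = c(5, 500),
              sigma_log = sigma_log)
}

# brute-force Spearman oracle: exhaustive permutation p via the d^2 formula
# (valid without ties), independent of the package's Pearson-on-ranks path
oracle_spearman_notie <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  r_obs <- 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  perms <- gnaokin:::.perm_matrix(n)
  d2 <- rowSums((matrix(ry[perms], nrow(perms), n) -
                   matrix(rx, nrow(perms), n, byrow = TRUE))^2)
  r_all <- 1 - 6 * d2 / (n * (n^2 - 1))
  list(r_s = r_obs, p = mean(abs(r_all) >= abs(r_obs) - 1e-12))
}

# brute-force Mann-Whitney oracle: U from the pair-count definition and p
# from explicit enumeration of group assignments of the pooled values
oracle_mw <- function(a, b) {
  u_of <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pool <- c(a, b)
  n1 <- length(a)
  idx <- combn(length(pool), n1)
  u_all <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  u_obs <- u_of(a, b)
  eps <- 1e-9
  list(u = u_obs,
       p = min(1, 2 * min(mean(u_all <= u_obs + eps),
                          mean(u_all >= u_obs - eps))))
}
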