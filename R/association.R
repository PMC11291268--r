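# Genotype-phenotype statistics: wild-type normalisation, localisation
# ratios, agonist-induced BRET changes, exact-permutation Spearman and
# Mann-Whitney tests, and biomarker ranking against disease onset.

#' Region-to-total localisation ratio
#'
#' Confocal images acquired with varying settings are compared through
#' ratios of mean fluorescence intensities — region (plasma membrane or
#' Golgi) over total cell — rather than absolute values.
#'
#' @param region_mean Mean region intensity, RFU (>= 0); vectorised.
#' @param total_mean Mean whole-cell intensity, RFU (> 0); vectorised.
#' @return `region_mean / total_mean`.
#' @examples
#' localization_ratio(50, 100)  # 0.5
#' @export
localization_ratio <- function(region_mean, total_mean) {
  if (any(!is.finite(total_mean)) || any(total_mean <= 0))
    stop("`total_mean` must be > 0", call. = FALSE)
  if (any(!is.finite(region_mean)) || any(region_mean < 0))
    stop("`region_mean` must be >= 0", call. = FALSE)
  region_mean / total_mean
}

#' Agonist-induced BRET change
#'
#' The BRET ratio (acceptor/donor) is averaged over a pre-injection window
#' and a post-injection window; their difference is the agonist-induced
#' delta-BRET. Defaults follow the assay layout: ~30 s of baseline reads
#' before injection and ~50 s after. The measure is invariant to any
#' additive offset of the whole series.
#'
#' @param times Read time stamps, seconds.
#' @param ratios BRET ratios, same length.
#' @param injection_time Agonist injection time, seconds.
#' @param pre_window Length of the baseline window ending at injection, s.
#' @param post_window Length of the response window starting at injection, s.
#' @return `mean(post) - mean(pre)`, BRET-ratio units.
#' @export
delta_bret <- function(times, ratios, injection_time, pre_window = 30,
                       post_window = 50) {
  stopifnot(length(times) == length(ratios), pre_window > 0, post_window > 0)
  pre <- ratios[times >= injection_time - pre_window & times < injection_time]
  post <- ratios[times > injection_time & times <= injection_time + post_window]
  if (length(pre) < 2L || length(post) < 2L)
    stop("pre- and post-injection windows must each contain >= 2 reads",
         call. = FALSE)
  mean(post) - mean(pre)
}

#' Normalise phenotype columns to a reference variant
#'
#' Each selected column is divided by its value in the reference row, so
#' the reference becomes exactly 1 (100% of wild type) and other variants
#' are expressed as fractions of it. The operation is idempotent.
#'
#' @param table Phenotype `data.frame` with a `variant` column.
#' @param reference Reference variant label (default `"WT"`).
#' @param columns Columns to normalise; `NULL` selects every numeric column
#'   except `onset_median_days`.
#' @return The table with normalised columns.
#' @export
normalize_to_wildtype <- function(table, reference = "WT", columns = NULL) {
  stopifnot(is.data.frame(table), "variant" %in% names(table))
  ref_row <- which(table$variant == reference)
  if (length(ref_row) != 1L)
    stop("reference variant '", reference, "' must appear exactly once",
         call. = FALSE)
  if (is.null(columns)) {
    columns <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                       "onset_median_days")
  }
  for (col in columns) {
    ref <- table[[col]][ref_row]
    if (!is.finite(ref) || ref <= 0)
      stop("reference value for '", col, "' must be > 0", call. = FALSE)
    table[[col]] <- table[[col]] / ref
  }
  table
}

# all permutations of 1..n as an (n! x n) index matrix, cached per n
.perm_matrix <- function(n) {
  key <- paste0("perm", n)
  if (!is.null(.gnaokin_cache[[key]])) return(.gnaokin_cache[[key]])
  pm <- if (n == 1L) matrix(1L, 1, 1) else {
    sub <- .perm_matrix(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
      rest <- seq_len(n)[-i]
      cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    }))
  }
  storage.mode(pm) <- "integer"
  .gnaokin_cache[[key]] <- pm
  pm
}

# Spearman r_s for the observed data and a matrix of permuted rank rows
.spearman_r <- function(rx, ry_mat) {
  rxc <- rx - mean(rx)
  ryc <- ry_mat - mean(ry_mat[1, ])           # row sums identical under permutation
  num <- as.vector(ryc %*% rxc)
  den <- sqrt(sum(rxc^2) * sum(ryc[1, ]^2))
  num / den
}

#' Two-tailed Spearman rank correlation test
#'
#' `r_s` is the Pearson correlation of the average-rank vectors. The
#' two-tailed p-value counts permutations with `|r| >= |r_obs|`:
#'
#' * `n <= exact_n` (default 8) — exhaustive enumeration of all `n!`
#'   permutations (`method = "exact_permutation"`), valid with ties;
#' * `exact_n < n <= mc_n` (default 12) — seeded Monte-Carlo permutation
#'   with `nperm` draws (`method = "mc_permutation"`);
#' * larger n — the t approximation
#'   `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#'   (`method = "t_approximation"`).
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param exact_n Largest n for exhaustive enumeration.
#' @param mc_n Largest n for Monte-Carlo permutation.
#' @param nperm Monte-Carlo permutation draws.
#' @param seed Seed for the Monte-Carlo path.
#' @return A list of class `correlation_result` with `r_s`, `p_value`, `n`,
#'   `method`.
#' @examples
#' spearman_test(1:4, c(10, 20, 30, 40))  # r_s = 1
#' @export
spearman_test <- function(x, y, exact_n = 8L, mc_n = 12L, nperm = 1e5L,
                          seed = 1L) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need n >= 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined for a constant vector", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  r_obs <- cor(rx, ry)
  if (n <= exact_n) {
    pm <- .perm_matrix(n)
    r_all <- .spearman_r(rx, matrix(ry[pm], nrow(pm), n))
    p <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
    method <- "exact_permutation"
  } else if (n <= mc_n) {
    perm <- withr::with_seed(as.integer(seed),
      matrix(ry[vapply(seq_len(nperm), function(i) sample.int(n),
                       integer(n))], nperm, n, byrow = TRUE))
    r_all <- .spearman_r(rx, perm)
    # add-one rule keeps the Monte-Carlo p strictly positive and valid
    p <- (sum(abs(r_all) >= abs(r_obs) - 1e-12) + 1) / (nperm + 1)
    method <- "mc_permutation"
  } else {
    tt <- r_obs * sqrt((n - 2) / max(1 - r_obs^2, .Machine$double.eps))
    p <- min(1, 2 * pt(-abs(tt), df = n - 2))
    p <- max(p, .Machine$double.xmin)
    method <- "t_approximation"
  }
  structure(list(r_s = r_obs, p_value = p, n = n, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: r_s = %.4f, p = %.4g (n = %d, %s)\n",
              x$r_s, x$p_value, x$n, x$method))
  invisible(x)
}

# U1 statistic (first sample) with average ranks, plus the exact null
# distribution of U1 under exchangeability, memoised per rank multiset
.mw_exact_dist <- function(r, n1) {
  key <- paste0("mw:", n1, ":", paste(signif(sort(r), 12), collapse = ","))
  if (!is.null(.gnaokin_cache[[key]])) return(.gnaokin_cache[[key]])
  idx <- combn(length(r), n1)
  u_all <- colSums(matrix(r[idx], nrow(idx))) - n1 * (n1 + 1) / 2
  .gnaokin_cache[[key]] <- u_all
  u_all
}

#' Two-tailed Mann-Whitney U test
#'
#' Ranks are averaged over ties; the statistic is
#' `U = R1 - n1 (n1 + 1) / 2` (rank-sum of the first sample). For
#' `n1 + n2 <= exact_limit` (default 12) the p-value is exact: all
#' `choose(n1 + n2, n1)` group assignments are enumerated and the
#' two-tailed p is `min(1, 2 * min(P(U <= u), P(U >= u)))`. Larger samples
#' use the normal approximation with tie correction and a 0.5 continuity
#' correction.
#'
#' @param a,b Numeric samples, each non-empty.
#' @param exact_limit Largest `n1 + n2` for exact enumeration.
#' @return A list of class `test_result` with `statistic` (U of `a`),
#'   `p_value`, `n1`, `n2`, `method`.
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(10, 20, 30))  # U = 0, exact p = 0.1
#' @export
mann_whitney_test <- function(a, b, exact_limit = 12L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty", call. = FALSE)
  nn <- n1 + n2
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (nn <= exact_limit) {
    u_all <- .mw_exact_dist(r, n1)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u_obs + eps),
                        mean(u_all >= u_obs - eps)))
    method <- "exact_enumeration"
  } else {
    ties <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  structure(list(statistic = u_obs, p_value = p, n1 = n1, n2 = n2,
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney test: U = %g, p = %.4g (n = %d/%d, %s)\n",
              x$statistic, x$p_value, x$n1, x$n2, x$method))
  invisible(x)
}

#' Rank candidate biomarkers by correlation with disease onset
#'
#' Every metric column of the phenotype table is Spearman-correlated with
#' the per-mutation median onset and the metrics are sorted by descending
#' `|r_s|`. All results are retained — no significance filtering is applied
#' silently; an optional Holm adjustment of the p-values can be requested.
#' Metrics that are constant across variants are flagged (`note`) and carry
#' `NA` statistics rather than failing the whole ranking.
#'
#' @param table Phenotype `data.frame` with `variant`, metric columns and
#'   `onset_median_days`; rows without onset (e.g. the WT reference) are
#'   dropped.
#' @param onset_col Name of the onset column.
#' @param adjust `"none"` (default) or `"holm"`.
#' @param ... Passed to [spearman_test()].
#' @return A `data.frame` with columns `metric`, `r_s`, `p_value`, `n`,
#'   `method`, `note`, ordered by `|r_s|` descending.
#' @export
rank_biomarkers <- function(table, onset_col = "onset_median_days",
                            adjust = c("none", "holm"), ...) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(table), onset_col %in% names(table))
  tab <- table[is.finite(table[[onset_col]]), , drop = FALSE]
  if (nrow(tab) < 3L) stop("need >= 3 variants with onset", call. = FALSE)
  metrics <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                     onset_col)
  if (length(metrics) == 0L) stop("no metric columns found", call. = FALSE)
  rows <- lapply(metrics, function(m) {
    res <- tryCatch(spearman_test(tab[[m]], tab[[onset_col]], ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(metric = m, r_s = NA_real_, p_value = NA_real_,
                 n = nrow(tab), method = NA_character_,
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(metric = m, r_s = res$r_s, p_value = res$p_value,
                 n = res$n, method = res$method, note = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_value <- stats::p.adjust(out$p_value, "holm")
  out <- out[order(-abs(out$r_s), out$metric, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
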