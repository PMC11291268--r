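# Seeded generators for every input the pipeline consumes: fluorescence
# traces with known kinetics, patient cohorts with configured group medians,
# and phenotype tables with a controllable monotone association to onset.

# Bateman (sequential first-order A -> B -> C) intermediate, the noiseless
# BODIPY-GTP model: fluorescent species is the bound, unhydrolysed ligand.
# Continuous at k_bind == k_hydr via the A*k*t*exp(-k t) limit.
.bateman <- function(t, k_bind, k_hydr, amplitude, baseline) {
  if (k_hydr == 0) return(baseline + amplitude * (1 - exp(-k_bind * t)))
  if (abs(k_bind - k_hydr) <= 1e-10 * k_bind) {
    baseline + amplitude * k_bind * t * exp(-k_bind * t)
  } else {
    baseline + amplitude * (k_bind / (k_hydr - k_bind)) *
      (exp(-k_bind * t) - exp(-k_hydr * t))
  }
}

.add_noise <- function(values, amplitude, noise) {
  if (noise$sigma_rel == 0) return(values)
  withr::with_seed(noise$seed,
    values + rnorm(length(values), sd = noise$sigma_rel * amplitude))
}

#' Simulate a BODIPY-GTPgammaS (binding-only) fluorescence trace
#'
#' The non-hydrolysable ligand gives a saturating single-exponential rise,
#' `F(t) = F0 + A * (1 - exp(-k_bind * t))`. Gaussian noise with s.d.
#' `sigma_rel * A` is added under the seed in `noise`, so the generator is a
#' pure function of its arguments.
#'
#' @param params A [kinetic_params()] object; only `k_bind`, `amplitude` and
#'   `baseline` are used.
#' @param schedule A [sampling_schedule()].
#' @param noise A [noise_model()].
#' @param variant,replicate Labels copied onto the trace.
#' @return A [fluorescence_trace()] with `ligand = "GTPgS"`.
#' @examples
#' tr <- simulate_gtpgs_trace(kinetic_params(0.01, amplitude = 100, baseline = 50),
#'                            sampling_schedule(0, 600, 121))
#' tail(tr$values, 1)  # 50 + 100 * (1 - exp(-6)) ~= 149.75
#' @export
simulate_gtpgs_trace <- function(params, schedule = sampling_schedule(),
                                 noise = noise_model(), variant = "WT",
                                 replicate = 1L) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "sampling_schedule"),
            inherits(noise, "noise_model"))
  t <- schedule$times
  f <- params$baseline + params$amplitude * (1 - exp(-params$k_bind * t))
  fluorescence_trace(t, .add_noise(f, params$amplitude, noise),
                     ligand = "GTPgS", variant = variant,
                     replicate = replicate)
}

#' Simulate a BODIPY-GTP (binding-then-hydrolysis) fluorescence trace
#'
#' The hydrolysable ligand follows the sequential first-order (Bateman)
#' intermediate: `F(t) = F0 + A * k_bind/(k_hydr - k_bind) *
#' (exp(-k_bind t) - exp(-k_hydr t))`, with the continuous limit
#' `F0 + A * k_bind * t * exp(-k_bind t)` at equal rates. For `k_hydr = 0` the
#' model reduces exactly to the binding-only form of
#' [simulate_gtpgs_trace()].
#'
#' @inheritParams simulate_gtpgs_trace
#' @return A [fluorescence_trace()] with `ligand = "GTP"`.
#' @examples
#' # rise-and-fall; analytic peak at ln(k_bind/k_hydr)/(k_bind - k_hydr)
#' tr <- simulate_gtp_trace(kinetic_params(0.02, 0.002, 100, 0))
#' tr$times[which.max(tr$values)]
#' @export
simulate_gtp_trace <- function(params, schedule = sampling_schedule(),
                               noise = noise_model(), variant = "WT",
                               replicate = 1L) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(schedule, "sampling_schedule"),
            inherits(noise, "noise_model"))
  t <- schedule$times
  f <- .bateman(t, params$k_bind, params$k_hydr, params$amplitude,
                params$baseline)
  fluorescence_trace(t, .add_noise(f, params$amplitude, noise),
                     ligand = "GTP", variant = variant, replicate = replicate)
}

#' Cohort specification for the synthetic patient generator
#'
#' @param mutation Character vector of unique mutation labels.
#' @param disorder `"DEE17"` or `"NEDIM"` per mutation.
#' @param n_patients Integer >= 1 per mutation.
#' @param median_onset_days Target median onset, days (> 0), per mutation.
#' @param sigma_log Log-scale dispersion (>= 0) per mutation; onsets are
#'   drawn log-normal so the spread is multiplicative, matching onsets that
#'   range from days to years. The default 0.5 corresponds to roughly a
#'   +/- 2-fold interquartile-scale spread around the median.
#' @return A `data.frame` of class `cohort_spec`.
#' @export
cohort_spec <- function(mutation, disorder, n_patients, median_onset_days,
                        sigma_log = 0.5) {
  if (length(mutation) == 0L) stop("empty cohort specification", call. = FALSE)
  if (anyDuplicated(mutation))
    stop("mutation labels must be unique", call. = FALSE)
  if (!all(disorder %in% c("DEE17", "NEDIM")))
    stop("`disorder` must be DEE17 or NEDIM", call. = FALSE)
  n_patients <- as.integer(n_patients)
  if (any(n_patients < 1L)) stop("`n_patients` must be >= 1", call. = FALSE)
  if (any(median_onset_days <= 0))
    stop("`median_onset_days` must be > 0", call. = FALSE)
  if (any(sigma_log < 0)) stop("`sigma_log` must be >= 0", call. = FALSE)
  out <- data.frame(mutation = as.character(mutation),
                    disorder = as.character(disorder),
                    n_patients = n_patients,
                    median_onset_days = as.numeric(median_onset_days),
                    sigma_log = as.numeric(rep_len(sigma_log, length(mutation))),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_spec", "data.frame")
  out
}

#' Bundled synthetic cohort specification
#'
#' Loads the synthetic per-mutation cohort table shipped with the package
#' (`inst/extdata/cohort_spec_synthetic.csv`). The table is a *synthetic
#' reconstruction*: per-mutation median onsets and patient counts were chosen
#' to be jointly consistent with the published onset classes and group-level
#' summaries (29 DEE17 patients with median onset 43 days, 31 NEDIM patients
#' with median 569 days, 13 patients carrying biochemically inactive
#' mutations with median 31 days). Individual patient onsets are not real
#' data.
#'
#' @param sigma_log Optional override of the per-mutation dispersion column
#'   (a single value recycled to all mutations); `NULL` keeps the stored
#'   values.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(sigma_log = NULL) {
  path <- system.file("extdata", "cohort_spec_synthetic.csv",
                      package = "gnaokin", mustWork = TRUE)
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(sigma_log)) tab$sigma_log <- sigma_log
  cohort_spec(tab$mutation, tab$disorder, tab$n_patients,
              tab$median_onset_days, tab$sigma_log)
}

#' Simulate a patient cohort
#'
#' For each mutation, `n_patients` onsets are drawn log-normally with median
#' `median_onset_days` and log-s.d. `sigma_log`, then rounded to whole days
#' (clinical reporting convention). With `sigma_log = 0` every patient gets
#' exactly the configured median.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; identical `(spec, seed)` give identical cohorts.
#' @return A `data.frame` with columns `patient_id`, `mutation`,
#'   `onset_days`, `disorder`.
#' @examples
#' spec <- cohort_spec(c("G45E", "R209C"), c("DEE17", "NEDIM"),
#'                     c(3, 3), c(5, 500), sigma_log = 0)
#' simulate_cohort(spec, seed = 1)
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (nrow(spec) == 0L) stop("empty cohort specification", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(nrow(spec)), function(i) {
      n <- spec$n_patients[i]
      onset <- exp(log(spec$median_onset_days[i]) +
                     spec$sigma_log[i] * rnorm(n))
      data.frame(mutation = spec$mutation[i],
                 onset_days = as.integer(pmax(0, round(onset))),
                 disorder = spec$disorder[i],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- data.frame(patient_id = sprintf("P%03d", seq_len(nrow(out))), out,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Phenotype-metric specification for the synthetic generator
#'
#' Each metric gets a wild-type value, an absolute Gaussian noise s.d., an
#' association sign with disease onset (-1, 0 or +1) and an association
#' strength (relative spread of the per-variant target means).
#'
#' @param metric Unique metric names.
#' @param wt_value Wild-type value per metric (> 0 for normalisable metrics).
#' @param noise_sd Gaussian noise s.d. per metric (>= 0), same units as the
#'   metric.
#' @param assoc_sign -1, 0 or +1: the sign of the Spearman correlation with
#'   per-mutation median onset that the noiseless construction produces.
#' @param assoc_strength Half-range of the target means relative to
#'   `wt_value` (default 0.8: means span `wt_value * (1 +/- 0.8)`).
#' @return A `data.frame` of class `phenotype_spec`.
#' @export
phenotype_spec <- function(metric, wt_value, noise_sd = 0, assoc_sign = 0,
                           assoc_strength = 0.8) {
  if (length(metric) == 0L) stop("empty phenotype specification", call. = FALSE)
  if (anyDuplicated(metric)) stop("metric names must be unique", call. = FALSE)
  if (any(noise_sd < 0)) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!all(assoc_sign %in% c(-1, 0, 1)))
    stop("`assoc_sign` must be -1, 0 or 1", call. = FALSE)
  out <- data.frame(metric = as.character(metric),
                    wt_value = as.numeric(wt_value),
                    noise_sd = as.numeric(rep_len(noise_sd, length(metric))),
                    assoc_sign = as.numeric(rep_len(assoc_sign, length(metric))),
                    assoc_strength = as.numeric(rep_len(assoc_strength, length(metric))),
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_spec", "data.frame")
  out
}

#' Default phenotype-metric specification
#'
#' The nine molecular readouts quantified per variant: expression (% of wild
#' type), plasma-membrane and Golgi localisation ratios, co-IP levels with
#' Gbetagamma, RGS19, Ric8A and Ric8B, the Ric8B Golgi relocalisation ratio,
#' and the agonist-induced BRET change. Association signs encode the
#' headline direction of each readout versus onset (e.g. Ric8B co-IP is
#' strongest in early-onset variants, hence negative).
#'
#' @return A [phenotype_spec()].
#' @export
default_phenotype_spec <- function() {
  phenotype_spec(
    metric = c("expression", "pm_ratio", "golgi_ratio", "gbg_coip",
               "rgs19_coip", "ric8a_coip", "ric8b_coip", "ric8b_golgi_ratio",
               "delta_bret"),
    wt_value = c(100, 0.35, 0.25, 1, 1, 0.1, 0.1, 0.2, 0.02),
    noise_sd = c(15, 0.05, 0.04, 0.2, 0.1, 0.3, 0.25, 0.05, 0.01),
    assoc_sign = c(0, 1, 0, 1, 0, -1, -1, -1, -1),
    assoc_strength = 0.8)
}

#' Simulate a per-variant phenotype table
#'
#' One row per mutation present in `cohort` (plus, by default, an exact
#' wild-type reference row). For each metric the per-variant target mean is a
#' monotone map of the per-mutation median onset — rank-scaled to `[-1, 1]`,
#' multiplied by `assoc_sign * assoc_strength * wt_value` and added to
#' `wt_value` — so the noiseless Spearman correlation with onset has exactly
#' the configured sign. Gaussian noise (`noise_sd`) is added and values are
#' clipped at 0. Explicit per-variant means can be supplied to override the
#' monotone construction.
#'
#' @param spec A [phenotype_spec()].
#' @param cohort A cohort `data.frame` from [simulate_cohort()].
#' @param seed Integer seed.
#' @param variant_means Optional named list `metric -> named numeric vector`
#'   of per-variant target means; variant names must exist in the cohort.
#' @param include_reference Add a `"WT"` row carrying the exact `wt_value`s
#'   (no noise) with `onset_median_days = NA`, used as the normalisation
#'   anchor.
#' @return A `data.frame` with `variant`, one column per metric, and
#'   `onset_median_days`.
#' @export
simulate_phenotype_table <- function(spec, cohort, seed = 1L,
                                     variant_means = NULL,
                                     include_reference = TRUE) {
  stopifnot(inherits(spec, "phenotype_spec"), is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  med <- aggregate(onset_days ~ mutation, data = cohort, FUN = median)
  variants <- med$mutation
  onset <- med$onset_days
  if (!is.null(variant_means)) {
    bad <- setdiff(unlist(lapply(variant_means, names)), variants)
    if (length(bad))
      stop("unknown variant(s) in `variant_means`: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(variants)
  # rank-scaled onset in [-1, 1]; average ranks keep ties neutral
  z <- if (n > 1) 2 * (rank(onset) - 1) / (n - 1) - 1 else rep(0, n)
  withr::with_seed(as.integer(seed), {
    cols <- lapply(seq_len(nrow(spec)), function(j) {
      m <- spec$wt_value[j] *
        (1 + spec$assoc_sign[j] * spec$assoc_strength[j] * z)
      if (!is.null(variant_means) && spec$metric[j] %in% names(variant_means)) {
        vm <- variant_means[[spec$metric[j]]]
        m[match(names(vm), variants)] <- vm
      }
      pmax(0, m + if (spec$noise_sd[j] > 0)
        rnorm(n, sd = spec$noise_sd[j]) else 0)
    })
    names(cols) <- spec$metric
    out <- data.frame(variant = variants, cols,
                      onset_median_days = onset,
                      stringsAsFactors = FALSE, check.names = FALSE)
    if (include_reference && !"WT" %in% variants) {
      wt <- data.frame(variant = "WT",
                       as.list(setNames(spec$wt_value, spec$metric)),
                       onset_median_days = NA_real_,
                       stringsAsFactors = FALSE, check.names = FALSE)
      out <- rbind(wt, out)
    }
    rownames(out) <- NULL
    out
  })
}
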