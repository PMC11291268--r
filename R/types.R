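#' Kinetic parameters of a Gao variant
#'
#' Bundles the two first-order rate constants of the nucleotide cycle with
#' the amplitude and baseline of the fluorescence readout. `k_bind` is the
#' pseudo-first-order GTP uptake constant (the fluorescence rise), `k_hydr`
#' the hydrolysis constant (the decay of the BODIPY-GTP signal).
#'
#' @param k_bind GTP uptake rate constant, 1/s; must be > 0.
#' @param k_hydr GTP hydrolysis rate constant, 1/s; must be >= 0 (0 models a
#'   non-hydrolysable ligand or a GTPase-dead variant).
#' @param amplitude Fluorescence amplitude A, relative fluorescence units
#'   (RFU); must be >= 0.
#' @param baseline Baseline fluorescence F0, RFU.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(k_bind = 0.01, k_hydr = 0.002, amplitude = 100, baseline = 50)
#' @export
kinetic_params <- function(k_bind, k_hydr = 0, amplitude = 100, baseline = 0) {
  stopifnot(is.numeric(k_bind), length(k_bind) == 1L, is.finite(k_bind),
            is.numeric(k_hydr), length(k_hydr) == 1L, is.finite(k_hydr),
            is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude),
            is.numeric(baseline), length(baseline) == 1L, is.finite(baseline))
  if (k_bind <= 0) stop("`k_bind` must be > 0", call. = FALSE)
  if (k_hydr < 0) stop("`k_hydr` must be >= 0", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  structure(list(k_bind = k_bind, k_hydr = k_hydr,
                 amplitude = amplitude, baseline = baseline),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic parameters: k_bind = %.4g 1/s, k_hydr = %.4g 1/s, A = %.4g RFU, F0 = %.4g RFU\n",
              x$k_bind, x$k_hydr, x$amplitude, x$baseline))
  invisible(x)
}

#' Uniform sampling schedule for a plate-reader time course
#'
#' @param t_start First time point, seconds (>= 0).
#' @param t_end Last time point, seconds (> `t_start`).
#' @param n_points Number of equally spaced samples (>= 2). The default
#'   schedule, 0-3600 s every 5 s, is long enough for the rise-and-fall of a
#'   slowly hydrolysing variant to be visible.
#' @return An object of class `sampling_schedule` with a `times` vector.
#' @export
sampling_schedule <- function(t_start = 0, t_end = 3600, n_points = 721L) {
  stopifnot(is.numeric(t_start), length(t_start) == 1L,
            is.numeric(t_end), length(t_end) == 1L,
            is.numeric(n_points), length(n_points) == 1L)
  if (t_start < 0 || !is.finite(t_start)) stop("`t_start` must be >= 0", call. = FALSE)
  if (t_end <= t_start) stop("`t_end` must exceed `t_start`", call. = FALSE)
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("`n_points` must be >= 2", call. = FALSE)
  structure(list(t_start = t_start, t_end = t_end, n_points = n_points,
                 times = seq(t_start, t_end, length.out = n_points)),
            class = "sampling_schedule")
}

#' Measurement noise model for simulated fluorescence traces
#'
#' Plate-reader read noise is approximated as iid Gaussian with a standard
#' deviation proportional to the trace amplitude, so the signal-to-noise
#' ratio is the single knob `sigma_rel`.
#'
#' @param sigma_rel Noise s.d. as a fraction of the amplitude (>= 0).
#' @param seed Integer RNG seed; generators are pure functions of
#'   (parameters, schedule, seed).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_rel = 0, seed = 1L) {
  stopifnot(is.numeric(sigma_rel), length(sigma_rel) == 1L,
            is.numeric(seed), length(seed) == 1L)
  if (sigma_rel < 0) stop("`sigma_rel` must be >= 0", call. = FALSE)
  structure(list(sigma_rel = sigma_rel, seed = as.integer(seed)),
            class = "noise_model")
}

#' Construct a fluorescence trace
#'
#' One time-resolved BODIPY assay well. Times must be strictly increasing and
#' values finite; `ligand` records whether the well contained the
#' non-hydrolysable BODIPY-GTPgammaS ("GTPgS", binding only) or BODIPY-GTP
#' ("GTP", binding then hydrolysis).
#'
#' @param times Time points, seconds, strictly increasing, length >= 2.
#' @param values Fluorescence, RFU, same length as `times`.
#' @param ligand `"GTPgS"` or `"GTP"`.
#' @param variant Variant label (e.g. `"WT"`, `"L199P"`).
#' @param replicate Optional replicate identifier.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(times, values, ligand = c("GTPgS", "GTP"),
                               variant = "WT", replicate = 1L) {
  ligand <- match.arg(ligand)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2L) stop("a trace needs at least 2 samples", call. = FALSE)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  structure(list(times = times, values = values, ligand = ligand,
                 variant = as.character(variant), replicate = replicate),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace: %s / BODIPY-%s, %d points, t = [%g, %g] s, F = [%.4g, %.4g] RFU\n",
              x$variant, x$ligand, length(x$times),
              min(x$times), max(x$times), min(x$values), max(x$values)))
  invisible(x)
}

#' Cellular context for the nucleotide-cycling model
#'
#' The cycling equations are linear in the bound species, so the nucleotide
#' excesses do not enter the dynamics; they are carried for provenance and
#' reporting, matching the assumed cellular context of ~10 uM Gao, a ~100-fold
#' excess of guanine nucleotides over G protein and a ~10-fold excess of free
#' GTP over GDP.
#'
#' @param total_Gao Total Gao concentration, uM (> 0).
#' @param gtp_gdp_excess Free GTP : GDP excess (> 0); provenance only.
#' @param nucleotide_excess_over_G Nucleotide : G-protein excess (> 0);
#'   provenance only.
#' @param init_fraction_gtp Fraction of Gao initially GTP-loaded, in `[0, 1]`.
#'   Defaults to 0: purified protein is GDP-loaded.
#' @return An object of class `cycling_config`.
#' @export
cycling_config <- function(total_Gao = 10, gtp_gdp_excess = 10,
                           nucleotide_excess_over_G = 100,
                           init_fraction_gtp = 0) {
  stopifnot(is.numeric(total_Gao), total_Gao > 0,
            is.numeric(gtp_gdp_excess), gtp_gdp_excess > 0,
            is.numeric(nucleotide_excess_over_G), nucleotide_excess_over_G > 0,
            is.numeric(init_fraction_gtp),
            init_fraction_gtp >= 0, init_fraction_gtp <= 1)
  structure(list(total_Gao = total_Gao, gtp_gdp_excess = gtp_gdp_excess,
                 nucleotide_excess_over_G = nucleotide_excess_over_G,
                 init_fraction_gtp = init_fraction_gtp),
            class = "cycling_config")
}
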