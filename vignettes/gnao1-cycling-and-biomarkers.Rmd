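---
title: "Nucleotide cycling kinetics and biomarker ranking for GNAO1 encephalopathy variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleotide cycling kinetics and biomarker ranking for GNAO1 encephalopathy variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnaokin)
```

## Background

Missense mutations in *GNAO1*, the gene encoding the neuronal heterotrimeric
G-protein alpha subunit Gαo, cause two pediatric encephalopathies that are
distinguished clinically: DEE17 (developmental and epileptic
encephalopathy-17, with epilepsy, typically very early onset) and NEDIM
(neurodevelopmental disorder with involuntary movements, milder and later in
onset). Characterising a panel of pathogenic Gαo variants biochemically and
cellularly — nucleotide handling, localisation, partner binding — and
correlating those molecular phenotypes with the clinical score (disease
onset) is the analysis this package implements as reusable, tested code.

The package covers four quantitative layers, plus the synthetic-data
generators that make the whole chain testable without any laboratory input.

## The kinetic model of BODIPY fluorescence traces

Purified Gαo incubated with a fluorescent nucleotide analog reports its
nucleotide handling as a fluorescence time course:

* **BODIPY-GTPγS** is non-hydrolysable, so fluorescence follows binding
  only — a saturating single-exponential rise,
  $$F(t) = F_0 + A\,(1 - e^{-k_\mathrm{bind} t}).$$
* **BODIPY-GTP** is bound and then hydrolysed, and the fluorescent bound
  species is the intermediate of the irreversible two-step sequence
  free → bound → hydrolysed. Its concentration follows the classical
  sequential first-order (Bateman) form,
  $$F(t) = F_0 + A\,\frac{k_\mathrm{bind}}{k_\mathrm{hydr}-k_\mathrm{bind}}
  \left(e^{-k_\mathrm{bind} t} - e^{-k_\mathrm{hydr} t}\right),$$
  with the continuous limit $F_0 + A\,k_\mathrm{bind}\,t\,
  e^{-k_\mathrm{bind} t}$ at equal rates, and exact reduction to the
  binding-only form when $k_\mathrm{hydr} = 0$.

This is the minimal model carrying exactly the two constants of interest:
the pseudo-first-order GTP uptake constant $k_\mathrm{bind}$ and the
hydrolysis constant $k_\mathrm{hydr}$, both in s⁻¹. We deliberately do not
model a residual fluorescence of bound product (a post-hydrolysis plateau
above $F_0$): the model decays back to its starting level, which is also
what the projected-baseline extrapolation below assumes. An assay that does
show a stable elevated plateau would need that extension; the fit result's
`rmse` makes such misfit visible.

### Fitting and the two baseline conventions

`fit_binding_rate()` fits the single-exponential to a GTPγS trace;
`fit_gtp_kinetics()` jointly fits $(k_\mathrm{bind}, k_\mathrm{hydr}, A,
F_0)$ to a GTP trace by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`, objective tolerance 1e-10, bounds
$k_\mathrm{bind} > 0$, $k_\mathrm{hydr} \ge 0$, $A \ge 0$). Starting values
are derivative-free and robust: $k_\mathrm{bind}$ from the time to half the
observed rise, $k_\mathrm{hydr}$ from the log-slope of the decaying flank,
$A$ from the peak height via the equal-rate peak relation.

Two baseline conventions are branched on automatically:

* **direct** — hydrolysis ran essentially to completion: the terminal value
  has decayed back to within a configurable fraction (default 10%) of the
  peak excursion above the initial value. The end point anchors the
  baseline; $F_0$ is initialised there but left free in the joint fit.
  (Fixing it would inject a small bias whenever the window is a few
  hydrolysis half-lives rather than many.)
* **extrapolated** — for strongly hydrolysis-impaired variants the assay
  window ends long before the decay completes, so the terminal value says
  nothing about the baseline. Here $F_0$ is *fixed* at the initial
  fluorescence value — the level the Bateman curve provably returns to —
  and the three remaining parameters are fitted. The 10 % switch criterion
  is a package choice; the underlying assay protocol leaves it implicit.

A GTP trace that only rises (hydrolysis indistinguishable from zero) is not
an error: the fit returns $k_\mathrm{hydr}$ at its lower bound 0 with a
wide-uncertainty note, matching the behaviour of a GTPase-dead variant.

Variants with no measurable nucleotide binding are screened out *before*
fitting by `classify_activity()`: a trace is inactive when its empirical
amplitude (maximum minus initial value) is below $k\sigma$ with default
$k = 3$, $\sigma$ estimated from early-time residuals when not supplied.
The threshold operationalises "no measurable binding"; a trace exactly at
$3\sigma$ classifies as active, i.e. ties resolve toward attempting a fit.

## The GDP/GTP cycling model

In a cell without GEFs, GAPs or GDIs, and with guanine nucleotides in large
excess over the G protein (so both rate constants are effectively
first-order), Gαo shuttles between its GDP- and GTP-bound states:

$$\frac{d[\mathrm{G\alpha o^{GDP}}]}{dt} =
  k_\mathrm{hydr}[\mathrm{G\alpha o^{GTP}}] -
  k_\mathrm{bind}[\mathrm{G\alpha o^{GDP}}], \qquad
\frac{d[\mathrm{G\alpha o^{GTP}}]}{dt} =
  k_\mathrm{bind}[\mathrm{G\alpha o^{GDP}}] -
  k_\mathrm{hydr}[\mathrm{G\alpha o^{GTP}}].$$

`simulate_cycle()` integrates this two-state linear system with a
fixed-step classical 4th-order Runge–Kutta scheme. A fixed step — auto-
shrunk so $(k_\mathrm{bind}+k_\mathrm{hydr})\,\Delta t \le 0.01$ — is the
right tool here: the system is linear and stiffness-free at these rates,
and a fixed-step scheme yields byte-reproducible trajectories with no
adaptive-solver nondeterminism. The derivatives sum to zero exactly, so
total Gαo is conserved to floating-point accuracy along every trajectory
(asserted at 1e-9 relative in the tests). Integration stops when the
relative per-step change drops below 1e-12 or the horizon (default
$40/(k_\mathrm{bind}+k_\mathrm{hydr})$) is reached; which one fired is
recorded.

At equilibrium the fluxes balance, giving the closed form

$$\frac{[\mathrm{G\alpha o^{GTP}}]}{[\mathrm{G\alpha o^{GDP}}]} =
  \frac{k_\mathrm{bind}}{k_\mathrm{hydr}},$$

exposed as `steady_state_ratio()` and asserted against the numerical
equilibrium at 1e-6 relative on a 100-point random rate grid. Since the
package computes both routes, any numerical-settings discrepancy between
them would be caught rather than silently absorbed. The GTPase-dead limit
$k_\mathrm{hydr}=0$ is handled as a typed `Inf` sentinel (all Gαo ends
GTP-loaded), never as a numeric overflow. The cellular context (total Gαo
10 µM, ~100-fold nucleotide excess, ~10-fold GTP:GDP excess) is carried in
`cycling_config()` for provenance; because both constants are lumped
first-order, those excesses do not enter the dynamics, and every reported
quantity — the ratio and its fold-change versus wild type
(`ratio_fold_change()`) — is invariant to the absolute rate scale. The
package's default wild-type pair ($k_\mathrm{bind}$ 2.56e-3,
$k_\mathrm{hydr}$ 1.0e-3 s⁻¹) encodes the wild-type GTP/GDP ratio of 2.56
with an arbitrary but realistic absolute scale.

## The clinical score

Disease onset in postnatal days is the clinical score. `classify_onset()`
maps it to the four half-open classes very early $[0,10)$, early
$[10,90)$, late $[90,730)$ and very late $[730,\infty)$. The month/year
boundaries use the round clinical conversions 3 months = 90 d and
2 years = 730 d; both are configurable because day equivalents are a
convention, not a measurement. Medians are always taken over *patients*,
not over per-mutation medians, with the usual mean-of-central-pair rule
for even groups.

The mutation dictionary (`gnao1_mutations()`, shipped as an editable CSV)
records, for the 17 studied mutations plus Q52P, the OMIM disorder (DEE17
or NEDIM), the assigned onset class and the biochemical activity status.
Q52P is included with activity status (inactive) and the same onset class
as Q52R so it can participate in the inactive-group summary, although it
is not among the systematically characterised variants.

## Genotype–phenotype statistics

All correlation claims use the two-tailed Spearman rank correlation
(`spearman_test()`): $r_s$ is the Pearson correlation of average-rank
vectors, and the p-value is computed by exhaustive permutation enumeration
for $n \le 8$ (exact, valid under ties), seeded Monte-Carlo permutation
(100,000 draws) for $9 \le n \le 12$, and the $t$ approximation beyond.
Group comparisons use the two-tailed Mann–Whitney U test
(`mann_whitney_test()`) with average-rank ties, exact enumeration of all
$\binom{n_1+n_2}{n_1}$ assignments for $n_1+n_2 \le 12$ and the
tie-corrected, continuity-corrected normal approximation beyond. The
exact/approximate thresholds are feasibility choices (8! = 40,320
permutations and $\binom{12}{6} = 924$ assignments enumerate instantly);
both implementations are property-tested against independent brute-force
oracles and against `cor.test()`/`wilcox.test()` where those offer exact
references.

`rank_biomarkers()` correlates every phenotype metric against per-mutation
median onset and sorts by $|r_s|$. No multiple-testing correction is
applied by default — per-metric $r_s$ and p are reported as-is, which is
how such screens are usually read — but a Holm adjustment flag is
available. Onset enters on the day scale; displaying onset on a log axis
(as severity plots usually do) cannot change any rank statistic.
Supporting quantifications follow the field's conventions:
`localization_ratio()` (region mean over total-cell mean fluorescence,
robust to per-image acquisition settings), `normalize_to_wildtype()`
(idempotent division by the reference row) and `delta_bret()` (mean
post-injection minus mean pre-injection BRET ratio, windows defaulting to
the ~30 s baseline and ~50 s response reads, invariant to additive
offsets).

## What the synthetic generators emulate — and what they do not

`simulate_gtpgs_trace()`/`simulate_gtp_trace()` produce noiseless model
curves plus iid Gaussian noise with s.d. proportional to the amplitude
(`sigma_rel`, a single SNR knob approximating plate-reader read noise).
The default schedule is 0–3600 s at 5 s cadence — long enough to show the
rise-and-fall that the extrapolation rule needs; the true acquisition
cadence of a plate reader is instrument-dependent and configurable here.
Fluorescence is in arbitrary RFU since absolute units carry no
information for rate fitting.

`simulate_cohort()` draws per-patient onsets log-normally around each
mutation's median (onsets span days to years, so multiplicative spread is
the natural scale; log-s.d. defaults to 0.5) and rounds to whole days.
The bundled `default_cohort_spec()` is a *synthetic reconstruction*: its
per-mutation medians and patient counts were constructed once to be
jointly consistent with the published group-level facts (29 DEE17
patients, median 43 d; 31 NEDIM patients, median 569 d; 13 patients with
biochemically inactive mutations, median 31 d; each mutation's onset
class). Individual rows are not real patients.

`simulate_phenotype_table()` maps per-mutation median onset through a
rank-scaled monotone function (sign and strength per metric) and adds
Gaussian noise, clipped at zero. This construction makes the *sign* of
the noiseless Spearman correlation with onset exactly controllable, which
is what the ranking tests need; it is deliberately not a copula and does
not emulate between-metric correlation structure.

Consequently, passing tests demonstrate that the estimators and statistics
recover known ground truth under these idealised conditions — iid noise,
exact model form, independent metrics. They do not certify behaviour under
real-data pathologies (drifting baselines, correlated residuals,
non-lognormal onset outliers), which is the usual caveat of
simulation-validated pipelines.

## Numerical and design choices, collected

* Optimizer: Levenberg–Marquardt, `ftol = ptol = 1e-10`; non-convergence
  is surfaced as a warning plus `converged = FALSE`, never masked.
* Direct-vs-extrapolated branch: 10 % of peak excursion (configurable).
* Inactivity threshold: amplitude $< 3\sigma$; ties active; non-positive
  amplitude always inactive.
* Integrator: RK4, $(k_\mathrm{bind}+k_\mathrm{hydr})\Delta t \le 0.01$,
  per-step equilibrium tolerance 1e-12, hard cap of 5e6 steps.
* Fold-changes are ratios of fitted constants (not means of per-replicate
  ratios); values below 1 are reported as fold-decreases with a direction
  flag.
* Exact-test limits: $n \le 8$ (Spearman), $n_1+n_2 \le 12$
  (Mann–Whitney); Monte-Carlo p-values use the add-one rule so they are
  never zero.
* All generators are pure functions of (specification, seed); pipeline
  artifacts carry provenance headers (package version, seed).

## Problem sizes used in the test suite

The property suites run at sizes chosen to make the statistical assertions
sharp while keeping a full check fast on a laptop: 100 random rate pairs
for the ODE-vs-closed-form grid, 200 replicate traces for the
binding-rate bias check (tolerance 2 % at 2 % noise), 1,000 random small
samples against the brute-force rank-test oracles, 10,000 null
replicates for the Mann–Whitney type-I bound, and 500 seeded replicates
for the biomarker-ranking recovery study at signal-to-noise 5.

## End-to-end example

```{r pipeline, eval = FALSE}
out <- run_pipeline(tempfile("gnaokin-demo-"), seed = 1)
out$cycling          # steady-state GTP/GDP ratios and fold vs wild type
out$group_summaries  # onset medians by disorder and by activity
head(out$biomarkers) # metrics ranked by |r_s| against onset
```

## Known limitations

* The Bateman model assumes irreversible binding and hydrolysis and no
  fluorescent product; reversible exchange or a fluorescent GDP-bound
  state would bias $k_\mathrm{hydr}$ low.
* Near $k_\mathrm{bind} \approx k_\mathrm{hydr}$ the two constants are
  weakly identifiable from a single noisy trace; replicate averaging (as
  in the bias study) is the remedy.
* The cycling model deliberately excludes GEF/GAP/GDI regulation; its
  ratios describe the isolated protein's propensity, not the cellular
  steady state under receptor drive.
* The synthetic cohort reproduces group medians by construction; it
  cannot stand in for real per-patient clinical data in any inferential
  sense.
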