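# gnaokin

Quantitative analysis of pathogenic Gαo (*GNAO1*) variants: kinetic fitting
of fluorescent-nucleotide binding/hydrolysis assays, the GDP/GTP
nucleotide-cycling model, onset-based clinical scoring, and the rank
statistics that connect molecular phenotypes to disease severity.

## The problem

De novo missense mutations in *GNAO1*, encoding the major neuronal
G-protein α subunit Gαo, cause two pediatric encephalopathies: the severe,
epileptic **DEE17** and the milder **NEDIM**. Characterising a variant
means answering, quantitatively:

1. How fast does the purified protein take up and hydrolyse GTP? BODIPY
   fluorescence time courses are fit with a single-exponential rise
   (BODIPY-GTPγS, binding only),
   `F(t) = F0 + A (1 − exp(−k_bind t))`, or with the sequential
   first-order (Bateman) intermediate (BODIPY-GTP, binding then
   hydrolysis),
   `F(t) = F0 + A · k_bind/(k_hydr − k_bind) · (exp(−k_bind t) − exp(−k_hydr t))`,
   yielding the rate constants `k_bind` and `k_hydr` (s⁻¹). For variants
   whose hydrolysis is too slow to complete within the assay, the baseline
   is projected from the initial fluorescence value and `k_hydr`
   extrapolated.
2. What nucleotide state does that imply in a cell? The two-state cycle
   `d[Gαo·GDP]/dt = k_hydr [Gαo·GTP] − k_bind [Gαo·GDP]` (and its mirror)
   is integrated to equilibrium; the steady-state occupancy ratio
   `[Gαo·GTP]/[Gαo·GDP] = k_bind/k_hydr` and its fold-change versus wild
   type summarise each variant.
3. How severe is the disease? Onset in postnatal days is the clinical
   score, classified into very early (<10 d), early (10 d–3 mo), late
   (3 mo–2 y) and very late (≥2 y), with medians summarised per disorder,
   per mutation, or per biochemical-activity group.
4. Which molecular readout predicts severity? Phenotype metrics
   (expression, PM/Golgi localisation ratios, Gβγ/RGS19/Ric8A/Ric8B
   co-IP levels, ΔBRET) are rank-correlated with onset using a two-tailed
   Spearman test (exact permutation p-values at small n) and ranked by
   |r_s|; group contrasts use the exact Mann–Whitney U test.

A seeded synthetic-data module generates every input — traces with known
kinetics, cohorts with configured group medians, phenotype tables with a
controllable monotone association to onset — so the full pipeline is
testable end to end without laboratory data.

## Worked example

Fit both rate constants from a simulated noisy BODIPY-GTP trace, then ask
what GTP/GDP ratio they imply relative to wild type:

```r
library(gnaokin)
wt <- kinetic_params(2.56e-3, 1.0e-3)        # wild-type: ratio 2.56
tr <- simulate_gtp_trace(kinetic_params(0.02, 0.002, 100, 10),
                         sampling_schedule(0, 2500, 501),
                         noise_model(0.02, seed = 1))
fit <- fit_gtp_kinetics(tr)
fit
#> Gao kinetic fit (direct, active): k_bind = 0.02009 1/s, k_hydr = 0.002003 1/s,
#>   A = 100.3, F0 = 10.02, rmse = 2.02, converged = TRUE
ratio_fold_change(kinetic_params(fit$params$k_bind, fit$params$k_hydr), wt)
#> GTP/GDP ratio: mutant 10.03 vs wild type 2.56 -> 3.92-fold increase
```

The fitted constants recover the generating truth (0.02 and 0.002 s⁻¹)
within 0.5 % at 2 % noise; the mutant would sit at ~10:1 GTP:GDP, a
~4-fold shift toward the GTP-loaded state.

The whole chain — simulate, fit, cycle, classify, correlate — runs from
one call:

```r
out <- run_pipeline(tempfile("demo-"), seed = 1)
out$cycling
#>  variant  ss_ratio fold_vs_wt direction
#>       WT  2.435280   1.000000  increase
#>    L199P 25.255681  10.370752  increase
#>    C215Y  1.000135   2.434951  decrease
#>    E246K 58.029738  23.828779  increase
#>    Q205L 15.086926   6.195151  increase
head(out$biomarkers, 3)
#>             metric        r_s      p_value  n          method note
#>           pm_ratio  0.9850285 1.211056e-13 18 t_approximation <NA>
#>           gbg_coip  0.9117193 1.402088e-07 18 t_approximation <NA>
#>  ric8b_golgi_ratio -0.9106868 1.533655e-07 18 t_approximation <NA>
```

Here the fitted L199P constants (k_bind ×34, k_hydr ×3.5 versus wild type)
put it ~10-fold more GTP-loaded than wild type, C215Y (hydrolysis doubled)
~2.4-fold *less*, and the biomarker table ranks the metrics whose
configured association with onset survived the simulated noise. All
artifacts (traces, fitted constants, ratios, onset classes, summaries,
biomarker ranking, plain-text report) are written to the output directory
with provenance headers.

## Package layout

* `R/synthetic-data.R` — trace, cohort and phenotype generators
* `R/kinetics.R` — activity classification and rate-constant fitting
* `R/cycling.R` — RK4 integration of the cycle and steady-state ratios
* `R/clinical.R` — onset classes, mutation dictionary, group summaries
* `R/association.R` — normalisation, ΔBRET, Spearman / Mann–Whitney,
  biomarker ranking
* `R/io.R` — validated CSV readers/writers and `run_pipeline()`
* `vignettes/gnao1-cycling-and-biomarkers.Rmd` — models, assumptions,
  numerical choices and limitations
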