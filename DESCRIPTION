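Package: gnaokin
Title: Kinetic Modelling and Genotype-Phenotype Analysis of GNAO1
    Encephalopathy Gao Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative characterisation of pathogenic Gao
    (GNAO1) variants: fitting of fluorescent-nucleotide (BODIPY-GTP and
    BODIPY-GTPgammaS) binding and hydrolysis time courses to a sequential
    first-order (Bateman) model to estimate the GTP uptake (k_bind) and
    hydrolysis (k_hydr) rate constants, including baseline extrapolation for
    incomplete hydrolysis; a two-state GDP/GTP nucleotide-cycling model
    integrated to equilibrium with an analytic steady-state cross-check;
    onset-based clinical classification of DEE17 and NEDIM patients; and rank
    statistics (exact-permutation Spearman correlation and Mann-Whitney tests)
    for genotype-phenotype correlation and molecular biomarker ranking. A
    seeded synthetic-data module generates fluorescence traces, patient
    cohorts and per-variant phenotype tables with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
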