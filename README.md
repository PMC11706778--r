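# evfrac

Analysis toolkit for label-free quantitative (LFQ) proteomics of
density-gradient extracellular-vesicle (EV) fractions, built around a
simulation-calibrated **hybrid MNAR/MAR imputation strategy** and
empirical-Bayes moderated differential-enrichment testing. It is aimed at
proteomics analysts working with DIA LFQ intensity tables from fractionated
EV preparations (8 density fractions per donor, grouped F1–3 / F4–6 / F7–8),
and at anyone who needs the surrounding machinery: single-sample gene-set
enrichment (ssGSEA) with set filters, peptide-level coverage tracks for
2N4R tau (441 residues), and nanoparticle-tracking-analysis (NTA) size
summaries.

## The problem and the model

Fraction-selective proteins are the biological signal in an EV gradient —
and exactly the proteins that go missing in the fractions where they fall
below detection. Dropping incomplete proteins (complete-case analysis)
discards them; testing observed values only sees truncation-biased
intensities. The hybrid strategy instead classifies every missing cell:

* for each protein × fraction with missing cells, if the protein is never
  observed in that fraction, or its mean observed log2 intensity lies below
  the fraction's cutoff *c_f*, the cells are **MNAR** (censored below
  detection) and are imputed from a left-shifted Gaussian,
  `N(mu_s − 1.8 sigma_s, (0.3 sigma_s)^2)` on the sample's observed moments;
* otherwise they are **MAR** and are imputed by averaging the k = 10 nearest
  protein rows (Euclidean distance on jointly observed samples).

Cutoffs come from a simulated study with planted differentially enriched
proteins (DEPs) and known missingness: the MNAR share of missing cells is
traced against protein mean intensity and the cutoff set at the bottom of
its steep decline (`select_cutoff()`, ~12 log2 units on the default
simulation). Differential enrichment across the three fraction groups uses
moderated F and t statistics — per-protein residual variances are shrunk
towards a moment-matched scaled inverse-chi-squared prior
(`s2_post = (d0 s0^2 + df s^2) / (d0 + df)`) — with Benjamini–Hochberg
correction at adjusted p < 0.05.

## Worked example

```r
library(evfrac)

study <- simulate_study(sim_config(n_proteins = 1000, n_dep = 300, seed = 42))
study
#> simulated_study: 1000 proteins x 61 samples, 300 DEPs, 22.5% missing

out <- hybrid_impute(study$observed, cutoffs = 12, seed = 42)
res <- run_contrasts(out$imputed, alpha = 0.05)
head(res[order(res$adj_p_F), c("protein", "F1-3", "F4-6", "F7-8", "F", "adj_p_F")], 3)
#>     protein  F1-3  F4-6  F7-8    F   adj_p_F
#> 78   P00078 12.32 14.49 12.27 1662 9.614e-52
#> 218  P00218 13.48 11.20 13.42 1248 2.941e-48
#> 772  P00772 13.21 10.78 10.82 1224 3.591e-48

compare_strategies(study, cutoff = 12, seed = 42)
#>        strategy n_tested n_called capture accuracy mean_adj_p_dep
#> 1        hybrid     1000      297   94.67    95.62      3.676e-02
#> 2     unimputed      868      218   70.67    97.25      4.247e-05
#> 3 complete_case      329       72   23.33    97.22      6.608e-22

select_cutoff(missingness_curve(study))
#> [1] 12.25
```

The group columns are mean log2 intensities per fraction group; `capture`
is the percentage of planted DEPs called significant and `accuracy` the
precision of the calls. Imputation keeps 1000/1000 proteins testable and
recovers 94.7% of the planted DEPs here, against 70.7% for the unimputed
analysis (truncation bias plus untestable groups) and 23.3% for
complete-case analysis (only 329 complete proteins survive).

Other entry points: `vsn_normalize()` / `filter_proteins()` for
preprocessing, `ssgsea_scores()` + `filter_gene_sets()` +
`run_ssgsea_contrasts()` for gene-set analysis, `merge_near_duplicates()` +
`annotate_regions()` for the tau peptide track, and `normalize_dilution()`,
`scale_per_mg()`, `aggregate_replicates()`, `mode_diameter()`,
`percentile_diameters()`, `size_band_fraction()` for NTA exports. The
methods vignette (`vignettes/evfrac-methods.Rmd`) documents the models,
defaults and calibration.

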