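# loopstate

Spatial statistics for chromatin-state organisation along single
transcribed chromatin fibres.

Super-resolution microscopy shows interphase chromatin organised as
chains of ~50-nm nucleosome clusters. On single-fibre model systems
(e.g. the megabase-long Y loops of *Drosophila* primary spermatocytes),
two data types capture how histone modifications map onto this
organisation: STORM/SMLM localisation tables (point clouds of labelled
marks, nm coordinates) and STED line profiles (paired-channel intensity
series along a traced fibre). `loopstate` implements the full analysis
pipeline for both, together with a ground-truth simulator:

* **Clustering & widths** — kernel mean-shift clustering of one mark's
  localisations (Gaussian kernel, σ = 50 nm, ≥ 15 points per cluster by
  default) and cluster FWHM estimation,
  FWHM = 2√(2 ln 2) σ̂ with σ̂ the bias-corrected isotropic Gaussian
  scale of member displacements; width distributions, medians/IQR and
  rank-sum comparisons.
* **Exclusivity** — the fraction of mark-B localisations within 50 nm of
  mark-A cluster centres (per ROI, both directions), and the cross-class
  mark connection function
  p_AB(r) / (2 p̂_A p̂_B), centred so 0 = random labelling, with a
  Monte-Carlo random-labelling envelope and a
  repulsion/random/attraction verdict per distance bin.
* **Profiles** — peak detection by sd-relative prominence ("tolerance
  factor"), pooled inter-peak spacing statistics, and channel
  displacement as the lag maximising the windowed Pearson
  cross-correlation, with the 1.96/√n significance rule and Welch
  t-tests between conditions.
* **Polymerase association** — k-nearest-neighbour distances (k = 5, 9,
  21) from mark localisations to elongating RNA polymerase II
  localisations, ECDFs, and per-ROI quantile comparisons.
* **Simulator** — seeded generator of curved fibres carrying Gaussian
  nucleosome clusters at gamma spacings with Markov state domains,
  tunable exclusivity/contamination/background, and paired peak-train
  profiles with a known channel shift; ground truth is returned with
  every dataset.

## Worked example

Simulate five fibres with fully exclusive marks, cluster one mark, and
quantify exclusivity both ways:

```r
library(loopstate)

sim <- simulate_fibre(fibre_sim_config(n_rois = 5, seed = 1))
sim$table
#> Localisation table: 5336 localisations, 2 mark(s), 5 ROI(s) [nm]

cs <- mean_shift_cluster(sim$table, "H3K36me3")
cs
#> Cluster set for 'H3K36me3': 47 cluster(s) (sigma = 50 nm, min 15 pts)
#>   median FWHM 52.5 nm, median size 61 localisations

overlap_fraction(cs, sim$table, "H3K27me3")
#> Overlap: H3K27me3 localisations within 50 nm of H3K36me3 cluster centres
#>   median fraction 0.000 (0.0%) over 5 ROI(s)

mcf <- mark_connection(sim$table, "H3K36me3", "H3K27me3",
                       n_permutations = 199, seed = 7)
exclusivity_verdict(mcf, scale_limit = 200)$summary
#> [1] "repulsion"
```

The recovered median FWHM (52.5 nm) matches the generator's 52-nm truth;
with no simulated contamination the overlap fraction is 0 and the mark
connection function sits below its random-labelling envelope at all
distances under 200 nm — the clusters are mutually exclusive.

Displacement analysis on simulated STED-style profiles whose mark
channel is shifted 200 nm from the chromatin channel:

```r
ps <- simulate_paired_profiles(profile_sim_config(n_profiles = 20,
                                                  channel_shift = 200,
                                                  seed = 1))
xc <- lapply(ps$profiles, cross_correlate, max_lag = 1000)
xc[[1]]
#> Cross-correlation 'profile01': best lag 200 nm
#>   (r = 0.971, significant at 1.96/sqrt(231))
```

All 20 ROIs pass the significance cutoff and the median absolute lag is
200 nm — the configured shift, recovered to the sampling step.

An end-to-end run from one config (`run_config()`/`run_pipeline()`)
writes every stage output plus a JSON manifest and log;
`inst/scripts/loopstate` wraps the same stages for shell use. See the
vignette (`vignettes/chromatin-state-statistics.Rmd`) for the models,
parameter meanings and validation design.

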