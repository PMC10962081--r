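---
title: "Quantifying chromatin-state organisation along single fibres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin-state organisation along single fibres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopstate)
```

## The problem

Interphase chromatin is organised as chains of nucleosome clusters —
discrete blobs of roughly 50 nm width strung along the fibre — rather
than as a continuous 30-nm fibre. Single transcription-unit model fibres
(such as the Y loops of *Drosophila* primary spermatocytes, megabase-long
loops that extend into open nucleoplasm) make it possible to image this
organisation one fibre at a time and ask how histone modifications map
onto it: do 'active' marks (H3K4me3, H3K36me3) and the 'inactive' mark
H3K27me3 share nucleosome clusters, alternate between them, or occupy
longer exclusive domains? And how does elongating RNA polymerase II
(phospho-Ser2, "RPol-PSer2") sit relative to each?

Two kinds of data feed these questions:

* **SMLM/STORM localisation tables** — point clouds of (x, y) fluorophore
  positions in nm, one mark per channel;
* **STED line profiles** — paired-channel intensity series sampled at a
  uniform arc-length step (typically 20 nm) along a traced fibre.

`loopstate` implements the analysis stages for both, plus a seeded
synthetic-data generator that produces fibres and profiles with known
ground truth so every stage can be validated end to end.

## Statistical machinery

### Mean-shift clustering and FWHM widths

Localisations of one mark are clustered by kernel mean shift: each point
ascends the kernel density estimate (Gaussian kernel, bandwidth
`bandwidth_sigma`, default 50 nm) until its shift falls below
`convergence_tol` (0.1 nm); converged positions within `merge_radius`
(default `bandwidth_sigma/2`) are merged, and modes supported by fewer
than `min_points` (default 15) localisations are discarded, their points
left unassigned. The defaults are the parameters conventionally used for
nucleosome-cluster analysis at this scale. A flat (uniform) kernel
variant is available for sensitivity checks. The Gaussian kernel is
truncated at 3.7 bandwidths inside the compiled kernel; the neglected
weights are below 1e-3 of the central weight and move converged modes by
far less than the convergence tolerance.

Cluster width is summarised as FWHM. Member displacements from the
cluster mean are modelled as an isotropic 2-D Gaussian; the squared
scale is estimated as $\hat\sigma^2 = \sum_i \lVert r_i - \bar r
\rVert^2 / (2(n-1))$, de-biased on the $\sigma$ scale by the
chi-distribution correction for $2(n-1)$ degrees of freedom, and
converted by $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma \approx
2.3548\,\sigma$. The radial-Gaussian fit is a pinned choice: other FWHM
conventions (1-D histogram fits, profile fits) would shift absolute
widths by a few per cent, which matters when comparing against medians
obtained with a different estimator. Width distributions are reported
with linear-interpolation (R type-7) median and IQR and a
probability-normalised histogram; two marks are compared by the percent
difference of medians and a two-sided Wilcoxon rank-sum test, with Holm
adjustment when more than two comparisons are requested.

### Exclusivity: overlap fractions and the mark connection function

Given clusters of mark A and localisations of mark B, the overlap
fraction per ROI is the share of B localisations whose nearest A cluster
centre lies within `radius` (default 50 nm, the nominal cluster
half-width); the median across ROIs is reported, and the roles are
swapped for the complementary analysis so unequal abundances do not bias
the conclusion. Per-ROI-then-median is the default; a pooled fraction is
available.

The mark connection function asks the same question without reference to
clustering. For distance bins $[r, r+\Delta)$ (default 20-nm bins to
500 nm, matching the STED pixel pitch),

$$p_{AB}(r) = \frac{\#\{\text{cross-mark pairs at distance} \in
[r, r+\Delta)\}}{\#\{\text{all pairs at that distance}\}},$$

normalised by $2\hat p_A \hat p_B$ (observed class proportions) so that
random labelling has expectation 1; the `centred` field subtracts 1 so
that 0 means random mixing, negative values repulsion (exclusivity) and
positive values attraction. Pair counting is within-ROI only — fibres
from different cells must not form pairs — and pooling across ROIs
weights by pair counts. The null envelope reallocates labels at random
within each ROI, holding positions fixed (default 199 permutations), and
reports pointwise 2.5%/97.5% quantiles of the centred statistic. No
edge correction is applied (none is conventional for this statistic on
traced fibres); an optional toroidal distance is available for
rectangular simulation windows. Bins with zero pairs are flagged, not
silently dropped. `exclusivity_verdict()` classifies each bin against
the envelope and summarises by majority over bins below a scale limit
(default 200 nm, the cluster scale).

### Profile analyses

Profiles are extracted from two-channel images by bilinear interpolation
at uniform arc-length steps along a polyline ROI (pixel centres at
$(i+0.5)\,\times$ pixel size). Peaks are local maxima whose
*prominence* — height above the higher of the two flanking minima
separating the peak from higher terrain — reaches `tolerance_factor`
times the channel standard deviation. This makes detection invariant to
affine intensity rescaling, with 0.17 a permissive and 1.0 a stringent
setting; plateaus report their midpoint and endpoints never count.
Inter-peak spacings are pooled across ROIs (mean and sample SD).

Channel displacement is the lag maximising $|\mathrm{corr}|$ between the
two channels, computed at every integer-sample lag with mean and SD
recomputed on the overlapping segment (so $|\mathrm{corr}| \le 1$ at
every lag; ties resolve to the smallest absolute lag). A ROI is
significant when $|\mathrm{corr}|$ at the best lag exceeds
$1.96/\sqrt{n}$, with $n$ the overlap length there. Only significant
ROIs enter the displacement summary (median absolute lag per condition,
two-sided Welch t-test between conditions — Welch because condition
variances differ in practice).

### Polymerase association

For each mark localisation, the distance to its $k$-th nearest reference
(RPol-PSer2) localisation is computed within the ROI, for $k \in \{5, 9,
21\}$ by default: the $k$-th neighbour is robust to isolated false
localisations while staying inside the nearest cluster. Distances are
measured from the mark to the reference; the opposite direction is a
role swap. Quantiles use the right-continuous empirical convention (the
smallest datum with cumulative probability $\ge q$). Marks are compared
by per-ROI 90% quantiles (or medians) with a Welch t-test across ROIs;
pooled quantiles are also reported.

## The synthetic-data generator

`simulate_fibre()` emulates a fibre as a bounded-curvature random walk
(10-nm steps, turning angle uniform within `curvature`, default 0.3 rad)
along which cluster centres are placed at gamma-distributed arc spacings.
The gamma family is matched to the requested mean and SD and guarantees
positive spacings, which a normal model would not. Defaults are the
study conditions the package targets: spacing 276 ± 164 nm, cluster FWHM
52 nm (the total-histone median), a Poisson mean of 60 localisations per
cluster (comfortably above the 15-point clustering threshold), and two
mark classes.

Cluster classes follow a two-state Markov chain along the fibre with
`domain_persistence = 0.85`, giving mean runs of about 6 same-state
clusters — the domain structure apparent in dual-colour STORM images of
single fibres — rather than independently random classes. A cluster is
single-class with probability `exclusivity` (default 1), otherwise its
localisations are mixed 50/50. `contamination_fraction` then relocates
that share of second-class localisations into first-class cluster cores
(isotropic Gaussian of σ = 50/3 nm truncated to a 50-nm disc around a
uniformly chosen first-class centre), so the generated overlap is known
by construction. Uniform background can be added per class
(`background_rate`, per µm²; default 0). Localisation precision is
folded into the cluster σ; fluorophore re-blinking and photophysics are
not modelled, and fibre curvature statistics are a free knob with no
claim of realism.

`simulate_paired_profiles()` renders channel A as a train of
unit-amplitude Gaussian peaks (FWHM `peak_fwhm`, default 100 nm) at
gamma spacings on a `step` grid (default 20 nm); channel B is channel A
translated by a whole number of samples (`channel_shift`), both truncated
to the common support, plus i.i.d. Gaussian noise of `noise_sd` times
the peak amplitude (`noise_sd = 0.1` is SNR 10). Truth records the shift
and every spacing.

Everything is driven by a single integer seed; the pipeline derives
per-stage sub-seeds by a stable string hash (`stage_seed()`), so adding
stages never perturbs existing ones.

### What passing the simulator tests does and does not show

The generator reproduces the features the statistics consume — Gaussian
cluster profiles, gamma spacings, state domains, channel shifts, flat
background — but not antibody labelling efficiency, fluorophore
re-blinking (which inflates apparent cluster counts in real STORM
tables), chromatic registration error beyond a rigid shift, or 3-D
structure projected into 2-D. Recovery of generator truth therefore
validates the estimators' correctness and calibration, not the absence
of these instrument effects in real data.

## Numerical choices and degenerate inputs

* Mean shift: convergence tolerance 0.1 nm, max 500 iterations, merge
  radius bandwidth/2; deterministic given input order, and permutation
  of rows changes centres only at floating-point level (< 1e-9 nm).
* Identical coincident points form a valid cluster; a cluster whose
  members all coincide raises a degenerate-cluster error in the width
  estimator (σ = 0 has no FWHM).
* Empty inputs: clustering an absent mark returns an empty cluster set;
  overlap against an empty cluster set is an error (undefined), and ROIs
  with localisations but no clusters are skipped with a warning.
* Mark connection bins with zero pairs are reported as missing and
  listed in `empty_bins`; the verdict ignores them.
* Peak detection on a zero-variance channel warns and returns no peaks;
  strictly monotone profiles have no peaks; profile ends never count.
* Cross-correlation requires ≥ 3 overlapping samples and non-zero
  variance; at equal $|\mathrm{corr}|$ the smaller $|$lag$|$ wins.
* The $1.96/\sqrt{n}$ rule is exact for a single correlation; maximising
  over many lags makes it anti-conservative (for white noise the best of
  nine lags exceeds the cutoff in roughly a third of runs). The
  convention follows the field's practice and is kept as is; the test
  suite verifies the rule at a single lag and this caveat is the reason.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on simulated
data at desk scale, chosen to keep each stage's check to seconds or a
couple of minutes: 300 clusters × 60 localisations for width recovery,
~2,000 points × 100 label allocations for the mark-connection
calibration, 20 five-µm profiles for displacement recovery, ~200
spacings for the peak-spacing twin, and 10 ROIs for the overlap twin.
Exact-oracle checks (exhaustive pair counting, grid mode search, full
sorting for knn) use ≤ 500 points where exhaustive computation is cheap.

## Known limitations

* The FWHM estimator pins one of several defensible definitions; medians
  from other conventions are not directly comparable at the nm level.
* Peak detection cannot resolve peaks closer than roughly the rendering
  FWHM: for gamma(276, 164) spacings rendered at FWHM 100 nm, about 17%
  of spacings fall below the ~105-nm two-peak resolution limit, and the
  recovered mean spacing is inflated by roughly 12% relative to
  generative truth. This is a property of prominence-based detection on
  diffraction-limited-style profiles, shared by any analysis of such
  data, and should be kept in mind when comparing recovered to printed
  means.
* No edge correction in the mark connection function; on short ROIs the
  largest bins are pair-poor and noisy.
* The exclusivity verdict is a pointwise-majority summary, not a global
  envelope test; use the per-bin table when scale structure matters.

## A worked run

```{r example, eval = FALSE}
cfg <- run_config(stages = c("simulate", "cluster", "exclusivity"),
                  out_dir = "run1", seed = 1,
                  fibre_config = fibre_sim_config(n_rois = 5))
man <- run_pipeline(cfg)
man$stages$exclusivity$outputs$verdict   # "repulsion"
```

The same stages are exposed individually (`mean_shift_cluster()`,
`overlap_fraction()`, `mark_connection()`, `find_peaks()`,
`cross_correlate()`, `knn_distances()`, ...) for scripted analyses of
real localisation tables and profiles read with `read_localisations()`
and `read_profiles()`.
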