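# megnet

Frequency-resolved functional brain networks from resting-state MEG source
series, with surrogate-calibrated wPLI connectivity, rich-club topology, and
small-sample group statistics.

## The problem

Resting-state MEG gives, per subject, a set of region-of-interest (ROI)
source time series. To ask whether the *alcohol-naïve* organization of a
macaque's functional brain network predicts how much it will later drink —
and how chronic free-access drinking reorganizes that network — each
subject's series must be turned into a graph whose edges are genuine
phase-coupled connections, not volume conduction or noise, and whose
topology can be compared across timepoints and correlated with intake in a
cohort of only six animals.

`megnet` implements that pipeline end to end:

1. **Connectivity.** For every ROI pair the weighted phase lag index
   (wPLI) is computed on Welch-segmented cross-spectra:

   `wPLI(f) = |E_k[ Im S_xy(f, k) ]| / E_k[ |Im S_xy(f, k)| ]`

   over segments *k*. wPLI is insensitive to source amplitude and to
   exactly zero-lag (volume-conduction-like) coupling.
2. **Surrogate null.** A per-subject null is built from 5,000 unique pairs
   of phase-randomized series (original amplitude spectrum, random
   conjugate-symmetric phases), pooled into a per-frequency mean mu(f) and
   SD sigma(f). Each pair's connection is operationalized at the frequency
   maximizing `z(f) = (wPLI(f) - mu(f)) / sigma(f)`; pairs with
   `max z < 2.5` stay unconnected.
3. **Thresholding.** Gated candidates are ranked by `z` and cut to the
   density implied by the exponent criterion `S = log(N) / log(K)` with
   `S = 2.5`, i.e. average degree `K = N^(1/S)` (91 edges at N = 41).
4. **Topology.** Clustering coefficient, global efficiency, degree
   assortativity, Louvain module counts (500 randomized runs), rich-club
   extraction — `phi(k) = 2 E_{>k} / (N_{>k} (N_{>k} - 1))` normalized by
   500 degree-preserving rewired networks — hubs (top 10% by degree), and
   per-band connection-frequency statistics.
5. **Group statistics.** Paired t tests across timepoints, exact binomial
   McNemar tests of per-region membership change, exact-permutation
   Spearman correlations of baseline metrics against free-access intake
   (g/kg), and Cohen's d effect sizes.

A first-class synthetic-data module generates ROI series with planted
phase-lag coupling and whole cohorts whose intake outcome is negatively
coupled to a planted rich-club minimum degree, so every stage is testable
without any recorded data.

## Worked example

```r
library(megnet)

# a 6-subject synthetic cohort: planted rich-club minimum degrees 3..8,
# outcome = 4.7 - 0.8 * degree + noise (g/kg)
sp  <- cohort_spec(n_subjects = 6, n_rois = 24, planted_min_degree = 3:8,
                   fs = 128, duration_s = 16, freq_pool = seq(4, 38, 2),
                   seed = 1)
coh <- generate_cohort(sp, timepoints = "baseline")

cfg <- pipeline_config(f_min = 2, f_max = 40, segment_length_s = 0.5,
                       n_surrogate_pairs = 150, n_random_networks = 100,
                       n_louvain_runs = 50, master_seed = 1)

fit <- fit_network(coh$S6$baseline, cfg)
fit
#> <functional_network> subject S6 / baseline
#>    24 nodes, 43 edges (target E = 43, achieved K = 3.58, S = 2.5, gate = 2.5 SD)

summary(fit)$rich_club
#> <rich_club_result> k* = 3 | 9 members, min degree 8 , coefficient 1.152 (vs 100 rewired nulls)

# naive-state rich-club degree vs future intake across the cohort
mind <- sapply(coh, function(s)
  rich_club_analysis(fit_network(s$baseline, cfg), n_random = 100,
                     seed = child_seed(1, "rc", s$subject_id))$min_degree)
mind
#> S1 S2 S3 S4 S5 S6
#>  6  5  6  6  7  8

spearman_test(mind, cohort_outcomes(coh)$outcome_g_per_kg)
#> <Spearman> statistic = -0.8197, df = 4, p = 0.06667, effect = -0.82
```

Subject S6 carries a planted 9-clique (minimum degree 8): the fit recovers
all 36 clique edges inside its 43-edge budget, and the rich-club extraction
returns the planted club with its minimum degree. Across the cohort the
recovered minimum degree correlates negatively with intake — the planted
phenotype — with an exact permutation p value at n = 6.

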