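---
title: "Methods: surrogate-gated wPLI networks and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate-gated wPLI networks and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`megnet` turns per-subject ROI source time series from resting-state MEG
into binary functional networks and compares their topology across
timepoints and against a behavioural outcome. This vignette documents the
model, its assumptions, the tunable parameters, the synthetic-data
generator used for validation, and the numerical and design choices that
were genuinely open.

## The connectivity model

**Estimator.** Coupling between two series is measured with the weighted
phase lag index over Welch-segmented cross-spectra,

$$\mathrm{wPLI}(f) \;=\;
\frac{\bigl|\,\mathbb{E}_k[\,\mathrm{Im}\,S_{xy}(f,k)\,]\bigr|}
     {\mathbb{E}_k[\,|\mathrm{Im}\,S_{xy}(f,k)|\,]},$$

with $S_{xy}(f,k)$ the complex cross-spectrum of Hann-tapered segment $k$.
Using only the imaginary part makes the estimator invariant to source
amplitude (scaling either series cancels) and blind to exactly zero-lag
coupling, the signature of volume conduction. Frequencies where
$\mathbb{E}_k|\mathrm{Im}\,S_{xy}|$ vanishes (identical zero-lag signals)
are defined as wPLI $= 0$ and flagged, so such coupling can never be
called a connection. The original analysis does not state its spectral
estimator; segmented averaging is the standard wPLI substrate and is the
only practical choice for records of a few minutes. Defaults: 2 s
segments, 50% overlap, band 1–80 Hz, giving a 0.5 Hz grid; all
configurable through `spectral_params()`.

**Null.** Real series produce nonzero wPLI by chance, with a bias that
grows as segments shrink. The null is built per subject from phase-
randomized surrogates: each draw picks a ROI pair uniformly, randomizes
the Fourier phases of both series independently (conjugate-symmetric, DC
and Nyquist untouched — the amplitude spectrum, hence the autocorrelation,
is preserved exactly), and computes a full wPLI spectrum. The default
5,000 draws are pooled into a per-frequency mean $\mu(f)$ and SD
$\sigma(f)$. "Unique pairs" is interpreted as unique (ROI-pair,
realization) draws: every draw uses fresh independent phases, so no two
draws are identical by construction. Pooling across pairs (one null per
subject, not per pair) follows the per-animal construction of the original
analysis; a per-pair null would need far more draws per pair to estimate
tail SDs and is not the default.

**Connection calling.** Each pair is summarized by
$z(f) = (\mathrm{wPLI}(f) - \mu(f))/\sigma(f)$, the connection frequency
$f^\* = \arg\max_f z(f)$ (ties broken toward the lowest frequency,
deterministically), and the effect size $z_{\max}$. Pairs with
$z_{\max} < 2.5$ stay unconnected. Because $z_{\max}$ is a maximum over
the whole grid, its null exceedance rate is the family-wise one — far
above the per-frequency tail — so the 2.5 SD gate is a noise floor, not a
significance test; the density threshold below does the real selection.

**Density threshold.** Gated candidates are ranked by $z_{\max}$ (the
only effect size the pipeline defines; the original text does not say how
edges are ranked) and cut to $E = \mathrm{round}(N \cdot N^{1/S}/2)$
edges, $S = 2.5$ — at $N = 41$, $K \approx 4.42$ and $E = 91$. Ties at
the cutoff break by lower $f^\*$, then label order. If the gate leaves
fewer than $E$ candidates the network is left sparser and the achieved
degree is recorded; the gate is never backed off.

## Topology battery

All metrics are computed on the binary thresholded graph: mean clustering
coefficient ($C_i = 2T_i/(d_i(d_i-1))$, $C_i = 0$ for $d_i < 2$), global
efficiency (mean inverse shortest path, disconnected pairs contributing
0), Newman degree assortativity (undefined on regular graphs, returned as
flagged `NaN`), and the mean Louvain module count over 500 runs. Louvain's
stochastic element is the vertex sweep order, so each run permutes the
vertex labels uniformly; isolated nodes count as their own module and an
edgeless graph has $N$ modules with $Q = 0$.

The rich club is extracted from
$\phi(k) = 2E_{>k}/(N_{>k}(N_{>k}-1))$, the density among nodes of degree
$> k$, normalized by the mean $\phi_{\mathrm{rand}}(k)$ over 500
degree-preserving rewired networks (Maslov–Sneppen double-edge swaps, 10
attempts per edge; the rewiring conditions on exactly the degree sequence
that $\phi(k)$ is biased by). The original text reports a single club per
network without stating how one level is chosen from the $\phi$ curve; the
package takes $k^\* = \arg\max_k \phi(k)/\phi_{\mathrm{rand}}(k)$ —
the maximally differentiated club — with ties toward the smallest $k$.
Members are the nodes of degree $> k^\*$; the reported characteristics are
the member count, the minimum member degree, and the normalized
coefficient at $k^\*$. Hubs are the top `max(1, floor(0.10 N))` nodes by
degree (4 at $N = 41$), ties broken by label order.

Connection-frequency statistics (mean $f^\*$ and per-band counts; delta
[1,4), theta [4,8), alpha [8,13), beta [13,30), gamma [30,80] Hz —
conventional MEG boundaries, configurable) are computed on the gated
candidate set by default rather than the thresholded network: the
published per-band counts sum to roughly 260 connections at baseline,
which is incompatible with the ~91 edges the density criterion allows at
$N = 41$, so band counting appears to precede thresholding. The edge set
is switchable (`band_count_edge_set = "thresholded"`).

## Group statistics

With six subjects, asymptotic tests are the wrong tool:

* **Paired t** across timepoints (and across regions for the membership
  tables); zero difference variance returns a flagged degenerate result.
* **McNemar** per region is the exact binomial form,
  $p = \min(1,\, 2\,P(X \le \min(b,c)))$, $X \sim \mathrm{Bin}(b+c, 1/2)$
  on the discordant counts; the continuity-corrected chi-square variant is
  available behind a flag for comparability with the original label.
* **Spearman** correlations use average ranks and, for $n \le 8$, an
  exact two-tailed p by enumerating all $n!$ permutations (720 at
  $n = 6$; the t approximation is unreliable there).
* **Cohen's d** is offered in paired and one-sample forms. The published
  intake effect size (d = 5.23) has an unstated baseline; against the
  final 1.5 g/kg induction dose the one-sample form gives 3.09, so
  neither form is asserted to reproduce the printed value. (The same
  analysis is printed once with p = 0.02 and once with p < 0.001 in the
  source material; neither is treated as a checkable target.)
* No multiplicity correction by default (matching the two-tailed,
  alpha = 0.05 analysis); Holm adjustment is available as an option.

Membership tables collapse ROIs to structures by an any-aspect OR (a
structure is a hub if any of its aspects is), with inclusion thresholds of
3 subjects for rich-club tables and 1 for hub tables. The shipped 41-ROI
atlas is an illustrative reconstruction — the published region list
resolves to 39 labels, so a parietal subdivision was added to reach 41 —
and is labelled synthetic; real analyses should provide their own map.

## The synthetic-data generator

The generator is the package's evidence base, so its physics matter.

**Oscillators.** A planted connection is a shared narrowband oscillator:
carrier at the planted frequency, constant carrier phase lag between the
two channels, multiplied by a shared strictly positive band-limited
envelope ($1 + 0.8\,s(t)$, $s$ low-pass noise scaled to $\max|s| = 1$,
bandwidth 1 Hz) and carrying slow shared phase drift (3 rad depth, 0.3 Hz
bandwidth), plus independent Gaussian noise per channel. Two properties
were non-negotiable and drove this design:

* *The wPLI analytic limit must be exact.* Because envelope and drift are
  shared and the envelope is positive, the two channels' analytic signals
  differ by exactly $e^{-i\,\mathrm{lag}}$ at every positive frequency, so
  $\mathrm{Im}\,S_{xy}$ keeps one sign and wPLI $= 1$ at the planted
  frequency, noiselessly and exactly — the property the tests assert.
* *Surrogates and non-coupled oscillators must genuinely decohere.* A pure
  infinite sinusoid occupies one Fourier bin; phase randomization then
  only adds a constant phase, the surrogate pair keeps a constant lag, and
  the null collapses onto the signal (gate never passes). Likewise, two
  deterministic carriers at frequencies $f_1 \ne f_2$ are perfectly
  phase-locked across segments whenever $(f_1 - f_2)\times$ (segment
  step) is an integer, producing spurious connections. Amplitude
  modulation spreads the spectrum so surrogate phases genuinely scramble,
  and the independent-per-oscillator phase drift randomizes cross-
  oscillator phase relations. Pure unmodulated sinusoids are available
  (`env_depth = 0, pm_depth = 0`) but defeat the surrogate logic by
  construction.

An important consequence, documented rather than hidden: the *exact*
zero-noise limit is ill-posed for end-to-end recovery. With no noise
floor, every bin of a coupled pair is perfectly phase-consistent through
window leakage, so the argmax connection frequency is arbitrary. The
analytic wPLI $= 1$ limit is therefore asserted at zero noise *at the
planted frequency*, while edge-set and frequency recovery is asserted in
the high-SNR regime (noise SD 0.3 against amplitude 1).

**Cohorts.** Each subject's baseline network plants a rich club as a
$(d+1)$-clique sharing one oscillator with node phase offsets
$m\pi/(c+1)$ — every within-club lag strictly inside $(0, \pi)$ — and
leaves the remaining ROIs as pure noise. Every planted edge is then a
club edge, so the $S = 2.5$ budget can never cut the club as long as the
clique fits ($d \le 8$ at $N = 24$), and the recovered rich-club minimum
degree equals $d$ up to spurious gate-passers (which can only add
degree). The outcome is $4.7 + \mathrm{slope}\cdot d +
\mathcal N(0, \mathrm{sd}^2)$ g/kg with defaults slope $-0.8$ and sd
$0.5$: the intercept and spread sit on the observed free-access intake
scale (mean 4.7, SD 1.0 g/kg), and slope/noise were chosen once so the
implied degree–intake rank correlation is near the observed $-0.88$.

**What the generator does not emulate.** Real source series are broadband
$1/f$-like, nonstationary, and correlated through field spread that
beamforming only partly removes; connection frequencies there arise from
oscillatory dynamics, not planted carriers. Passing tests therefore
demonstrate that the pipeline recovers known ground truth under its own
stated model — estimator correctness, calibration, and end-to-end
plumbing — not that the biological findings would replicate.

## Numerical choices and degenerate inputs

* Degenerate wPLI denominators are detected at
  $\mathbb{E}|\mathrm{Im}\,S| \le 10^{-10}\,\mathbb{E}|S|$ (relative, so
  amplitude-invariance is preserved) and return 0, flagged.
* A surrogate null with $\sigma(f) = 0$ anywhere is an error (broken
  surrogates), as is a request for fewer than 100 draws.
* `threshold_network()` with zero gated candidates warns and returns the
  empty network; metrics that need edges are skipped (`NA`) downstream.
* All ties (argmax frequency, threshold rank, hub cutoff, rich-club
  level) break deterministically, as listed above.
* Every stochastic stage draws its seed from one master seed through
  `child_seed()` (a base-31 string hash into $[0, 2^{31}-1)$, tagged by
  stage, subject, timepoint, and replicate), so any subject or stage can
  be recomputed independently and bit-identically.

## Problem sizes used in tests

Tests and the acceptance script exercise the full-scale defaults' code
paths at reduced sizes chosen to keep simulations in seconds: 100–150
surrogate draws (the pooled null's mean/SD are already stable there for
the fixtures used), 24 s × 200 Hz or 16 s × 128 Hz records, cohorts of 6
subjects × 24 ROIs, 50–100 rewired networks and Louvain runs, and 50–100
replicate seeds for the calibration and phenotype-recovery rates. The
full-scale constants (5,000 draws, 500 networks, 500 runs, 1–80 Hz at
0.5 Hz) remain the defaults of `pipeline_config()`.

## Known limitations

* The wPLI null is right-skewed (roughly half-normal), so the 2.5 SD gate
  passes ~2% of null pairs per frequency — about three times the Gaussian
  tail — and far more family-wise across the grid. This is a property of
  the published design that the package reproduces faithfully; its
  consequences are measured, not corrected.
* The gate/threshold interaction means recovered networks at full density
  always contain some spurious edges whenever the true structure is
  sparser than $E$; topology metrics inherit that noise.
* The rich-club level rule ($\arg\max$ of the normalized coefficient) is
  one defensible reading of an under-specified step; published per-subject
  club characteristics cannot be verified without the original data.
* HDF5 input is not supported; the on-disk format is a TSV matrix with a
  YAML metadata sidecar.
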