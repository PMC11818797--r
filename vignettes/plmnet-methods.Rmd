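---
title: "Methods: PLM connectivity, eigenvector centrality, and permutation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLM connectivity, eigenvector centrality, and permutation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

plmnet analyses frequency-resolved functional brain networks starting from
source-level region time series — typically 90 regions of the AAL
parcellation after cerebellar exclusion — and ends in group-level
statistics on lobe-aggregated eigenvector centrality. This vignette
documents the model at each stage, the tunable parameters, the numerical
choices, and what the synthetic cohort generator can and cannot stand in
for.

## Pipeline overview

For each subject and each canonical frequency band:

1. **Band-pass filtering.** A 4th-order Butterworth band-pass, applied
   forward and backward (`signal::filtfilt`) so the net phase response is
   zero. Zero-phase application is essential: the connectivity metric
   downstream is phase-based, and a causal IIR pass would distort phase
   relations between regions. The canonical bands are delta (0.5–4 Hz),
   theta (4–8 Hz), alpha (8–13 Hz), beta (13–30 Hz) and gamma (30–48 Hz);
   all edges are configurable. (Alpha is sometimes quoted as 8–12 Hz; this
   package uses 8–13 Hz as its default and leaves the edge configurable.)
2. **Instantaneous phase.** The argument of the analytic signal, computed
   per region over the full recording by the frequency-domain Hilbert
   transform. The estimate is only meaningful for band-limited input; the
   first and last second are flagged and dropped before connectivity
   estimation to suppress transform edge effects (`edge_trim_s`,
   default 1 s).
3. **Phase linearity measurement (PLM).** For regions $i, j$ with phases
   $\phi_i(t), \phi_j(t)$, form the interferometric signal
   $z(t) = e^{\,\mathrm{i}(\phi_i(t) - \phi_j(t))}$ and estimate its power
   spectrum $|S_Z(f)|^2$. Then
   $$\mathrm{PLM}_{ij} \;=\;
     \frac{\sum_{|f| \le B} |S_Z(f)|^2}{\sum_f |S_Z(f)|^2},$$
   the fraction of the interferometric power concentrated within the
   integration half-bandwidth $B$ (default 1 Hz). A phase relation that is
   nearly linear in time concentrates $z$ at a single low frequency and
   pushes the ratio toward 1; incoherent phases spread it and push the
   ratio toward 0. The DC bin is zeroed before integrating
   (`discard_dc = TRUE`): zero-lag identity of phases — the signature of
   instantaneous mixing / volume conduction — leaves no power after DC
   removal and scores 0 rather than a spuriously perfect coupling. The
   spectrum is estimated by a plain periodogram by default (deterministic
   and parameter-free); a Welch estimator (`spectral_estimator = "welch"`,
   Hann-windowed non-overlapping segments) is available for noisier data,
   and the two rank region pairs consistently (rank correlation > 0.9 on
   simulated cohorts). Estimation uses the full trimmed recording;
   optional non-overlapping epoching with matrix averaging is available
   via `epoch_s`.
4. **Eigenvector centrality.** With the symmetric nonnegative
   connectivity matrix $A = (a_{ij})$, the centrality of node $i$ solves
   $x_i = \lambda^{-1} \sum_{j \in N(i)} a_{ij}\, x_j$, i.e. $Ax = \lambda
   x$, and the reported vector is the eigenvector of the largest
   eigenvalue $\lambda$ — nonnegative by Perron–Frobenius for connected
   nonnegative matrices — normalized so that $\sum_i \tilde{x}_i^2 = 1$.
   A node scores highly when its neighbours score highly, which makes the
   measure sensitive to hub reorganization rather than to local degree
   alone.
5. **Lobe aggregation.** Region scores are averaged within six groups —
   frontal, insular, temporal, parietal, occipital, subcortical — trading
   spatial detail for statistical power: six tests per band instead of
   ninety.
6. **Statistics.** Per (band, lobe): a two-group permutation test on
   $|\bar{x}_\mathrm{PD} - \bar{x}_\mathrm{HC}|$ (50,000 relabellings by
   default; exhaustive enumeration whenever the number of distinct
   assignments is smaller), Benjamini–Hochberg FDR correction at
   $q = 0.05$ across the six lobes within each band, and Pearson
   correlations of lobe centrality against clinical scores (UPDRS-III,
   disease duration) within the patient group, by default restricted to
   the cells that showed a significant group difference.

## Numerical choices

- **Eigensolver.** Dense symmetric eigendecomposition for $N \le 256$;
  power iteration (tolerance $10^{-12}$, at most 10,000 iterations, small
  diagonal shift to remain convergent on bipartite-like spectra) above
  that. The two agree to better than $10^{-8}$ per component on random
  matrices. The sign is fixed by making the largest-magnitude component
  positive; components below $-10^{-12}$ trigger an error (ambiguous
  leading eigenspace, impossible for the strictly positive matrices PLM
  produces), and tiny negative rounding residues are clamped to zero
  before renormalizing.
- **Input diagonal** is forced to zero before the eigenproblem;
  self-coupling is undefined for PLM.
- **Permutation p-values** use add-one smoothing,
  $p = (1 + \#\{\text{surrogate} \ge \text{observed}\})/(1 + n_\mathrm{perm})$,
  guaranteeing $p > 0$; the plain proportion is available
  (`smooth = FALSE`). Surrogate comparisons use a relative tolerance of
  $10^{-12}$ on the observed statistic so ties are counted as exceedances.
  The absolute-difference statistic is inherently two-sided; direction is
  reported separately.
- **FDR family.** The package corrects across the six lobes within each
  band, matching per-band reporting; `fdr_family = "global"` corrects
  across all band × lobe tests instead. Which family a given study used
  is often ambiguous, so both are exposed.
- **PLM symmetry.** The sign of the phase difference is canonicalized
  before the FFT, which makes `plm_pair(x, y)` and `plm_pair(y, x)`
  bit-identical rather than merely equal up to rounding.
- **Degenerate pairs.** If the spectrum retains (numerically) no power
  after DC removal — constant phase difference — PLM returns 0 with a
  warning.

## The synthetic cohort generator

No public source-level dataset accompanies the analysis this pipeline
implements, so validation rests on a generator with known ground truth.
Each subject is a system of $N$ stochastic phase oscillators integrated
by Euler–Maruyama at the sampling rate:
$$\mathrm{d}\phi_i = 2\pi f_i\,\mathrm{d}t
  + 2\pi\,c\,k_i \sin(\psi - \phi_i)\,\mathrm{d}t
  + \sigma_\phi\,\mathrm{d}W_i,$$
where $\psi$ is a shared driver phase advancing at the carrier frequency
$f_0$ (the centre of `carrier_band`, default alpha) with its own slow
diffusion, $k_i \in [0, 1)$ is the region's coupling strength,
$c$ = `coupling_rate_hz` converts it to a pull rate, and the emitted
signal is $\cos\phi_i$ plus 1/f background noise. Hub regions of PD-like
subjects use $k = $ `base_coupling` $+$ `effect_realized`; everyone else
uses `base_coupling`. Stronger coupling means tighter phase locking to
the driver, hence higher PLM with every other coupled region, hence
higher eigenvector centrality — the planted effect propagates through the
same mechanics the pipeline is designed to detect. Pseudo-UPDRS-III is an
affine function of the realized increment plus Gaussian noise (truncated
at zero), so clinical correlations are recoverable exactly when the
planted effect varies between subjects (`effect_sd > 0`).

Carrier frequencies are a fixed property of the atlas: per-region offsets
evenly spaced over ±`freq_jitter` (default 2 Hz) in a fixed shuffled
order, plus a small ±0.25 Hz per-subject jitter. Making the detuning
pattern subject-invariant matters: if every subject redraws its regional
frequencies, the healthy-control lobe centrality becomes dominated by the
detuning draw rather than by group membership, and the planted contrast
drowns (measured Cohen's d dropped from ≈3 to ≈1.1 at the Monte-Carlo
scale below).

Default noise scales (`phase_noise_sd` 2 rad/√s, `driver_noise_sd`
0.5 rad/√s, `background_amp` 0.5, `coupling_rate_hz` 4 Hz,
`base_coupling` 0.2, `effect_size` 0.3, `effect_sd` 0.15,
`score_noise_sd` 3) were calibrated once so that the planted effect is
reliably detectable at desk scale; no per-subject variance estimates
exist to match them to recorded MEG, so they are chosen for test power,
not realism.

**What the generator does not emulate:** sensor-space physics (forward
models, channel noise, head movement), artifacts (cardiac, ocular),
amplitude dynamics and cross-frequency structure of real MEG, spatially
correlated source leakage beyond the shared driver, and any
heterogeneity of effect location across subjects. Passing tests
demonstrate that the pipeline recovers hub-strength effects expressed
through phase coupling; they do not certify performance on recorded
data.

**A floor worth knowing about.** For two *independent* signals confined
to the same narrow band, the interferometric spectrum is the convolution
of two band-width-limited spectra, so a fixed fraction of its power —
about 0.32 for the 5 Hz-wide alpha band at $B = 1$ Hz, independent of
sampling rate and duration — always falls inside the integration band.
Uncoupled region pairs therefore plateau around 0.3, not 0. Truly small
PLM values require phase processes whose spectra are broad relative to
$B$ (e.g. heavily diffusing raw phase walks, or broadband signals before
band-limiting). Interpreting within-band PLM matrices should be done
relative to this floor, which is why the package's validation asserts
separation between coupled and uncoupled pairs rather than absolute
smallness.

## Monte-Carlo problem sizes

The statistical validation uses reduced study conditions chosen once:
10+10 subjects, 12 regions (two per lobe, `reduced_atlas(2)`), 20 s of
signal at 128 Hz, alpha band only, 999 permutations per test. Under
these conditions the suite verifies that (a) with no planted effect the
pipeline's permutation p-values are uniform (Kolmogorov–Smirnov over 500
null cohorts) and BH at $q = 0.05$ keeps the realized false discovery
rate at or below 0.05; and (b) with the calibrated planted effect the
frontal lobe is flagged after FDR correction in at least 80 of 100
cohorts and frontal centrality correlates positively with the pseudo
clinical score in at least 90 of 100. Full-scale runs (47+47 subjects,
90 regions, five bands, 50,000 permutations) use exactly the same code
paths.

## Known limitations

- The shipped lobe partition follows conventional AAL groupings
  (anterior/mid cingulate → frontal, posterior cingulate → parietal,
  Rolandic operculum → frontal); atlases differ on these assignments, so
  the partition is an editable CSV, not a fixed truth.
- Whether connectivity should be estimated on the full recording or on
  epochs is study-dependent; both are supported, full-record is the
  default.
- PLM parameters ($B$, estimator, epoching) vary across the literature;
  defaults follow the metric's original description and are configurable.
- Correlations are computed only within the patient group and are not
  adjusted for covariates such as age or education.
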