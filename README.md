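# plmnet

Frequency-resolved functional brain network analysis from source-level
neurophysiological recordings — and a simulator to validate every stage of
it.

Resting-state MEG/EEG studies of Parkinson's disease and other conditions
often summarize each brain region's role in the network with **eigenvector
centrality** (EC): the region's component in the leading eigenvector of the
connectivity matrix, high when a region is strongly connected to other
well-connected regions. plmnet implements the full path from region time
series to group-level statistics:

1. **Band decomposition** — zero-phase 4th-order Butterworth filtering into
   delta (0.5–4 Hz), theta (4–8), alpha (8–13), beta (13–30) and gamma
   (30–48 Hz);
2. **Phase linearity measurement (PLM)** — for each region pair, the
   fraction of the interferometric signal
   `z(t) = exp(i(φᵢ − φⱼ))`'s spectral power within ±B Hz (B = 1 by
   default), a [0, 1] synchronization index whose DC-bin removal makes it
   insensitive to instantaneous mixing (volume conduction);
3. **Eigenvector centrality** — leading eigenpair of each subject × band
   PLM matrix `A x = λ x`, scores normalized so Σx̃² = 1, averaged into six
   lobe values (frontal, insular, temporal, parietal, occipital,
   subcortical) over the AAL 90-region parcellation (cerebellum excluded);
4. **Statistics** — permutation tests (50,000 relabellings, exact
   enumeration when feasible) on the absolute group mean difference per
   band × lobe, Benjamini–Hochberg FDR at q = 0.05 within each band,
   optional sex-stratified reruns, and Pearson correlations of lobe EC
   against clinical scores (UPDRS-III, disease duration) in the patient
   group.

Because source-level cohort data of this kind are rarely public, the
package ships a **synthetic cohort generator**: coupled phase oscillators
with a shared driver, a planted hub-strength increase in the frontal lobe
of the PD-like group, and pseudo clinical scores correlated with the
planted effect. Every statistical claim in the test suite is validated
against cohorts with known ground truth. See the methods vignette
(`vignettes/plmnet-methods.Rmd`) for the model and its calibration.

## Worked example

A reduced synthetic study — 10 PD-like vs 10 control subjects, 12 regions
(two per lobe), 20 s of signal at 128 Hz, alpha band, frontal hub effect
planted in the PD-like group:

```r
library(plmnet)

spec <- cohort_spec(n_pd = 10, n_hc = 10, atlas = reduced_atlas(2),
                    fs = 128, duration_s = 20, seed = 7)
cfg <- pipeline_config(
  out_dir = file.path(tempdir(), "plmnet-demo"),
  synthetic = spec,
  bands = data.frame(name = "alpha", low = 8, high = 13),
  n_perm = 5000, seed = 7)
res <- run_pipeline(cfg)

print(res$comparison[, c("band", "lobe", "observed_abs_mean_diff",
                         "p_raw", "p_fdr", "direction")], digits = 3)
#>    band        lobe observed_abs_mean_diff  p_raw  p_fdr direction
#> 1 alpha     frontal                0.05171 0.0004 0.0024 PD_higher
#> 2 alpha     insular                0.01159 0.1578 0.1893 HC_higher
#> 3 alpha    temporal                0.02455 0.0034 0.0102 HC_higher
#> 4 alpha    parietal                0.00725 0.2787 0.2787 HC_higher
#> 5 alpha   occipital                0.00653 0.1288 0.1893 HC_higher
#> 6 alpha subcortical                0.01760 0.0104 0.0208 HC_higher
```

The planted frontal effect is recovered (`PD_higher`, p_FDR = 0.0024).
Note the mirror-image `HC_higher` rows: EC vectors are unit-norm, so a
genuine centrality gain in one lobe necessarily depresses scores
elsewhere — a compensation effect to keep in mind when reading real EC
contrasts. Correlations with the pseudo clinical score are positive where
the effect was planted:

```r
print(res$correlations[1, ], digits = 3)
#>    band    lobe variable     r p_raw p_fdr  n
#> 1 alpha frontal   updrs3 0.422 0.225 0.384 10
```

(`run_correlations(..., comparison = NULL)` correlates every band × lobe
cell instead of only the significant ones.)

All outputs (cohort table, per-region and per-lobe EC tables, comparison
and correlation CSVs, a JSON run manifest and a log) are written under
`cfg$out_dir`; rerunning an identical configuration reproduces them
byte-for-byte. A command-line front end with `simulate`, `connectivity`,
`centrality`, `stats` and `run-all` subcommands lives at
`inst/cli/plmnet.R`.

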