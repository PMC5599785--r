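# plitree

Resting-state EEG network analysis in R: phase-lag-index (PLI) functional
connectivity, minimum-spanning-tree (MST) reconstruction of the
strongest-connection backbone, global tree-topology metrics, and the group
statistics used to compare two cohorts (e.g. smokers vs nonsmokers). A
synthetic phase-coupled EEG generator with known ground-truth coupling makes
every stage testable without access to real recordings.

## Who it is for

EEG researchers who want a scripted, reproducible path from multichannel
resting-state recordings (plain-text channel × sample matrices plus a
subject manifest) to a per-band table of network metrics and group
comparisons — without hand-tuned connectivity thresholds, which the MST
approach avoids by construction.

## The method

For each subject, band (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–25 Hz),
and artifact-free 8-s epoch:

1. **Connectivity.** Instantaneous phases φ(t) come from the analytic
   signal (Hilbert transform). For each channel pair,

   PLI = | ⟨ sign( sin(φᵢ(tₖ) − φⱼ(tₖ)) ) ⟩ₖ |

   PLI ∈ [0, 1] measures the consistency of a *nonzero* phase lag: exactly
   zero-lag coupling — the signature of volume conduction — contributes
   sign(0) = 0 and is discounted.

2. **Tree backbone.** The N × N PLI matrix is reduced to its maximum-weight
   spanning tree (equivalently, the minimum spanning tree of distance
   1 − PLI): N − 1 strongest connections, no loops, no threshold.

3. **Topology metrics**, normalised by M = N − 1 where applicable:
   max degree/M, leaf fraction N_leaf/M, diameter/M, mean eccentricity/M,
   maximum betweenness centrality BC_max (normalised by (n−1)(n−2)), tree
   hierarchy T_H = N_leaf/(2·M·BC_max), and degree divergence
   κ = ⟨s²⟩/⟨s⟩. High leaf fraction and κ indicate star-like, hub-dominated
   integration; high diameter and eccentricity indicate path-like,
   inefficient organisation.

4. **Statistics.** Pooled-variance two-sample t per (band, metric) between
   groups (df = n₁ + n₂ − 2, two-sided, uncorrected; Welch and
   Holm-corrected columns emitted as extensions), and Pearson correlations
   between alpha-band metrics and smoking covariates within the smoker
   group.

## Worked example

Simulate two 16-channel cohorts with known alpha-band coupling — a hub
("star") topology for one group, a sequential ("chain") topology for the
other — and run the full pipeline:

```r
library(plitree)
manifest <- simulate_dataset("star_vs_chain", n_per_group = 5,
                             out_dir = "demo_data", seed = 42,
                             n_channels = 16, duration = 80)
cfg <- pipeline_config(bands = list(band_definition("alpha", 8, 13)))
res <- run_pipeline(manifest, "demo_out", cfg)
print(res$comparison[, c("band", "metric", "mean_smoker", "sd_smoker",
                         "mean_nonsmoker", "sd_nonsmoker", "t", "p")],
      digits = 3)
```

Output (chain-coupled group labelled "smoker", star-coupled "nonsmoker"):

```
   band         metric mean_smoker sd_smoker mean_nonsmoker sd_nonsmoker      t        p
1 alpha            pli       0.823   0.00112          0.227       0.0081 163.07 2.24e-15
2 alpha         degree       0.775   0.02724          1.000       0.0000 -18.49 7.53e-08
3 alpha  leaf_fraction       0.915   0.01966          1.000       0.0000  -9.70 1.06e-05
4 alpha       diameter       0.213   0.01333          0.133       0.0000  13.42 9.12e-07
5 alpha   eccentricity       0.200   0.00774          0.129       0.0000  20.33 3.58e-08
6 alpha             bc       0.934   0.01068          1.000       0.0000 -13.84 7.20e-07
7 alpha tree_hierarchy       0.490   0.00595          0.500       0.0000  -3.94 4.31e-03
8 alpha          kappa       5.592   0.22228          8.000       0.0000 -24.22 9.00e-09
```

Reading it: the star-coupled group is recovered as an exact star on every
subject (leaf fraction 1, diameter at its 2/15 floor ≈ 0.133, κ at its
16-channel star value 8), while the chain-coupled group shows lower leaf
fraction and κ and higher diameter and eccentricity — the "path-like vs
star-like" contrast the metrics are designed to detect. Mean PLI is higher
in the chain group because chain coupling links many channel pairs at
consistent nonzero lags. `demo_out/` also contains per-subject PLI matrices,
tree edge lists, `metrics.tsv`, `correlation.tsv` and a run log.

A command-line front end with `simulate` and `run` subcommands is installed
at `system.file("cli", "plitree-cli.R", package = "plitree")`.

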