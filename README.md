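# swayclust

Clustering of quiet-standing postural sway from motion-capture marker
trajectories, aimed at post-stroke movement analysis.

## What it does, and for whom

Post-stroke motor recovery is usually tracked through summary posturography
(center-of-pressure area, velocity), which has correlated poorly with
demographic factors such as days after stroke onset. `swayclust` implements
a shape-based alternative for researchers working with marker-based motion
capture of quiet standing: short windows of the multivariate trajectory are
clustered by their temporal shape, and the clusters — not individual sway
summaries — are then related to kinematic variables and to recovery time.

A recording is 30 s of 10 body markers (shoulder, hip, knee, ankle, toe;
left and right) plus the center of mass (COM), each in X/Y/Z — 33 kinematic
variables at 60 Hz. The pipeline:

1. **Standardize** — offset every variable by the time-averaged ankle-pair
   midpoint; divide by the summed segment lengths *l₁ + l₂ + l₃*
   (shoulder–hip, hip–knee, knee–ankle mean marker distances), making the
   data dimensionless; zero-phase double-pass 2nd-order Butterworth low-pass
   at 12 Hz; cut into *t*-second non-overlapping **data slots** (30 s at
   *t* = 5 gives 6 slots of 300 × 33).
2. **Cluster** — pairwise dynamic-time-warping (DTW) distances between slots
   (symmetric step, no window; per-variable alignments summed by default),
   then *K*-cluster partition-around-medoids (**DTW-PAM**, random
   initialization, best of 10 restarts by total cost) or DTW barycenter
   averaging centroids (**DTW-DBA**).
3. **Select (t, K)** — grid over *t* ∈ {3, 5, 6, 10} s and *K* ∈ {3, 4, 5}
   scored by Calinski-Harabasz (higher better), Davies-Bouldin (lower
   better) and Dunn (higher better), all evaluated in DTW space:
   DB = (1/K) Σᵢ maxⱼ≠ᵢ (δᵢ+δⱼ)/d(cᵢ,cⱼ),
   C-H = [(N−K)/(K−1)] · BGSS/WGSS, D = d_min/d_max.
4. **Explain** — per slot and variable compute sway **amplitude**
   (max − min), **SD**, and **sway frequency** (dominant FFT peak, 0.2 Hz
   resolution at *t* = 5); compare each between clusters with a gated
   post-hoc test (Tukey-Kramer if all clusters pass Shapiro-Wilk and
   Bartlett; otherwise pairwise Wilcoxon with Benjamini-Hochberg
   adjustment), and tabulate cluster membership against days after onset.

Because clinical recordings are rarely shareable, the package includes a
synthetic cohort generator (`generate_cohort()`) with planted cluster
structure — sway sinusoids in the 0.5–1.5 Hz band, upper-body amplitudes
exceeding lower-body, CH/CI metadata, optional onset-day cluster drift —
used by the test suite and the acceptance script.

## Worked example

```r
library(swayclust)

coh   <- generate_cohort(cohort_spec(n_subjects = 8, duration = 15, seed = 42))
slots <- preprocess_cohort(coh$recordings, t = 5)
length(slots)            # 24 slots = 8 recordings x 3 slots
#> [1] 24
dim(slots[[1]]$data)     # 5 s at 60 Hz, 33 kinematic variables
#> [1] 300  33

dm  <- dtw_distance_matrix(slots)
sol <- pam_cluster(dm, K = 4, restarts = 10, seed = 42)
sol
#> <sway_clustering> PAM, K = 4, n = 24, total cost 187.52
#> cluster sizes: 6 6 6 6

calinski_harabasz(sol, dm = dm)   # 214.9569  (higher = better separated)
davies_bouldin(sol, dm = dm)      # 0.4399391 (lower = better)
dunn_index(dm, sol)               # 1.695271  (> 1: clusters farther apart
                                  #            than their own diameters)

feats <- featurize(slots, sol)
tab   <- build_significance_table(feats)
head(tab[tab$parameter == "amplitude",
         c("variable", "part", "side", "axis", "branch", "pairs")], 4)
#>    variable     part side axis   branch                        pairs
#> 1         1      com         X wilcoxon 1&2, 1&3, 1&4, 2&3, 2&4, 3&4
#> 4         2      com         Y wilcoxon 1&2, 1&3, 1&4, 2&3, 2&4, 3&4
#> 7         3      com         Z wilcoxon 1&2, 1&3, 1&4, 2&3, 2&4, 3&4
#> 10        4 shoulder    L    X wilcoxon 1&2, 1&3, 1&4, 2&3, 2&4, 3&4
```

The four planted clusters are recovered as four equal groups of 6 slots;
every cluster pair differs significantly in COM/shoulder amplitude via the
Wilcoxon branch (the sway parameters are not normally distributed, so the
gate routes away from Tukey). `cluster_characteristics()` and
`build_transition_table()` then relate clusters to subject metadata — see
the methods vignette (`vignettes/sway-clustering-methods.Rmd`) for the full
model description, parameter defaults and design decisions.

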