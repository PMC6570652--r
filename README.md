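# engramtrack

Analysis pipeline for calcium-imaging studies of hippocampal **engram
cells** — neurons tagged by activity-dependent reporter expression during
learning — and the question of whether their population activity is stable
and reactivated across learning, post-learning sleep (NREM/REM) and memory
retrieval, in contrast to the surrounding non-engram population.

The package is aimed at labs doing head-mounted miniature-microscope
recordings who have already extracted per-cell transient traces and want the
downstream population analyses, and at methodologists who want those
statistics with a fully controlled synthetic benchmark.

## What it computes

Given per-session cell × time transient matrices over a shared cell registry
(sessions A–F: learning, NREM1, NREM2, REM, retrieval, different context),
plus a reporter snapshot:

- **Engram labelling** from the snapshot: 2× binning, flat-field division by
  a low-passed (r = 20 px) copy, top-8% intensity threshold, binary cleanup,
  closing, watershed particle separation, area filtering, and a geometric
  ROI-to-cell match.
- **Repetition of correlation structure** during learning: sliding-window
  (1 s / 200 ms) correlation matrices Ĉ(t), their overlap
  M(t,t′) = (1/(N(N−1))) Σ_{i≠j} C\_ij^t C\_ij^{t′}, the repetition statistic
  Σ_t M_total(t) over the first 60 s, and a Monte-Carlo shuffle null.
- **Population-vector distance**: restricted Mahalanobis distance of each
  session to learning, PVD(X,Y) = sqrt(Σ of the 10 largest
  [v_i′(μ_X−μ_Y)]²/λ_i over the pooled-covariance eigendimensions), making
  groups with ~10× different cell counts comparable.
- **Sub-ensemble decomposition**: NMF (D ≈ BH, Frobenius cost, multiplicative
  updates + projected-gradient refinement, best of many random restarts) with
  the pattern number selected by AICc; patterns are unit-norm cell-weight
  vectors, intensities tell when each ensemble activates.
- **Cross-session pattern tracking**: cosine similarity, the matching score
  MS(X,Y) (fraction of X patterns with a partner above c = 0.6 in Y),
  shuffle-null normalized MS, aligned/isolated fate triplets across
  learning → sleep → retrieval, and pattern networks.
- **Synthetic experiments** with full ground truth: planted co-active
  sub-ensembles with controlled cross-session fates, calcium-kernel
  dynamics, background Poisson transients and blob snapshots, so every stage
  above is testable without any recording.

## Worked example

```r
library(engramtrack)

cfg <- synth_config(
  n_cells = 60, engram_fraction = 0.2, n_engram_patterns = 2,
  n_nonengram_patterns = 2, pattern_size = c(3, 5),
  session_plan = data.frame(
    label = c("A", "B", "D", "E"),
    stage = c("awake", "NREM", "REM", "awake"),
    duration_s = c(30, 15, 15, 30)),
  event_rate_hz = 0.02, pattern_activation_rate_hz = 0.2, noise_sd = 0.02,
  image_size = c(300, 300), seed = 1)
exp <- generate_experiment(cfg)

# label engram cells from the synthetic reporter snapshot
labs <- identify_engram_cells(exp$snapshot, exp$session_set$registry)$labels
sum(labs == "engram")
#> [1] 12            # all 12 planted expressing cells recovered

pcfg <- pipeline_config(session_set = exp$session_set, labels = labs,
                        preset = "test", k_range = 1:3, restarts = 20,
                        overlap_shuffles = 50, span_s = Inf, seed = 1)
report <- run_pipeline(pcfg)
tables <- summarize_report(report)

tables$repetition
#>             group ratio_to_non_engram
#> 1          engram            8.310752
#> 2      non_engram            1.000000
#> 3 shuffled_engram            1.002739

tables$pvd
#>   session   engram non_engram difference
#> 1       B 1.163779   1.851285  0.6875055
#> 2       D 1.189599   1.732067  0.5424678
#> 3       E 1.215111   1.622890  0.4077789

tables$ms
#>   session    engram non_engram difference
#> 1       B 0.3333333          0  0.3333333
#> 2       D 0.6666667          0  0.6666667
#> 3       E 0.3333333          0  0.3333333
```

Reading the numbers: the engram group's correlation structure during
learning repeats 8.3× more than the non-engram group's, and destroying
cross-cell timing (shuffled engram) brings that ratio back to ~1. Engram
population vectors stay closer to the learning session than non-engram
vectors in every later session (smaller PVD). A third to two-thirds of the
learning-session engram patterns find a cosine-similar partner (> 0.6) in
sleep and retrieval sessions, while no non-engram pattern does —
the planted design: engram sub-ensembles persist, non-engram structure is
session-unique. `tables$fates` breaks the same patterns into
aligned (`+++`) / isolated (`+--`) / mixed fate triplets per sleep variant.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/engramtrack.R simulate   --seed 7 --out demo/
Rscript inst/cli/engramtrack.R engram-id  --snapshot demo/snapshot.pgm --manifest demo/manifest.json --out demo/labels.json
Rscript inst/cli/engramtrack.R pipeline   --manifest demo/manifest.json --labels demo/labels.json --preset test --seed 7 --out demo/run/
```

Snapshots use plain-text PGM (P2) in place of TIFF (no TIFF-capable R
package in the target environment; the recipe is format-agnostic).

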