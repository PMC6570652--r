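---
title: "Methods: ensemble detection and cross-session tracking of engram activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble detection and cross-session tracking of engram activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`engramtrack` implements the population-activity analyses used to ask whether
hippocampal engram cells — neurons tagged by activity-dependent reporter
expression during learning — carry a stable, reactivated representation
across learning, post-learning sleep and retrieval, in contrast to the
surrounding non-engram population. The inputs are per-session cell × time
calcium-transient matrices over a shared cell registry (sessions labelled
A–F: learning, NREM1, NREM2, REM, retrieval, different context; 20 frames/s
by default), plus a single-channel reporter snapshot for engram/non-engram
labelling. Everything downstream of transient extraction is in scope; movie
registration, transient extraction and sleep scoring are upstream of this
package and their outputs are trusted inputs.

# The statistics

## Repetition of correlation structure

Pairwise Pearson correlations are computed in a 1 s window slid in 200 ms
steps, giving a time-indexed series of correlation matrices \(\hat C(t)\)
(window midpoint \(t\)). The overlap between two time points is

\[
M(t,t') = \frac{1}{N(N-1)} \sum_{i \neq j} C^t_{ij} C^{t'}_{ij},
\]

and \(M_{\mathrm{total}}(t) = \sum_{t'} M(t,t')\) measures how often the
correlation pattern at \(t\) recurs. The scalar statistic is the sum of
\(M_{\mathrm{total}}\) over the analysis span (first 60 s of learning by
default). Significance comes from a Monte-Carlo null (10,000 resamples at
study scale) that randomizes each cell's time course independently.

Numerical choices: cells with zero variance inside a window get zero
correlations (and a zero diagonal entry) rather than being dropped, so
matrix shapes are stable; the self term \(t'=t\) is included in
\(M_{\mathrm{total}}\) — it adds the same non-negative offset to every group
and cancels in ratio comparisons. The null's default randomization is a
per-cell circular shift, which preserves each cell's autocorrelation while
destroying cross-cell timing; per-cell bin permutation is available via
`scope = "permute"`.

## Restricted Mahalanobis population-vector distance

For one cell group, each frame's activity vector is a sample. Two sessions X
and Y are compared through the covariance of the pooled sample: with
eigenpairs \((\lambda_i, v_i)\), each eigendimension contributes
\(s_i = [v_i^\top(\mu_X - \mu_Y)]^2 / \lambda_i\), and

\[
\mathrm{PVD}(X, Y) = \sqrt{\max_\varphi \sum_{i=1}^{10} s_{\varphi(i)}}
  = \sqrt{\textstyle\sum \text{(10 largest } s_i)}.
\]

The maximum over a bijective reordering of a fixed number of independent
terms is simply the sum of the largest terms; the equivalence is verified
against exhaustive subset search in the tests. Restricting to 10 dimensions
makes a ~20-cell engram group comparable to a ~10× larger non-engram group,
since the unrestricted Mahalanobis distance grows with dimension.

Design notes: the projection term is squared — an unsquared projection can be
negative, cannot sit under a square root, and is not a distance; the squared
form is the standard Mahalanobis quadratic form and is what this package
computes. Eigenvalues at or below a floor (default
\(10^{-10}\,\mathrm{tr}(\Sigma)/N\)) are excluded from candidacy to avoid
division blow-ups; if fewer than 10 usable dimensions remain the distance
uses what is available and flags the truncation. Population vectors default
to per-frame samples; a bin width is exposed.

## NMF sub-ensemble decomposition with AICc

The cells × frames matrix \(D\) is factorized as \(D \approx BH\) with
\(B \ge 0\) (columns: co-activation patterns over cells) and \(H \ge 0\)
(rows: activation intensity over time), minimizing
\(E = \sum_{ij}(D_{ij} - (BH)_{ij})^2\). Each random restart runs
multiplicative (Lee–Seung) updates to near-convergence (200 iterations or
relative improvement below \(10^{-6}\)), then a projected-gradient
refinement with backtracking (≤ 100 steps; "additive" optimization realized
as projected gradient, since only the word itself is specified upstream).
The best of 1000 restarts (study scale; 50 at desk scale) is kept. Cost
decreases monotonically by construction; this is asserted per iteration in
the tests.

The pattern count K is chosen by the corrected Akaike information criterion
under a Gaussian residual model:

\[
\mathrm{AICc}(K) = n \ln(E_K/n) + 2p + \frac{2p(p+1)}{n - p - 1},
\qquad n = NT,\; p = K(N+T),
\]

minimized over a K range with ties going to the smaller K. The parameter
count ignores the K-dimensional scale gauge (each column of B can trade a
factor with the matching row of H); `gauge = "minus1"` uses
\(p = K(N+T-1)\). An \(E\) floor guards the exact-fit limit. Negative dF/F
entries violate non-negativity and are clipped at zero with the clipped
fraction recorded. Engram and non-engram groups are always factorized
separately per session.

After fitting, pattern columns are normalized to unit L2 norm with the scale
absorbed into H, leaving BH unchanged — the gauge in which cosine
comparisons are meaningful.

## Matching score and pattern fates

With unit-norm non-negative pattern vectors, the dot product is the cosine
similarity. The matching score between the pattern sets of sessions X and Y
is

\[
\mathrm{MS}(X,Y) = \frac{1}{N_X} \sum_{i \in X}
  \Theta\!\Big[\sum_{j \in Y} \Theta(v^X_i \cdot v^Y_j - c) - d\Big],
\]

the fraction of X patterns with at least one partner in Y above threshold
\(c = 0.6\). \(\Theta\) is strict (a cosine of exactly \(c\) does not
count), and any \(d \in (0,1)\) is equivalent because the inner sum is an
integer; \(d = 0.5\) is fixed. MS is asymmetric in (X, Y) by definition.

The MS shuffle null re-factorizes sessions whose timestamps and neuron
indices have both been shuffled (40 resamples at study scale), re-selecting
K per shuffle with the same AICc procedure (a flag can freeze K instead);
the normalized MS is the observed value minus the shuffle mean.

Fate classification tracks each learning-session pattern: "present" in a
later session iff some pattern there exceeds cosine \(c\). Triplets cover
(learning, sleep, retrieval), with sleep = NREM (B or C) in one variant and
REM (D) in the other; `aligned` = `+++`, `isolated` = `+--`, and the two
mixed triplets complete the partition, so per-group fractions sum to one.
Presence in the different-context session F is reported alongside. The
pattern network connects (session, pattern) nodes whose cosine exceeds
\(c\) across distinct sessions; connected components are pattern lineages.

## Engram identification from the reporter snapshot

The snapshot is binned 2× (block mean) and divided pixel-by-pixel by a
low-passed version of itself (Gaussian blur, \(\sigma = r/2\) with
\(r = 20\) px, edge-renormalized so a flat field maps to 1). Thresholding
keeps exactly the top 8% of pixel intensities (ties broken by intensity then
raster order; the kept count is within ±1 of `round(0.08 P)`). The binary
mask is cleaned (a set pixel survives with ≥ 2 of 8 neighbours set — a
faithful-intent reading of the ImageJ "Iteration 1, Count 2" binarization,
not a bit-for-bit one), closed once, and touching particles are split by a
watershed on the chamfer distance transform. Components are filtered by area
(defaults \(\pi 2^2\)–\(\pi 15^2\) binned px; unspecified upstream, exposed
as parameters). A cell is labelled engram iff at least one ROI centroid lies
within the match radius (default: mean ROI equivalent radius) *and* the cell
centroid falls inside the ROI mask — an explicit geometric criterion
replacing human visual scrutiny, for reproducibility. Manual
snapshot-to-movie alignment is replaced by an optional user-supplied 2-D
translation.

One property worth stating: flat-field division only *increases*
blob-to-background contrast when the illumination is non-uniform. On a
perfectly constant background the blob slightly inflates its own local mean,
so the ratio drops marginally; the tests therefore probe the contrast
property on a shaded background, which is the situation the operation
exists for.

Snapshots are read and written as ASCII PGM (P2) — a plain-text grayscale
image format — because no TIFF-capable R package is available in the target
environment; the in-memory representation and the recipe are format-agnostic.

# The synthetic-data generator

`generate_experiment()` emulates the recorded world: ~10:1
non-engram:engram cell ratio (defaults `n_cells = 200`,
`engram_fraction = 0.1`), sessions A–F with durations 360/60/60/60/180/180 s
at 20 frames/s, background per-cell Poisson transients, and planted
co-active sub-ensembles. A pattern activation makes its member cells co-fire
with amplitudes proportional to their participation weights (drawn from
(0.5, 1], matching the synchrony model NMF assumes); impulse trains are
convolved with a peak-normalized difference-of-exponentials calcium kernel
(rise 0.1 s, decay 0.8 s — plausible indicator kinetics, exposed as
parameters, not claimed as biology) and receive additive Gaussian noise
before clipping at zero. Engram pattern membership is fixed across sessions;
each engram pattern has a fate plan (which sessions it is active in), with
defaults cycling aligned (A–E), isolated (A only) and mixed (A, E)
categories and half of the aligned patterns also active in F. Non-engram
patterns are redrawn per session by default, so they carry no cross-session
structure. Engram cells also receive background events, so the groups differ
statistically, not trivially. The snapshot places a Gaussian blob (default
peak 2000 over background 200, noise SD 40) at each engram cell's centroid
over a gently shaded background.

Event rates and SNR are not documented for the original recordings; the
defaults (background 0.05 Hz/cell, pattern activations 0.2 Hz, noise SD
0.02 against unit-amplitude events) were chosen once for testability and are
all exposed in `synth_config()`.

What a green test does *not* establish: the generator has no photobleaching,
no motion artefacts, no spike-to-fluorescence nonlinearity, no overlapping
ROIs or crosstalk, and its background events are temporally unstructured.
Passing the end-to-end checks means the statistics recover what was planted
under these idealized conditions — not that the biological effect sizes
would be reproduced on real recordings.

# Scaling and determinism

Study-scale defaults (1000 restarts, 10,000 overlap shuffles, 40 MS
shuffles) are what the CLI and `pipeline_config(preset = "paper")` use; the
`"test"` preset (50 restarts, 200 overlap shuffles, 5 MS shuffles) exists so
the whole pipeline runs in minutes on one CPU. The test suite and the
acceptance checks use the test preset and smaller worlds; the statistics
under test are scale-free in those parameters (restart count affects only
optimization quality, shuffle count only null resolution).

Small-group caution: with very few cells per group (≈10), broad
background-driven NMF components can spuriously cosine-match planted sparse
patterns (two patterns over 10 cells sharing 5 members have cosine
\(\approx \sqrt{5/10} > 0.6\)). Group sizes of ~20 cells and up, as in the
default world, avoid this; it is a property of cosine geometry at low
dimension, not of the matching score.

All randomness flows through R's RNG: every generator, shuffle and restart
is reproducible from a single integer seed, and the pipeline derives
per-stage seeds from its master seed.

# Known limitations

- The AICc parameter count for NMF is a convention; model-order selection is
  only validated on the generator's world (it recovers planted K at high
  SNR and prefers small K on structureless data).
- The watershed is a plain distance-transform flood; heavily overlapping
  cells with no intensity saddle will not be split.
- The engram/non-engram label criterion is geometric; it cannot reproduce
  judgement calls a human would make on irregular or non-neuronal ROIs
  beyond the area filter.
- Group-level statistics across animals (t tests, ANOVA) are intentionally
  out of scope; the pipeline emits per-animal values.
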