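---
title: "Connectivity-based parcellation of the subthalamic nucleus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based parcellation of the subthalamic nucleus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stnparc)
```

## The problem

The subthalamic nucleus (STN) is a small diencephalic nucleus and a major
target of deep brain stimulation. Animal tracing work describes three
functional territories — an anterior limbic, a middle associative and a
posterior motor zone — but the STN is too small for these to be delineated
directly on clinical MRI. `stnparc` implements the analysis chain that
recovers this organisation indirectly, from connectivity: every STN voxel
is characterised by its whole-brain probabilistic-tractography profile,
voxels with similar profiles are clustered, and the resulting sub-regions
are related back to cortical and subcortical targets.

The package deliberately starts *after* tractography. Its inputs are
per-seed-voxel probability-of-connection (PICo) count maps — for each seed
voxel, how many of a fixed number of streamline samples (default 5000)
reached each brain voxel — together with ROI label volumes. Fibre
modelling, streamline sampling and spatial normalisation are upstream
concerns; their parameters (samples per voxel, curvature threshold) are
carried as metadata only.

## Parcellation model

For one subject, let the STN contain $N$ seed voxels with profiles over
$V$ target voxels.

1. **Binarization.** Each profile entry becomes 1 when its count reaches
   a fraction (default 1%) of the samples per voxel; with 5000 samples
   the cut sits at a count of 50. Comparisons are inclusive ($\ge$)
   throughout, except where noted below.
2. **Cross-correlation.** $C$ is the $N \times N$ Pearson correlation
   matrix of the binarized rows, with no down-sampling or binning. Seed
   voxels with constant binary profiles have no defined correlation;
   they keep their diagonal 1, get off-diagonal 0, stay in the matrix
   (so $N$ is preserved) and are flagged.
3. **Ward clustering.** The rows of $C$ are the feature vectors.
   Agglomerative Ward linkage on Euclidean row distances merges, at each
   step, the pair of clusters whose union minimally increases the total
   within-cluster sum of squared errors. We use `stats::hclust`'s
   `"ward.D2"` (Lance–Williams update) and validate its cuts against a
   direct greedy minimum-SSE-increase agglomeration in the test suite.
4. **Model selection.** Cutting the tree at each $K = 2 \ldots 20$
   yields a partition with
   $$W_{SSE}(K) = \sum_{k=1}^{K} \sum_{i \in k} \sum_{j=1}^{N}
     \Big(C_{ij} - \tfrac{1}{|k|}\sum_{m \in k} C_{mj}\Big)^2,$$
   compared against the total
   $T_{SSE} = \sum_{i,j} (C_{ij} - \bar{C}_{\cdot j})^2$; the fractional
   variance explained is $1 - W_{SSE}/T_{SSE}$. Because coarser cuts of
   the same tree merge clusters, $W_{SSE}$ is non-increasing and the
   variance explained non-decreasing in $K$, reaching 1 at $K = N$ and 0
   for the single-cluster partition.
5. **Elbow criterion.** The historical practice of reading the elbow
   visually is replaced by an objective rule: the elbow is the interior
   $K$ maximising the negated discrete second difference
   $-(v_{K+1} - 2v_K + v_{K-1})$ of the variance-explained curve — its
   most concave point. Ties (within $10^{-9}$, so the tie-break does not
   depend on rounding noise) resolve to the smaller $K$; a curve with no
   concave point returns $K_{min}$ with a warning.
6. **Naming and consolidation.** With $K = 3$, clusters are ordered by
   the world-$y$ coordinate of their centroid: anterior (limbic), middle
   (associative), posterior (motor). Cluster ids from a dendrogram are
   arbitrary, so consolidation across subjects matches clusters by these
   axis names, never by id. A group voxel receives the label with the
   highest across-subject frequency, provided that frequency reaches the
   presence threshold (default 25%, inclusive); otherwise background.

## Sub-region connectivity and overlap classes

Per subject and named cluster, the member seed-voxel binary profiles
are aggregated voxel-wise into a presence map. The default rule marks a
target as connected when at least a quarter of the cluster's member
voxels connect to it. The alternative any-member rule (maximum over
members) is available behind a flag but saturates for realistic cluster
sizes: with $m$ member voxels and per-entry noise rate $q$, a spurious
target fires with probability $1 - (1-q)^m$, which is already ~0.92 at
$m = 50$, $q = 0.05$ — every distribution then covers nearly the whole
brain and the overlap analysis degenerates to all-LAM. Requiring a
member quorum keeps the re-estimated distributions specific while
leaving every noiseless identity unchanged (for a single member voxel
any rule reduces to that voxel's thresholded profile). A count-sum
variant binarized against the member count scale is also provided.
Averaging the per-subject presence maps gives one group distribution
per cluster, with values that are exact multiples of $1/n_{subjects}$.

Target voxels are then hard-segmented by the argmax distribution among
those reaching the presence threshold, and every ROI voxel is classified
by the *subset* of the three distributions reaching it: the seven
non-empty subsets of {limbic, associative, motor} (L, A, M, LA, LM, AM,
LAM). Region composition tables report the proportion of each class
among a region's connected voxels. Argmax ties resolve in the fixed
order anterior < middle < posterior.

Group presence classes for region tables partition $[0, 100]$: none
$[0, 25)$, weak $[25, 50]$, strong $(50, 100]$. The weak band is closed
at both ends and the strong cut strict, matching the operational
definition "present in 25–50%" vs "more than 50%"; the 25% cut is
inclusive because its operational form is "3 or more of 12 subjects".

## Population tissue priors

The tissue module fits a groupwise mixture of bivariate Gaussians to
spatially normalised two-channel quantitative images (an MT-like channel
in percent units and an R2*-like channel in 1/s). Because the images are
quantitative, class means and covariances are shared across subjects;
the voxel-wise class priors $\pi_g(x)$ are shared too and are the
population tissue probability maps. EM maximises

$$\sum_s \sum_x J_s(x)\, \log \sum_g \pi_g(x)\,
  \mathcal{N}(y_s(x);\, \mu_g, \Sigma_g),$$

where $J_s(x)$ is the subject's Jacobian determinant. The weighting
enters every M-step through the responsibilities: a voxel that expanded
under normalisation represents more native-space tissue and counts
proportionally more. With $J \equiv 1$ the fit reduces exactly to the
unweighted mixture (verified to $10^{-6}$ in the tests). Numerical
choices: k-means initialisation on pooled intensities under a fixed
seed (classes ordered by the first channel for stable identities), a
ridge of $10^{-6}$ times the pooled channel variance on every
covariance, densities computed in log space, convergence when the
weighted log-likelihood — which is non-decreasing by construction —
improves by less than $10^{-6}$.

ROI priors are extracted by smoothing a probability map with a Gaussian
of 5 mm FWHM ($\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$, converted to
voxels through the affine) and binarising at 0.01. The smoothing is a
separable convolution with edge renormalisation, so constants are
preserved exactly and the dilation behaves correctly at volume borders.
Note that this mass-preserving kernel means an isolated unit voxel
spreads to a peak of about 0.007 at 5 mm FWHM — below the 0.01 cut; the
protocol is meant for multi-voxel ROI masks, whose plateaus the cut
genuinely dilates. Label assignment maximises the joint probability
$\pi_g(x)\,\mathcal{N}(y(x))$ over an explicit candidate set (typically
white matter plus the ROI), not over all classes.

## Literature normalisation

The literature module turns a table of tract-tracing report counts
$N_{ck}$ (region $c$, connection class $k \in$ {STN-afferent,
STN-efferent, paraSTN-afferent, paraSTN-efferent}) into
$$P_{ck} = 100\, \frac{N_{ck}}{\sum_c N_{ck}}, \qquad
  P n_{ck} = 100\, \frac{P_{ck}}{\sum_{k=1}^{4} P_{ck}},$$
so that ribbon widths are comparable across classes despite afferents
being reported far more often than efferents. Both normalisations sum
to 100 within their scope; all-zero classes or regions are flagged, not
divided by. The export is a generic (region, class, Pn, colour) CSV for
chord-diagram renderers; graphics are out of scope.

## The synthetic phantoms

No imaging data ship with the package; every claim is exercised on
generated phantoms with known ground truth.

**Connectivity phantom.** An ellipsoidal 1 mm seed mask elongated along
$y$ (axis ratio 1:1.8:1, ~150 voxels, matching reported STN volumes of
about 150 mm³) is split into $k_{true}$ equal-width anterior–posterior
bands. Each band carries a binary prototype over the target voxels:
contiguous blocks, with a fraction (`prototype_overlap`, default 0.25)
of each neighbouring block shared, so the middle band is a partial
mixture of its flanking prototypes — a connectivity gradient rather than
sharply distinct zones. Within its block a prototype connects to 4 of
every 5 targets: real whole-brain profiles leave most voxels unreached,
and the 80% support keeps binarized rows from becoming constant (a
constant row has no defined correlation, which would make the
single-prototype limit degenerate). Profiles are the band prototype
scaled to the sample budget, perturbed by per-subject prototype jitter
(default 0.02; the study quantifies no inter-subject profile
variability, so this is a free parameter reported in the manifest) and
per-entry Bernoulli flips (`flip_noise`). Defaults: 12 subjects (the
study cohort size), 600 targets, $k_{true} = 3$.

Target ROIs are contiguous chunks of the prototype core blocks, so each
region is dominated by one prototype and sub-region recovery has a
known right answer.

**What the phantom does not emulate:** streamline geometry,
distance-dependent PICo decay, registration error, or spatially
correlated noise. Passing tests therefore validate the *analysis* —
thresholding, correlation, clustering, model selection, aggregation —
not tractography itself; performance on real data depends additionally
on upstream quality.

**Tissue phantom.** Voxel classes are drawn from shared spatial priors
(default: three slabs along $x$ with local prior 0.85), intensities from
the class's bivariate Gaussian at a realistic quantitative-MRI scale
(CSF-like, grey-like, white-like means), and Jacobians uniformly from
`jacobian_range` (default [0.9, 1.1], small normalisation-scale volume
changes). Three well-separated classes are the default because the
phantom validates estimator correctness — parameter recovery within
sampling error and ≥95% label accuracy — not segmentation difficulty.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale: 20
single-subject phantoms of ~150 seed × 600 target voxels for
cluster-number recovery, 4–6 subjects for group stages, $10^3$–$4
\times 10^3$ voxels for the tissue fits, 50 random matrices ($N \le
12$) against naive-loop SSE oracles and $N \le 8$ against the greedy
Ward oracle. These sizes give stable statistics while keeping the whole
suite in seconds; all generators, sweeps and fits are deterministic
given their seed (Mersenne–Twister, fixed normal inversion).

## Known limitations

- One common grid per run is assumed; mixed-resolution pipelines must
  resample upstream (registration is out of scope by design).
- The elbow rule returns a single $K$; multi-elbow curves surface only
  through the stored sweep table.
- The cortical 2%-of-maximum threshold is computed per subject, as the
  protocol describes; a group-level variant is not provided.
- Zero-variance seed voxels are retained with zero correlation, which
  slightly dilutes $T_{SSE}$ when many seeds never connect.
- The EM fit assumes one shared intensity distribution per class across
  subjects — appropriate for quantitative maps, wrong for un-normalised
  weighted images; no bias-field or spatial-MRF regularisation is
  included.
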