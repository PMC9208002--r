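---
title: "Multiscale dynamic functional network connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale dynamic functional network connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msfnc)
```

## The model

`msfnc` treats resting-state fMRI as a linear mixture of spatial functional
sources. A subject's masked data form a voxels × time matrix $Y$; a source
is a spatial map $m_k$ (voxels) with an activity time course $a_k(t)$, and
$Y \approx \sum_k m_k a_k^\top + \varepsilon$. Spatial ICA estimates the maps
as maximally independent *over voxels*, so the time courses may be — and in
the brain are — correlated; that correlation, the functional network
connectivity (FNC), is the object of study, not a nuisance.

The package's premise is that the decomposition has no single correct
granularity. The ICA model order $N$ sets how finely the brain is parcelled:
a low order merges covarying subnetworks into one large-scale network; a
high order splits them. Because a coarse network is *not* simply the union
of its fine subnetworks (the subnetworks overlap it imperfectly and carry
activity of their own), decompositions at several orders contain
complementary information. `run_multiscale()` therefore repeats the whole
group-ICA chain at each requested order and all downstream stages treat the
pooled set of ICNs — within-order and between-order pairs alike — as one
connectivity system.

### Group decomposition

Per order, the chain is the standard group spatial ICA:

1. **Subject spatial PCA** (`subject_pca`): each subject's voxels × time
   matrix is reduced to $d$ whitened spatial components, $d$ chosen as the
   smallest dimension retaining 99.99% of variance (`var_retained`). This is
   essentially lossless; its role is normalisation (each subject contributes
   an equally scaled, whitened block) plus a modest computational saving.
2. **Group spatial PCA** (`group_pca`): subject blocks are concatenated
   along the component dimension and the top $N$ spatial directions are
   whitened as the ICA input.
3. **Infomax ICA** (`infomax_ica`): natural-gradient Infomax, full-batch,
   starting from a random orthogonal rotation. The default score is the
   *extended* one — the kurtosis sign of every source is re-estimated each
   iteration and sources use the matching $\tanh$ score — so both
   super-Gaussian (sparse spatial maps, the typical fMRI case) and
   sub-Gaussian sources separate. The classical logistic score is available
   via `extended = FALSE`; it is the right choice when all sources are known
   to be sparse, but it is provably unable to separate sub-Gaussian sources,
   which is why it is not the default. The learning rate (0.1) anneals by
   10% whenever the update direction reverses; convergence is a relative
   weight change below `tol = 1e-6` (default cap 1024 iterations).
   Non-convergence is recorded on the result object rather than raised: in a
   100-run stability analysis a handful of stragglers is informative, not
   fatal.
4. **ICASSO stability** (`icasso`): ICA is rerun `n_runs` times from random
   initial conditions (bootstrap resampling of voxels is available but off
   by default — randomised initial conditions alone are the simpler,
   adequate regime). All runs' components are pooled, similarity is absolute
   spatial correlation, and average-linkage agglomerative clustering cuts
   the pool into $N$ clusters. The per-cluster stability (quality) index is
   mean within-cluster similarity minus mean similarity to everything else;
   the run whose components sit jointly closest to the cluster centrotypes
   (optimal one-to-one matching, Hungarian algorithm) is kept as the best
   run. Components with index ≤ 0.8 are later rejected as unstable.
5. **Back-reconstruction** (`back_reconstruct`): subject time courses are
   the OLS coefficients of each subject volume regressed jointly on all
   group maps, time point by time point (spatial multiple regression).

ICA leaves sign, scale and order undetermined. The package fixes scale
(unit-variance source maps), sign (the peak-|Z| voxel of every map is
positive) and, for comparisons, order (Hungarian matching on |r| via
`match_maps`). Those three conventions are the only discrepancies tolerated
when the test-suite compares recovered maps against planted ground truth.

### ICN selection and domains

`select_icns` scores every component of every order and keeps those that
jointly pass: ICASSO stability > 0.8; low-frequency dominance of the time
course — the ratio of integrated spectral power in 0.01–0.10 Hz to power
above 0.15 Hz (Welch spectrum: mean of Hann-windowed, half-overlapping
periodograms) at least 2; grey-matter overlap of the |Z| > 1.96 thresholded
map at least 0.5; and maximal |correlation| with artifact templates at most
0.5. The stability bar is the one criterion with a principled value; the
other three defaults are ordinary operating points for criteria that, in
practice, combine metrics with expert judgment — all are arguments, and
`report_only = TRUE` returns scores without selecting. The spectral
"dynamic range" (peak power minus the minimum above the peak) is reported
alongside. Domain labels (cognitive control, cerebellum, default mode,
subcortical, somatomotor, temporal, visual in the reference analysis) are
deliberately a configuration mechanism — template matching or an explicit
lookup — not an algorithmic claim: anatomical assignment is prior knowledge.

### Time-course cleaning

Before any FNC computation, ICN time courses pass through a fixed chain
(`clean_timecourses`): polynomial detrending to cubic order; regression of
the six rigid-body motion parameters and their backward differences (first
sample zero-padded, preserving length); MAD-based despiking (flag samples
beyond 4 robust SDs of the median, with the MAD floored by a small epsilon
so constant stretches still flag genuine spikes; flagged samples are
replaced by a cubic smoothing spline fitted to the clean samples; more than
half flagged aborts); and a fifth-order Butterworth band-pass, 0.01–0.15 Hz,
applied forward and backward. Zero-phase filtering costs an effectively
doubled order but keeps windows aligned with the underlying signal, which
matters when window assignments are compared against state labels. Each
step is idempotent on its own output; despiking finds nothing on a second
pass. Series at a different sampling rate are spline-interpolated to a 2-s
grid (`resample_to_tr`). The series is mirror-padded before the spline fit,
which removes most of the free-boundary error; what remains is inherent to
cubic splines — interior accuracy is ~7e-4 for a 0.05 Hz signal sampled at
2.21 s, while the two or three samples at an endpoint whose phase puts
curvature there can err by a few 1e-3 with any standard end condition.

### Static and dynamic FNC

`static_fnc` is the Pearson correlation over the whole scan. Dynamic FNC
uses a taper built by convolving a rectangle (44 s, i.e. 22 samples at
TR = 2 s) with a unit-sum Gaussian (σ = 6 s) truncated at ±3σ
(`make_taper`); the taper's weights sum to the rectangle length. Windows
slide one sample at a time, and the window count convention is
$W = T - \mathrm{rect}$: with the Gaussian tails clipped and renormalised at
the scan edges, a 135-volume scan yields exactly 113 windows, which is the
convention that reconciles the reference cohort's bookkeeping
(827 subjects × 113 windows = 93,451 matrices, reproduced in the tests and
the acceptance script). Within a window, correlation is *weighted* Pearson:
taper weights normalised to sum one give the weighted means, variances and
covariances. Raw correlations are kept — no Fisher z, no regularised
precision — matching the plain-Pearson definition of FNC; every windowed
matrix is itself a valid correlation matrix (unit diagonal, entries in
[−1, 1], eigenvalues ≥ −1e−8), which the suite asserts.

### Connectivity states

States are recurring windowed-FNC patterns found by k-means
(`kmeans_custom`). The default metric is city-block, for which the correct
centroid update is the component-wise *median* (mean for Euclidean; for the
correlation metric, 1 − r on row-standardised vectors with a mean update).
Seeding is k-means++, best of `n_rep` restarts by total within-cluster
distance, empty clusters re-seeded at the farthest point. The default
strategy is two-stage: cluster only the exemplar windows — per subject, the
windows at strict local maxima of across-pair variance — then run one full
assignment pass over all windows initialised at those centroids. Two checks
of the same structure are built in as alternative strategies
(`subject_then_group`, `direct`), and the suite verifies all three
strategies and all three metrics land on the same planted centroids.

The number of states comes from the elbow of the within/between
cluster-variance ratio over k = 1…15 (`elbow_k`). "Maximum curvature" is
computed geometrically, $|r''| / (1 + r'^2)^{3/2}$ on discrete differences,
not as the bare second difference: on a curve with planted clusters the bare
second difference peaks one k *before* the bend (for four noiseless
equidistant clusters the ratio curve is 2, 0.5, 0, whose second difference
is maximal at k = 3), whereas the geometric curvature, which discounts the
steep initial descent, identifies the true k. k = 1 has zero
between-cluster variance and enters the curve as an infinite sentinel,
excluded from the scan. A curve that keeps declining steadily past the
chosen k (mean relative drop > 5% per step) has no bend — the single-cloud
signature — and falls back to k = 2 flagged `"low"` confidence.

Per-subject state means average the subject's windows assigned to each
state (absent states are recorded as missing, never imputed), and POC is
each state's share of all windows.

### Group statistics

`glm_contrast` fits, within one sex cohort, each feature on intercept,
diagnosis indicator, age, reference-coded site dummies (lexicographically
first site as reference; constant covariates are dropped as uninformative)
and mean framewise displacement, returning the diagnosis t and two-sided
parametric p. FD is the literal six-term sum of absolute first differences —
rotations in native radians — with an optional radians→mm conversion at a
50 mm radius behind the `rotation_radius` argument. The sex-specificity
statistic is `t_male − t_female`; its null (`sex_permutation_null`) permutes
sex labels *within* each diagnostic group (diagnosis labels and all
covariates stay attached to their subjects; group sizes are asserted
unchanged on every draw), refits both cohort models per draw, and reports
add-one two-sided p values, $p = (1 + \#\{|t^{null}| \ge |t^{obs}|\})/(B+1)$.
Draws that produce a degenerate cohort design (a diagnosis cell thinner
than two subjects, or collinear covariates in a small permuted cohort) are
redrawn. FDR control is Benjamini–Hochberg over one pooled vector — static
and state features, both cohorts, all orders, interaction tests — which is
deliberately more conservative than per-analysis correction.
`domain_aggregate` averages connectivity over all ICN pairs between (or
within, excluding the diagonal) each (domain × order) block; seven domains
by four orders give the 28 × 28 functional-integration matrix with
"CC25"-style labels. Symptom analyses (`symptom_correlation`) residualise
both feature and score on age, site and mean FD before correlating; the
"mean FD" covariate here follows the covariate set used everywhere else in
the package (the configuration allows substituting any covariate matrix).
BPRS totals convert to PANSS totals by monotone linear interpolation of a
supplied crosswalk table (`bprs_to_panss`), out-of-range values clamped
with a warning.

## The synthetic-data generator

The generator exists so that every stage can be tested as parameter
recovery rather than against irreproducible clinical data.

* **Sources** (`make_hierarchical_sources`): isotropic 3D Gaussian blobs on
  a voxel grid at two scales. Coarse blobs sit on a jittered lattice;
  each spawns `split_factor` children on a ring around it (child width
  0.75 σ, ring radius 0.8 σ). These constants were fixed once, from the
  geometry: each child keeps ≥ 80% of its mass inside its parent's support
  yet ≥ 10% outside the parent's half-maximum contour, sibling correlation
  stays below 0.5, and a coarse source correlates ≈ 0.94 with the union of
  its children — high enough that a low-order decomposition should find it,
  below the ≈ 1 that would make the hierarchy a trivial partition.
* **Dynamics** (`state_spec`, `simulate_state_timecourses`): a first-order
  Markov chain with geometric dwell (mean `dwell_mean` TRs) switches among
  covariance patterns; within a dwell, source samples are zero-mean
  multivariate normal with that state's covariance. Optional temporal
  smoothing (Gaussian, `smooth_sigma_trs`, applied to the innovations
  within each dwell and exactly variance-preserving) gives sources the
  low-frequency-dominated spectrum of BOLD signals; it is off by default
  (the covariance-convergence tests use the white form) and set to 2 TRs in
  `render_cohort`, without which the spectral ICN criterion would reject
  every source, since a temporally white source is not BOLD-like.
* **Subjects** (`render_cohort`): data = fine maps × time courses + a
  rank-1 motion term (a fixed random spatial pattern times the summed
  random-walk motion trace — giving nuisance regression a true positive) +
  i.i.d. Gaussian voxel noise. Diagnosis × sex cells receive configured
  covariance offsets (validated to keep every state PSD); phenotypes (age,
  site, symptom score) are drawn per subject, and mean FD is computed from
  the simulated motion exactly as the analysis stage would. `write_cohort`
  renders NIfTI volumes, SPM-convention `rp_*.txt` motion files, a TSV
  phenotype table and a JSON ground-truth sidecar.

What the generator does **not** emulate: hemodynamic convolution,
scanner-specific noise spectra and autocorrelation, spatial noise
correlations, registration error, multi-site amplitude effects. Passing
tests therefore demonstrate algorithmic correctness — that each stage
recovers what its model class can express — not robustness to the full
physics of fMRI.

One consequence is worth spelling out. The simulator's voxel amplitudes are
homogeneous: off-network voxels carry nothing but noise. Per-voxel variance
normalisation — the right preprocessing for real data, whose amplitude is
heterogeneous for non-neural reasons — then *amplifies* those empty voxels
and measurably biases recovered maps (matched |r| plateaus near 0.93
normalised versus 0.96+ raw at the test's noise level). The recovery tests
and the bundled synthetic configurations therefore decompose with
`normalize = FALSE`; the flag defaults to on and should stay on for scanner
data.

## Reference and test problem sizes

The reference configuration mirrors a large clinical analysis: four model
orders 25–100, 100 ICA runs per order, 5,000 permutations, a 44 s/σ = 6 s
taper at TR = 2 s, k from 1–15. The package's own tests and the acceptance
script exercise the identical code paths at sizes chosen to keep the whole
suite in a coffee break on one CPU: a 16 × 16 × 8 grid with 4 coarse + 8
fine sources, 12–30 subjects, orders {5, 10}, 5–10 ICA runs, 49–999
permutations, and a 50-subject × 150-TR × 12-ICN four-state problem for the
elbow. Determinism is end-to-end: one master seed fans out to every
consumer through a counter-indexed stream (`derive_seed`), so adding a
consumer never shifts the seeds of existing ones, and rerunning a pipeline
configuration reproduces its outputs bit for bit.

## Known limitations

* Infomax assumes linear instantaneous mixing; spatially overlapping
  sources with near-identical time courses merge at any order.
* The elbow rule needs a bend: gradually separating clusters or heavy
  window noise flatten the curve, and the low-confidence fallback (k = 2)
  is a convention, not an inference.
* The permutation test exchanges sex labels within diagnosis; covariates
  whose distribution differs strongly by sex reduce its power (they travel
  with the subject, as they must for validity).
* Windowed correlations at 22-sample rectangles are noisy; state centroids
  are robust but single-window assignments near dwell boundaries are not,
  and the suite only asserts assignment accuracy away from transitions.
* `bprs_to_panss` interpolates a *supplied* crosswalk; deriving one is out
  of scope.
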