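---
title: "Methods: whole-brain E/I balance mapping with eibalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain E/I balance mapping with eibalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model overview

`eibalance` implements a whole-brain analysis of excitation/inhibition (E/I)
balance from parcellated resting-state BOLD signals. The central quantity is
the per-region Hurst exponent H, an index of long-range temporal
autocorrelation that decreases when a local circuit shifts toward excitation.
Around this core the package provides: functional connectivity statics and
dynamics; a biophysical mean-field model whose regional parameters are
linear in two cortical annotation maps, fitted to connectivity by
evolutionary search; covariate-adjusted case-control statistics with FDR
control; network-spreading and epicenter analyses under two null models;
and a cross-validated case-control classifier. A synthetic cohort generator
supplies data with known ground truth, so every stage is testable without
imaging data.

# The Hurst estimator

Each regional time series is modeled as fractionally integrated noise with
memory parameter d = H - 1/2. After an orthonormal Haar discrete wavelet
transform, detail coefficients at scale j are treated as independent
zero-mean Gaussians with variance sigma^2 * 2^(2dj) (the wavelet-Whittle
approximation). The innovation scale sigma^2 is profiled out in closed
form; d is found by bounded scalar optimization (tolerance 1e-6) on the
box [-0.5, 1.5], and a fit ending within 1e-4 of a bound is flagged
(`boundary = TRUE`) rather than raised as an error. Series are mean-centered
and variance-normalized first; H is invariant under this scaling within the
model, so normalization only stabilizes arithmetic.

Two implementation choices deserve note:

* **Number of levels.** The default is `floor(log2(T)) - 3`, which keeps at
  least eight coefficients at the coarsest level; fewer would make the
  coarse-scale variance estimate dominate the likelihood with noise.
* **Odd lengths.** When a level has odd length the trailing sample is
  carried unchanged into the final approximation, so the transform conserves
  energy exactly for any T (no padding of the data themselves).

An independent estimator, the log2 variance-versus-scale regression
(`hurst_logvar`, slope beta maps to H = (beta+1)/2), is kept in the package
as a cross-check; the test suite requires the two estimators to agree on
simulated fractional Gaussian noise within 0.05 mean absolute difference.

The reference implementation this mirrors exposes optimization bounds as
two intervals; we interpret them as box constraints on (d, sigma^2). With
sigma^2 profiled out only the d box binds. This interpretation is an
assumption, recorded here, not a verified equivalence with that toolbox's
internals.

# Fractional Gaussian noise generation

Synthetic series use exact Davies-Harte circulant embedding with the fGn
autocovariance gamma(k) = sigma^2/2 (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}).
The embedding length is the next power of two at or above T, then the
series is truncated to T, keeping the embedding exact. For fGn the
circulant eigenvalues are nonnegative, so a negative eigenvalue is treated
as an internal error, not a recoverable condition. The test suite verifies
the mean sample autocovariance at lags 0-5 against gamma(k) within three
standard errors over 200 replicates for H in {0.6, 0.7, 0.8}.

# Connectivity dynamics

Static FC is the Pearson correlation matrix. FCD follows the sliding-window
construction: windows of 100 samples advanced by 1, per-window FC upper
triangles vectorized and correlated pairwise; 695 time points yield the
596 x 596 FCD matrix used in fitting. Distribution summaries use the
empirical CDF of the FCD upper triangle. Three decisions that affect the
third decimal and are therefore made explicit:

* group FC is averaged after Fisher z-transform and back-transformed;
* group FCD CDFs are averaged pointwise on a 1000-point grid over [-1, 1]
  with linear interpolation, which exceeds the resolution relevant to the
  KS statistic used in fitting;
* windowed FC vectors are cross-correlated raw (not Fisher-transformed).

The KS distance is the sup-norm difference of two CDFs evaluated on the
union of their grids, treating each as a right-continuous step function.

# The parametric mean-field model

Each region carries one excitatory gating variable S_i with
Euler-Maruyama dynamics

dS_i = [-S_i/tau_s + gamma (1 - S_i) r(x_i)] dt + sigma_i dW_i,
x_i = w_i J S_i + G J sum_j SC_ij S_j + I_i,

and transfer r(x) = (a x - b)/(1 - exp(-d (a x - b))). The regional
parameters are linear in two z-scored annotation maps (a myelin proxy and
a connectivity-gradient proxy): w_i = a_w Mye_i + b_w Grad_i + c_w, and
likewise I_i and sigma_i — nine linear coefficients plus the global
coupling G, ten parameters in all. Transfer and gating constants (a = 270,
b = 108, d = 0.154, tau_s = 0.1 s, gamma = 0.641, J = 0.2609) follow the
standard reduced-model lineage; they are configuration, not fitted
quantities. SC is max-normalized before coupling. Integration uses
dt = 10 ms; gating is clamped to [0, 1] with the clamp fraction reported.

Simulations start at S = 0.05, near the low-activity fixed point. This
matters: the gating equation is strongly nonlinear, and trajectories
started above the unstable branch saturate into a stiff high-activity
state with negligible fluctuations. The informative regime for
connectivity — and the default for fitting experiments
(c_w = 0.9, c_I = 0.315, c_s = 0.01, G = 1) — sits near the knee of the
low branch, where regional excitability shapes the correlation structure.

BOLD is produced by a standard Balloon-Windkessel forward model
(four hemodynamic states per region, integrated at the same dt,
nonlinear readout, downsampled to TR = 0.6 s). Two observation details:

* **Onset transient.** The hemodynamic states start at rest, so the first
  ~30 s of BOLD are a deterministic transient that would inflate all
  correlations; fitting discards them (`bold_burn`).
* **Observation noise.** `mfm_bold(obs_noise = f)` adds white measurement
  noise with a spatially homogeneous SD equal to f times the median
  regional signal SD. The pure forward model (f = 0) is heavily low-pass
  and its Hurst exponent saturates high for every region; a small common
  noise floor (f = 0.05 is used for Hurst analyses) restores the
  scanner-like mixture in which regional signal amplitude moves measured H.

## The E/I premise as a falsifiable simulation

`ei_premise_experiment()` runs paired simulations in which the recurrent
strength w of every other region is scaled by 1.3. In the strongly
recurrent baseline used (c_w = 1.2, c_I = 0.3, G = 1), extra recurrence
drives a region into saturation: its BOLD fluctuation amplitude collapses,
the (common) noise floor dominates, and the measured Hurst exponent drops
toward 0.5. The experiment reports per-seed mean H in perturbed vs
unperturbed regions and a paired one-sided t-test. This is the package's
operational reproduction of the claim that higher local excitability
manifests as a lower Hurst exponent; it is a statement about this model
and measurement chain, not direct evidence about cortex.

## Fitting protocol

The cost of a candidate theta is (1 - r) + KS, where r is the Pearson
correlation of simulated vs empirical static-FC upper triangles and KS the
distance between FCD CDFs; invalid thetas (any sigma_i <= 0 or w_i < 0)
and diverged simulations cost +Inf. Fitting uses CMA-ES (implemented in
the package: standard rank-mu/rank-one updates with cumulative step-size
adaptation) in scaled coordinates, since the ten parameters span four
orders of magnitude. Per train/validation/test split: `n_restarts`
independent runs of `n_iterations` generations on the training cost keep
the best candidate of every generation (the reference budget 50 x 5 yields
250 candidates); candidates are re-scored on validation; the top 10 are
re-scored on test; the best test theta is retained, and per-split thetas
are averaged.

Randomness is handled deliberately. Within one training run all candidate
evaluations share one simulation seed (common random numbers), so the
search surface is deterministic and the optimizer does not chase noise.
Each restart, however, gets its own evaluation seed: a single simulated
path biases the cost surface in a theta-dependent way, and restarts that
all share one path simply replay the same bias — independently seeded
restarts explore differently-biased surfaces and populate the candidate
pool from more than one basin. Validation and test re-scoring averages
two independent simulations per candidate (`n_select_runs = 2`), because
with single-path scoring the bias exceeds the cost separation between the
true optimum and mirror-compensated rivals.

Desk-scale parameter recovery (N = 40 regions, 400 TR, budget 20 x 3, two
splits) is part of the acceptance suite: data generated from a known theta
must be fitted back so that the recovered w map rank-correlates with the
true one above 0.8. Design points that make this a well-posed experiment:

* the "empirical" data are the Fisher-z group average of 15 independent
  runs per split — the training-split size of the reference protocol, and
  necessary: a single 400-TR run carries so much sampling noise that the
  FC correlation attainable even by the generating theta is about 0.25,
  too weak a target for any direction to be identified;
* the generating theta carries strong w heterogeneity
  (a_w = 0.3, b_w = -0.2; induced w spans roughly [0.2, 1.4]). Recovery
  of a map direction is only meaningful when that direction dominates the
  cost relief; with weak heterogeneity the cost surface develops a
  near-mirror basin (regions equidistant from the knee on either side
  look alike through FC) and the fitted sign is undetermined at this
  budget.

Even so, the experiment sits at the edge of what this desk scale can
identify, and that should be understood when reading its result. The
ceiling is single-run FC reliability: in the fluctuation-driven regime a
400-TR run's FC correlates only ~0.5-0.6 with its own ensemble mean, so
the relief separating well-fitting candidates is a few hundredths of cost
— comparable to the residual evaluation noise after the variance-reduction
steps above. Across independent replicates of the full experiment
(different substrate/search seeds) the recovered-map Spearman is high in
most runs (values near 0.97-0.99) with a left tail (values near 0.7-0.8)
in which one split's winner under-expresses one of the two annotation
loadings. The shipped acceptance check runs one fixed-seed replicate and
therefore inherits this draw; the replicate-to-replicate spread, not the
point value, is the honest summary of what a 20 x 3 budget buys.

# Group statistics

Patient maps are z-scored region-wise against controls, hemispheres are
reordered to (ipsilateral, contralateral) via the exact homotopic pairing
for right-focus subjects, and regions are compared with ordinary least
squares value ~ group + age + sex. Cohen's d is computed from
covariate-residualized values with a pooled residual SD, so its sign
convention matches the model (negative = lower in patients). FDR control
uses Benjamini-Hochberg across regions. Surface-based analyses in this
literature often use random-field-theory corrections defined on vertex
meshes; that method has no meaning for parcel-level synthetic data, and
BH is the standard parcel-level replacement — q-values here are BH
q-values. Summary-statistic t (Welch form; identical to pooled
at equal n) and 2x2 chi-square (no continuity correction) handle
printed-table comparisons. Community summaries, partial correlations
(residual-residual correlation, t on n - k - 2 df), and PC1 scores
(standardized columns, sign fixed positive on the column-mean composite)
complete the module. Directional tests are exposed per call
(`alternative=`), defaulting to two-sided.

# Network spreading, epicenters, and nulls

Neighbor alteration is D_i = (1/N_i) sum_j d_j SC_ij over structurally
connected neighbors (optionally weighted by FC_ij), with N_i the degree;
the summary statistic is the Spearman correlation between d and D.
Epicenter likelihood is the Spearman correlation between a region's
connectivity profile (self-connection excluded) and the alteration map,
ranked descending.

Two nulls are provided:

* **Spin rotations** for bilateral spherical parcellations: a uniform
  random rotation applied to left-hemisphere centroids and its x-mirror to
  the right, with nearest-neighbor value reassignment within hemisphere.
  Values never cross hemispheres; duplication/omission under reassignment
  is accepted, as is common at parcel level. Two-sided p with the +1
  correction. A label-permutation null (`perm_pvalue`) is offered for maps
  without spherical coordinates (e.g. subcortex).
* **Degree- and length-preserving rewiring**: edges binned by Euclidean
  distance into equal-count bins; within-bin double-edge swaps, each
  accepted only if it creates no self/duplicate edge and both new edges
  remain inside the bin. Degree sequence, edge count, weight multiset and
  the binned length distribution are preserved exactly. The bin count
  trades length fidelity against chain mixing: many narrow bins starve
  the swap chain on small spatial graphs (with 10 bins only ~25% of edge
  slots ever move), while plain within-bin swapping without the in-bin
  acceptance rule drifts the mean edge length by ~28% on desk-scale
  spherical graphs. The default — 5 bins, 2000 attempted swaps per edge
  (acceptance is ~1% but attempts are cheap) — turns over most edge slots
  while holding mean-length drift under 1-2%. One-sided exceedance p,
  matching the directional question "is the coupling stronger than
  geometry alone would give". Note what this null credits to geometry: a
  map that merely follows spatial proximity is *consistent* with this
  null, by design; only coupling beyond distance effects rejects it.

# Classification

A linear support-vector classifier (C = 1; the reference names the
algorithm family but not kernel or C, so both are exposed) on regional
maps, with stratified 4-fold cross-validation repeated `n_iterations`
times. Feature selection — top k% of cortical regions by absolute
training-split Cohen's d, plus an always-included set — and feature
standardization are computed inside every training fold, so held-out data
never influence them. Accuracy averages over folds; AUC is computed from
signed decision values pooled across an iteration's folds (decision values
oriented by the training-fold class means). Permutation significance
reruns the entire pipeline under shuffled labels with a reduced iteration
count per permutation (default 10, configurable) for tractability; p-values
use the +1 correction and are therefore never zero.

# The synthetic cohort generator

The generator is the package's test bed and defines the study conditions:

* geometry: n/2 quasi-uniform centroids (jittered Fibonacci lattice) on the
  right hemisphere of the unit sphere, mirrored across x = 0, so homotopic
  pairs are exact; communities from k-means on one hemisphere, shared by
  pairs;
* connectome: edge probability proportional to exp(-dist/decay), edge count
  fixed to the requested density, minimum spanning tree always included
  (connectedness guaranteed), heavy-tailed log-normal weights (sdlog 1.5)
  decaying with distance — matching the strong sparseness of streamline
  weight distributions, which also keeps max-normalized coupling row sums
  of order one;
* annotation maps: low-order polynomials in the centroid coordinates
  (hemispherically symmetric) plus noise with SD 1/smoothness, z-scored;
* time series: independent per-region fGn. Controls use a baseline Hurst
  map h_base + h_range x myelin proxy (default 0.75 +/- 0.04), so healthy
  H follows the cortical hierarchy; patients have H reduced by delta_h in
  an affected set (default: one left-hemisphere community), with half the
  effect in homotopic partners and the focus hemisphere randomized per
  patient. Default delta_h = 0.06 gives medium-to-large regional effects
  at T = 695, in line with the medium-to-large regional effects such
  case-control designs report;
* covariates: control ages uniform 28-44, patient ages 18-63 (the two
  cohorts' printed ranges), sex Bernoulli(0.5), no covariate-group
  confounding by default;
* cognition: a linear function of subject-mean true H plus noise.

What the generator does **not** emulate: within-subject spatial correlation
of Hurst values across regions (regions are independent fGn by default;
that within-subject correlation is not an established quantity, so
independence is a modeling choice, not a claim), between-subject variability of the true Hurst maps
(every subject in a group shares the group map, so between-subject
variance is pure estimation noise; whole-cohort effect sizes on subject
means are therefore much larger than a real cohort with biological
heterogeneity would show), hemodynamic structure in the fGn branch
(model-based BOLD comes from the mean-field module), physiological noise
spectra, and motion artifacts. Passing tests therefore demonstrate the
statistical machinery under known truth, not robustness to fMRI nuisance
structure.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which every property is statistically meaningful:
68-region parcellations for cohort-level analyses (40+40 subjects, T up to
1024), 40 regions for mean-field experiments (400 TR per evaluation),
null-model calibrations with 50-150 replicates at 49-99 surrogates each.
Reference protocol sizes (5000 spins, 1000 rewirings, 1000 CV iterations,
50 x 5 CMA-ES) remain the documented defaults of the corresponding
functions; the smaller test sizes are a deliberate statistical choice and
their tolerances reflect the replicate counts used.

Reproducibility: every stochastic function takes a seed; derived child
seeds are small deterministic integers, so a master seed fixes the entire
pipeline bit-for-bit. `run_pipeline` re-executes stages rather than
caching them on disk: with seeded determinism a rerun is itself the audit
trail, which replaces content-hash-based stage skipping.

# Known limitations

* The wavelet-Whittle likelihood ignores inter-scale coefficient
  correlation; its small-sample bias (< 0.05 for H in [0.6, 0.8] at
  T = 4096) is bounded by tests but grows at short T.
* The mean-field model has one excitatory population per region — no
  explicit interneuron classes and no feedback inhibition control — so
  "E/I" enters only through the recurrent gain and the Hurst proxy.
* Spin surrogates at parcel level duplicate/omit values under nearest
  rotated reassignment; calibration is verified empirically rather than
  guaranteed analytically.
* CMA-ES with the desk-scale budget identifies the w-map direction but
  cannot be expected to pin all ten parameters; only the averaged theta
  and the induced maps should be interpreted.
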