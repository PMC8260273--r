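---
title: "Model-based connectome completion: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based connectome completion: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vconn)
```

## The problem

Connectomic datasets pair two views of the same brain: the structural
connectome (SC), a nonnegative weighted matrix of anatomical coupling
between parcellated regions, and the functional connectome (FC), the
Pearson correlation matrix of regional resting-state BOLD signals. In
practice one of the two is often missing for many subjects. `vconn`
implements model-based completion: given an SC, simulate a whole-brain
model embedding it and read off a virtual FC; given an FC, invert the
model to grow a virtual SC. Chaining both directions yields a *bivirtual*
dual of the same kind as the input — a fully synthetic surrogate — and
repeating the stochastic completion with many seeds yields a *virtual
cohort* for data augmentation.

Everything in the package runs on synthetic ground-truth connectomes from
its own generator, so all claims made by the test suite are claims about
the algorithms at desk scale, not about any neuroimaging dataset.

## The linear model (SLM)

Regional activity is a set of coupled Ornstein–Uhlenbeck processes,

$$\dot x(t) = A\,x(t) + \sigma \xi(t), \qquad A = -I + G\,W,$$

with $W$ the SC and $G$ the global coupling. The system is stable for
$G < G_{critic} = 1/\lambda_{max}(W)$; every SC is spectrally normalized
($\lambda_{max}=1$) so that $G_{critic}=1$ on a common scale. The
stationary covariance is closed-form, $C = -\tfrac{\sigma^2}{2} A^{-1}$,
and its correlation normalization is the linear prediction of FC
(`linear_sc_to_fc()`). The noise amplitude $\sigma$ cancels in the
normalization and is frozen at 1. Completion uses the reference coupling
$G_{ref} = 0.83$, the median best-fit coupling reported for this model
family on normalized connectomes; the fit achieved at a common reference
rather than a per-subject optimum costs well under a percent in this
model, and `simulate_slm()` exists mainly as the Monte-Carlo oracle that
validates the closed form.

The inverse direction is algebra: $W^* = -C^{-1}/G_{ref}$
(`linear_fc_to_sc()`), with the diagonal zeroed to avoid offsets. Only
relative strengths in $W^*$ are meaningful; the absolute scale is set by
arbitrary conventions on $\sigma$ and $G$. Two policies are exposed for
the negative entries the inversion can produce: clipping to zero (the
default, so the result is a valid SC) and the raw signed matrix
(`clip_negative = FALSE`), which preserves the exact algebraic round trip
`analytic_covariance()` → `linear_fc_to_sc()` → perfect correlation with
$W$ — the strongest oracle in the package and the first thing the test
suite checks. When an FC correlation matrix (rather than a covariance) is
the only stored input, it is treated as a covariance with unit variances,
the only consistent reading.

## The nonlinear model (MFM)

Each region is a reduced Wong–Wang neural mass with one gating variable
$S_i$:

$$\frac{dS_i}{dt} = -\frac{S_i}{\tau_S} + (1 - S_i)\,\gamma R_i + \sigma\eta_i(t),
\qquad R_i = \frac{a x_i - b}{1 - e^{-d(a x_i - b)}},
\qquad x_i = \omega J_N S_i + J_N G \textstyle\sum_j C_{ij} S_j + I_0.$$

Frozen constants: $\gamma = 0.641$, $a = 270\,(\mathrm{V\,nC})^{-1}$,
$b = 108$ Hz, $d = 0.154$ s, $J_N = 0.2609$ nA, $\omega = 0.9$,
$I_0 = 0.32$. The free parameters are the long-range coupling $G$ and the
synaptic decay time $\tau_S$; the transfer function's removable
singularity at $a x = b$ is evaluated as $1/d$. Integration is
Euler–Maruyama at `dt_ms = 1` (and `dt <= tau/10` enforced when small
$\tau$ cells are visited), with $S$ clipped to $[0,1]$ each step and the
first 10% of steps discarded.

BOLD is emulated by a standard four-state Balloon–Windkessel stage per
region (vasodilatory signal, inflow, venous volume, deoxyhemoglobin),
driven by the gating variable $S$ — the bounded, conventional choice for
this model family — with the canonical constants
$\kappa = 0.65\,\mathrm{s}^{-1}$, $\gamma_f = 0.41\,\mathrm{s}^{-1}$,
$\tau = 0.98$ s, $\alpha = 0.32$, $\rho = 0.34$, $V_0 = 0.02$, sampled at
TR = 2 s. Hemodynamic states start at the fixed point of the first drive
sample, so constant input produces a flat baseline and no onset transient
contaminates short runs. An independent ODE integration of the same
system places the impulse-response peak at 3.1 s, which the test suite
reproduces.

### Noise amplitude and run length

The neural noise $\sigma$ and the simulated duration $T$ are nowhere
printed for this model family, and they interact: near the ignition
transition the network is multistable, and for small $\sigma$ each run
freezes into whichever activation pattern its initial condition selects.
At $\sigma = 0.01$ two runs of the same 20-node system at the same
working point produce FCs correlating at only ~0.1 — the completion
would not even be reproducible against itself. A sweep of $\sigma \in
[0.02, 0.04]$ at $T = 4\times10^5$ ms showed seed-to-seed FC
reproducibility falling from 0.95 to 0.60 while the FC–SC coupling rises;
$\sigma = 0.03$ was fixed once as the compromise (reproducibility ~0.8 at
the default $T$, ~0.94 at double length) and is not revisited. The
default $T = 4\times10^5$ ms (400 s of activity, 180 BOLD samples after
transient discard) is the smallest length at which FC estimates stabilize
at desk scale; short exploratory runs use the $0.2\,T$ convention.

## Choosing the working point

The best FC rendering occurs in a narrow subcritical stripe of the
$(G, \tau)$ plane. When no empirical FC is available to fit against, the
stripe is located by three criteria computable from simulated dynamics
alone (`grid_search_working_point()`, default 9×9 grid over
$G \in [1,3]$, $\tau \in [1,100]$ ms, one short $0.2\,T$ run per cell with
a cell-specific seed):

1. **Spatial heterogeneity** of activation: variance over mean, across
   regions, of the time-averaged BOLD. A mixture of ignited and
   non-ignited regions maximizes it; far from the stripe activity is
   homogeneous. (A coefficient-of-variation variant is available via
   `type = "cv"`; the variance-over-mean form is the primary definition.)
2. **FC clustering**: mean weighted clustering coefficient of the
   time-averaged FC — structured but not globally synchronized
   correlations.
3. **dFC clustering**: mean weighted clustering coefficient of the dFC
   matrix (below) — metastable FC dynamics with "knots" and "leaps".

"Jointly optimum" is operationalized as the argmax of the **product** of
the three criteria after per-criterion min–max normalization over the
grid: a product demands all three be simultaneously high, and a cell that
fails any one criterion scores near zero. Failed cells (numerical
blow-up) score $-\infty$ and the search continues. On a 20-node synthetic
ground truth the selected point fits a held-out target FC at ~0.8 while
all four grid corners fit at ~0.

## Time-resolved FC and the dFC matrix

`sliding_window_fc()` computes Pearson FC in windows (default 60 s
advancing by 10 s at TR 2 s — the window is an analysis choice, reported
with results, within the field's standard range) and `dfc_matrix()`
correlates the strict upper triangles of every window pair. Blocks of
high inter-window correlation are epochs of transiently stable FC;
negative entries are retained in the matrix and only zeroed where a
downstream metric (clustering, PageRank) requires nonnegative weights.

## Inverting FC to SC: effective connectivity

`nonlinear_fc_to_sc()` grows an SC compatible with a target FC: starting
from a random symmetric matrix, iterate

$$SC^{(k+1)} = SC^{(k)} + \lambda\,(FC_{target} - FC^{(k)}),$$

where $FC^{(k)}$ is simulated from $SC^{(k)}$ at the frozen working point
with a fresh seed per iteration (prime-strided so that runs launched from
adjacent seeds stay independent). After each update the candidate is
projected back onto the SC manifold: symmetrized, diagonal zeroed,
negatives clipped, spectrally normalized — without the projection the
iteration drifts off the scale the working point was chosen for.
Iteration stops when the simulated-vs-target correlation reaches
`cc_target = 0.7` (then a full-length confirmation run is recorded), at
`max_iterations = 2000`, or — a divergence guard — after 50 *consecutive*
decreases of the fit. The learning rate default is $\lambda = 0.01$ (FC
entries in $[-1,1]$, SC spectrally normalized each iteration): at this
rate the fit climbs monotonically to the threshold within tens of
iterations on 20-node problems. Larger rates (0.05) look attractive but
overshoot — the candidate orbits the solution manifold, the measured fit
oscillates well below threshold for hundreds to thousands of iterations
while the hidden similarity to the true SC quietly saturates, and
termination happens only by a lucky noise spike.

The frozen working point must be chosen with care on synthetic
connectomes: the ignition threshold of the mean-field model shifts with
the drawn weight configuration even after spectral normalization, and a
coupling that is fluctuation-driven for one draw can be past ignition for
another. Past ignition the model is multistable and each run freezes
into a seed-dependent activation pattern, so the target FC itself is not
reproducible — two simulations of the *true* SC can agree at only ~0.2 —
and the inversion then stalls whenever its iterate falls into a
competing pattern basin. The package's end-to-end recovery studies
therefore select the coupling per connectome as the argmax, over a
coarse scan, of the agreement between two independent simulations of the
input SC (the synthetic analogue of selecting the working point by fit
to an empirical FC, and computable whenever an SC is available): that
reliability peak sits slightly below ignition, exactly where whole-brain
models are operated.

Two properties of this stop rule matter for interpretation. First, the
rule acts on a *noisy estimate* of the fit (a short-run FC), so the
iteration count at which it fires has a luck component that shrinks with
inner-run length. Second, all runs stop at the same fit *to the target*,
not at the same similarity *to the hidden ground truth*: across
independent random initializations the recovered-SC-to-truth correlation
varies, and at 20 regions a non-negligible part of that variation is the
sampling noise of a correlation estimated from only 190 matrix entries
(roughly $(1-r^2)/\sqrt{190} \approx 0.05$ for $r \approx 0.5$, i.e. a
~10% relative floor). Dispersion figures measured at this scale are
therefore upper bounds on the algorithm's intrinsic variability; at ~100
regions the same metric floor is several times smaller.

## Bivirtual duals and virtual cohorts

`bivirtual_dual()` chains the two completion legs of one model family
(linear: closed-form both ways; nonlinear: simulation forward,
effective-connectivity back), records both legs and their seeds in the
result's metadata, and returns a connectome of the input's kind.
`generate_virtual_cohort()` repeats the nonlinear forward completion with
consecutive seeds at a working point fitted once — instances share
$(G^*, \tau^*)$ by construction, which the suite asserts.

## Graph metrics and comparison coefficients

* Strengths are plain signed row sums (diagonal excluded).
* Weighted clustering uses geometric-mean triangle intensity with weights
  rescaled by the maximum; negatives are zeroed for this metric (a
  geometric mean of signed weights is undefined).
* PageRank (damping 0.9) is a power iteration on the weight-proportional
  transition matrix; negatives zeroed, zero-strength columns teleport
  uniformly.
* Louvain community detection is implemented natively (local moving plus
  aggregation, seeded visiting order) with the "negative symmetric"
  two-layer quality $Q = Q^+ - \frac{m^-}{m^+ + m^-} Q^-$ at resolution
  $\Gamma = 1$, since the standard library implementations refuse
  negative weights; on positive graphs it reproduces the standard
  partitions (cross-checked against an independent implementation in the
  tests). One caveat established during testing: with heavy-tailed
  weights at low density, the modularity optimum can *legitimately*
  disagree with a planted partition (splitting a true module scores
  higher) — planted-recovery checks therefore use dense modules with
  moderate weight tails.
* Partition agreement uses mutual information normalized by the larger
  entropy (RMI), with a permutation chance level at the 99th percentile.
* `delta_trivial()` and `delta_pers()` are the percent-improvement
  coefficients over, respectively, the "use the other connectome"
  shortcut and the generic (non-personalized) dual.
* Correlations between regional feature vectors can be restricted to the
  interquartile range of the reference variable
  (`iqr_restricted_correlation()`); no extrapolation beyond the IQR is
  attempted, since any extrapolation model would be an invention — the
  restricted estimate itself is reported.
* `intersubject_distance_correspondence()` correlates the two vectors of
  pairwise correlation distances of matched connectome sets.

## What the synthetic generator does and does not emulate

`generate_sc()` draws a stochastic block model (planted modules,
within-module connection probability boosted by a contrast factor) with
i.i.d. log-normal weights, repairs connectivity with minimum-weight
bridges, and spectrally normalizes — reproducing the sparse, modular,
heavy-tailed character of tractography-derived SC. Cohorts share a base
backbone; subjects differ by Gaussian jitter on log-weights plus partial
edge resampling (both scaled by one jitter parameter, preserving
nonnegativity and the heavy tail), optionally with a group-specific
multiplicative edge modulation. It does **not** emulate spatial geometry,
distance-dependent wiring, hemispheric symmetry, tractography biases
(length-dependent undercounting, false positives) or measurement noise in
FC acquisition. Passing tests therefore demonstrate the algorithms'
internal consistency and recoverability on networks with realistic
first-order statistics, not performance on real neuroimaging data.

## Numerical choices and degenerate inputs

* Symmetrization tolerance 1e-9 on read; larger asymmetries are errors,
  not silently averaged.
* SC diagonals are forced to 0 and FC diagonals to 1; all comparisons use
  the strict upper triangle.
* Matrices are written as TSV with a label header at 17 significant
  digits plus a JSON sidecar (kind, provenance, seed, method), making the
  round trip lossless to 1e-12 and every artifact self-describing.
* Supercritical couplings, singular covariances (condition number
  > 1e12), zero-variance regions, all-zero SCs, and windows shorter than
  3 samples are errors with informative messages; zero-variance regions
  inside one sliding window flag the window rather than fail the stream.
* All stochastic functions take explicit integer seeds; identical seeds
  reproduce bitwise, and derived per-iteration/per-cell seeds use prime
  strides to avoid stream collisions between runs started from adjacent
  seeds.

## Problem sizes used by the test suite

The suite exercises full pipelines on 20-node, 2-module synthetic
connectomes with default dynamics lengths ($T = 4\times10^5$ ms;
$0.2\,T$ short runs), 9×9 working-point grids, 10 effective-connectivity
restarts, and 6-subject cohorts — sizes chosen so a complete run of every
pipeline, including the end-to-end recovery checks, completes on a single
CPU in minutes while keeping the FC estimator noise small enough for the
stop rules to act on signal rather than luck.

## Known limitations

* The fit metric (upper-triangle Pearson correlation) has a sampling
  floor at small region counts that inflates any dispersion measured
  across restarts (quantified above).
* The effective-connectivity inversion recovers SC up to the information
  present in FC at one working point; weak or redundant edges are not
  identifiable.
* Linear FC-to-SC output has arbitrary scale and, after clipping,
  discards inhibitory-like negative couplings.
* The grid search scores criteria on single short runs per cell; with a
  different master seed the selected cell can move within the best-fit
  stripe (the stripe itself is stable, the argmax within it is not).
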