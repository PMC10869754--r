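---
title: "Estimating transition statistics from short trajectories: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating transition statistics from short trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vsdga)
```

This vignette is the package's account of the science it implements: the
estimators, their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic generators do and do not emulate, and
the numerical choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The estimation problem

A voltage-sensing domain switches between a resting (down) and an active
(up) conformation. Direct simulation of the transition is impractical, but
an ensemble of short trajectories — each sampling a piece of the transition
region — contains enough information to reconstruct long-time statistics,
*provided* the dynamics are Markovian over a lag time $t$. That is the only
dynamical assumption made anywhere in the package; nothing requires the
dynamics to be molecular. All estimators therefore accept any
fixed-interval `short_trajectory_ensemble`, and the test bed uses discrete
Markov chains and overdamped Langevin dynamics, for which every target
quantity has an exact linear-algebra oracle.

For a statistic $f$ expanded as $f = \gamma + \sum_i v_i \phi_i$ with a
guess function $\gamma$ carrying the boundary conditions, projecting the
operator equation onto the basis and estimating expectations as averages
over stopped trajectory segments gives the linear system
$(C_t - C_0)v = -(r_t - r_0)$ assembled by `assemble_system()`. Three
statistics use it:

* **Committor** `solve_committor()`: stopping on both states, guess
  $\gamma = \mathbf{1}_B$ (indicator basis) or the distance-ratio guess
  $d_A^2/(d_A^2+d_B^2)$ (distance basis). Reconstruction is clipped to
  $[0,1]$ *after* the solve and before any downstream use (transform,
  sampling, binning); raw values are retained for diagnostics.
* **Weights** `solve_weights()`: no stopping. Rather than solving the
  adjoint system in an arbitrary basis, the package uses the indicator
  basis throughout, where the fixed-point equation is exactly the
  stationary law of the empirical cluster transition matrix; weights are
  $w = \pi_{\text{cluster}}/\mu_{\text{cluster}}$ per frame. Distance-type
  bases tend to produce noisy, sign-indefinite weights; the cluster route
  is variance-reducing and guarantees $w \ge 0$.
* **Mean first-passage time** `solve_mfpt()`: stopping on the product state
  only, zero guess, right-hand side the basis-weighted mean elapsed time —
  the Feynman–Kac analogue of the committor system.

With the one-hot cluster basis these estimators coincide to machine
precision with a boundary-conditioned Markov state model; the suite asserts
this equivalence at $10^{-10}$, which pins down the stopping bookkeeping
(`stop_times()`) as well as the algebra.

### Numerical choices

Linear systems are solved by least squares with a relative singular-value
cutoff (`rcond = 1e-10`) rather than direct inversion: whitened bases can
still be numerically rank-deficient on finite data, and the cutoff degrades
gracefully while reporting the effective condition number. The distance
basis is whitened by SVD with a relative tolerance of $10^{-8}$; dropped
directions are counted in the report. Ties in nearest-labeled-frame
distances are irrelevant to the basis values and are left to floating-point
order.

## State definitions and bases

States are ellipses in the translocation–rotation plane; the defaults are
a down ellipse (center $(-4.24\,\text{Å}, -56.95^\circ)$, radii
$(1.1\,\text{Å}, 8^\circ)$) and an up ellipse (center
$(-0.506\,\text{Å}, 3.94^\circ)$, radii $(0.84\,\text{Å}, 7.6^\circ)$).
Angle differences are wrapped to $(-180^\circ, 180^\circ]$ so labels are
invariant under $\theta \to \theta + 360^\circ$. Additional per-feature
min/max cutoffs are supported but default to "ellipses only"; the ellipse
membership alone already separates the metastable basins cleanly, and the
cutoff mechanism stays in config for data where it does not.

The committor basis follows the boundary-conforming distance construction:
$d_A$ and $d_B$ are Euclidean distances to the nearest $A$- or $B$-labeled
frame, $h = d_A d_B/(d_A+d_B)^2$ vanishes on both states, basis functions
are standardized features times $h$, and the guess is
$d_A^2/(d_A^2+d_B^2)$. Two open choices were resolved as follows:

* **Which space the distances live in.** The states are defined by data, so
  distance-to-nearest-labeled-frame in z-scored feature space is the
  default (it adapts to feature scales and is exactly zero on labeled
  frames, making the boundary conditions bit-exact). Distance to the
  ellipse boundary in the $(d, \theta)$ plane is available as
  `mode = "ellipse"`.
* **Standardization.** Features are z-scored before distances are computed;
  without a stated convention, equalizing feature scales is the defensible
  default for Euclidean metrics over heterogeneous distance features.

The weight basis reduces features to 10 (default; 5 in the shipped
pipeline, matched to the surrogate's 2 slow modes) IVAC dimensions and
clusters with k-means ($k = 200$ by default, $k = 150$ in the pipeline;
10 restarts keeping the best inertia, MacQueen updates, re-seeded retry on
an empty cluster). $k$ trades variance (too many sparse clusters) against
bias (too-coarse stationary law); values of 100–200 are conventional for
$10^4$–$10^5$ frames.

**Lag time.** The lag is deliberately config (`lag = 5` frames in the
pipeline, i.e. 0.25 surrogate time units) and is reported alongside every
result; there is no universally right value, only the requirement that the
dynamics be effectively Markovian at the chosen lag. The chain tests assert lag
robustness (lags 1, 2, 5 agree within sampling tolerance), which is the
operative property.

## Transition-path observables

PMFs are weighted histograms, $F = -kT\log\sum w$, min-shifted per grid;
empty bins are masked (`NA`), never zero, so serialization stays finite and
minima detection cannot be fooled by unsampled regions. PMF *differences*
are invariant to the weight normalization (frame-mean $w = 1$, chosen so
weighted and unweighted sample sizes match). Voltage tilts add $Q_d V$ with
$1\,e\cdot\text{mV} = 0.0230605$ kcal/mol; `kT` defaults to 0.5961 kcal/mol
(300 K) for molecular data and to 1 for the surrogate (which is built in
kT units).

The reactive current estimator antisymmetrizes each stopped pair:
$w(s)\,[q_-(s)q_+(e) - q_+(s)q_-(e)]\,(\xi(e)-\xi(s))/(2t)$, deposited half
at the start bin and half at the end bin, averaged over pairs, then
smoothed with a Gaussian kernel of width 1 bin. The factor $1/(2t)$ makes
the two time orientations of each transition count once. The estimator is
validated by oracle equivalence rather than against a reference formula: on
chain data the binned current reproduces the exact
reactive rate through interior cuts and the exact two-channel flux split
within the tolerances asserted in the tests. The backward committor
defaults to $q_- = 1 - q_+$, valid for reversible equilibrium dynamics (the
study regime); a DGA solve on time-reversed trajectories is the
cross-check, and the suite verifies the two agree on reversible chains with
equilibrium sampling — on non-stationary data the reversed empirical chain
is biased, which is why the default is the analytic identity rather than
the reversed solve.

Time-correlation functions are plain weighted estimators normalized by
$C(0)$, with no stopping; with uniform weights they are bit-identical to
the standard autocorrelation, which the suite asserts. The biexponential
fit constrains $a_1 + a_2 = 1$ and $\tau_1 \ge \tau_2 > 0$, works in
log-time-constant parameters with Levenberg–Marquardt, and multi-starts
from decade-spaced constants across the lag range; near-equal constants or
a vanishing amplitude are flagged as degenerate rather than reported as two
timescales.

## Sparse committor models and IVAC

Committor values are mapped to the real line branch-wise (lower branch
$\ln[2q/(1-2q)]$ on $(0, 0.5)$, upper branch $\ln[(2q-1)/(2-2q)]$ on
$(0.5, 1)$; the branches are exact mirror images), then regressed on
standardized CVs under the objective
$\sum_k (\beta^\top x^{(k)} - y_k)^2 + \lambda\|\beta\\|_1$, solved by
coordinate descent on the Gram matrices (exact QR least squares at
$\lambda = 0$). Fitting points are drawn with replacement (the sampling
scheme is otherwise unspecified; with-replacement keeps the estimator
simple and unbiased) with probability $\propto w\,q_+(1-q_+)$, which peaks
at the transition state. Default penalties are 0.02 (lower) and 0.03
(upper) *per sample* in the mean-squared-error convention of common solver
libraries; the total-RSS objective above therefore receives
$\lambda_{\text{total}} = 2n\lambda$. Because a sensible penalty is
ultimately chosen by inspecting the sparsity/accuracy tradeoff,
`lasso_path()` reports the full path rather than a single fit, and both the transformed-scale and
back-transformed (committor-scale) $R^2$ are emitted, since "fit quality"
is scale-ambiguous.

IVAC integrates symmetrized time-lagged covariances over a lag window and
solves the generalized eigenproblem against $C(0)$ ridged by $10^{-10}$.
Features are mean-centered first, which removes the trivial constant mode
exactly; zero-variance columns are dropped and reported. The lag window is
config (1–5 frames in the pipeline), and the
spectral tests (eigenvalue of a two-state chain; geometric lag-window sum)
validate the estimator at any window.

## The synthetic generators — what they emulate, and what they do not

`make_vsd_surrogate()` builds a two-dimensional landscape with five
inverted-Gaussian basins ($\sigma_d = 0.55$ Å, $\sigma_\theta = 7^\circ$,
interior depths 5 kT, end depths 7 kT) along a bent path — rotation first,
then translocation, emulating loose coupling of the two motions — confined
by a harmonic penalty ($2$ kT per squared scaled unit, with $12^\circ$ of
rotation treated as one length unit) on the perpendicular distance to the
path. The end basins coincide with the default state ellipses. Adjacent
basins are separated by ~3σ, giving barriers of roughly 2–3 kT: deep
enough for metastability, shallow enough that 120-frame trajectories hop
between neighbors. Features are deterministic functions of the path
progress (monotone, single-coordinate and V-shaped variants, the latter
emulating an arginine–plug distance that shrinks and then grows) with
per-frame Gaussian noise of SD 0.35; the charge observable is a logistic
step of width 0.12 in progress with a 1 e gap and per-frame noise of SD
0.15 e. The charge noise is deliberately larger than the spacing of
adjacent per-basin charge means: that is precisely what hides the
intermediates from the one-dimensional charge landscape while the
committor resolves them, and it mirrors how instantaneous displacement
charges fluctuate in real trajectories.

Langevin dynamics use the Euler–Maruyama scheme in the overdamped limit
with per-dimension diffusion constants; for the surrogate,
$D_\theta/D_d = (\sigma_\theta/\sigma_d)^2$ so both slow coordinates relax
on comparable timescales relative to their basin widths. Start points are
uniform along the basin path with perpendicular jitter — a stand-in for
seeding short simulations from enhanced-sampling windows, not a
reconstruction of any particular protocol.

What the surrogate does **not** emulate: real molecular features are
high-dimensional, redundant and non-Gaussian; kinetics can retain memory
beyond any fixed lag; state definitions on real data carry assignment
error; and the charge observable of a membrane system couples to solvent
degrees of freedom absent here. Passing tests on the surrogate therefore
demonstrate the *estimators* are correct and that the workflow exposes
committor-hidden intermediates when they exist — not that any particular
molecular system has them.

## Problem sizes

The shipped analyses and checks use sizes chosen to give comfortable
margins over their tolerances while remaining desk-scale: chain ensembles
of $10^5$ transition pairs for committor and current checks ($4\times10^5$
for the MFPT oracle, whose error decays slowest), a 600-trajectory
barrier-oversampled double well for the reweighting check, and a
400-trajectory, 120-frame surrogate ensemble (48,400 frames) for the
end-to-end pipeline. Headline numbers with closed-form truth (60 features,
0.9 e sensing charge, transform anchors, time constants 59 and 0.04) are
recomputed exactly.

## Known limitations

* Committor quality with the distance basis depends on the informativeness
  of the feature set; on the surrogate the committor at the second basin is
  estimated slightly below its nominal value, though the minima structure
  is unaffected. An indicator-basis committor is available when features
  are weak.
* Weights inherit the bias of the cluster discretization at the chosen lag;
  reducible empirical cluster chains fall back to the largest closed
  communicating class with a warning (outside frames get zero weight).
* No block-bootstrap error bars; condition numbers and pair counts are the
  reported diagnostics.
* Trajectory I/O covers PDB and DCD (plus CSV feature tables); other
  trajectory formats must be featurized externally. Serialization uses
  CSV/JSON/YAML.
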