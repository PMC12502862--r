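---
title: "Inverting anisotropic scattering maps of driven semiflexible chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverting anisotropic scattering maps of driven semiflexible chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A semiflexible polymer held in a flow cell experiences a stretching force
along the flow direction x and a shear gradient along z. Small-angle
scattering measures the resulting structure, but the scattering pattern of a
driven chain is anisotropic, so the classical isotropic form factors
(Gaussian chain, worm-like chain, flexible cylinder) cannot be fitted to it.
`drivenchain` takes the opposite route: it simulates the driven chain,
computes its two-dimensional scattering function in the flow-velocity
gradient plane, and trains Gaussian-process regressors that map a scattering
map back to the parameters that produced it.

## The chain model

The chain is a bead-rod ("freely jointed with bending stiffness") model: N
bonds of fixed length l_b connecting N+1 joints, with joint 0 pinned at the
origin. With tangents t_i = (r_{i+1} - r_i)/l_b the energy, in units of
k_B T, is

E = sum_{i=1}^{N-1} kappa (1 - t_{i-1}.t_i)
    - f l_b sum_{i=0}^{N-1} (t_i . x)
    - gamma l_b sum_{i=0}^{N-1} z_i (t_i . x),

where kappa is the bending modulus (persistence length ~ kappa l_b for stiff
chains), f the stretching force along x, and gamma the shear coupling: each
bond's x-extension is weighted by the z coordinate z_i of its *starting*
joint. Coupling at the bond midpoint would differ by O(l_b) per bond; the
starting-joint convention is used consistently in the energy and its tests.
Self-avoidance is a hard sphere of radius l_b/2 on every joint: any
non-consecutive joint pair closer than l_b is forbidden (an exact comparison
with a 1e-12 relative slack keeps exactly-touching spheres legal).

Shear enters as a static energy term, not hydrodynamics: the sampler is an
equilibrium method throughout.

Conformation observables are the squared end-to-end distance R^2 =
|r_N - r_0|^2, the squared radius of gyration Rg^2, and the xz component of
the gyration tensor R_xz, computed in centroid form in O(N); the
half-pair-average forms are asserted equal in the tests. The end-to-end
distance deliberately uses the *last* joint r_N: with N bonds there are
joints 0..N, and stopping at r_{N-1} would silently drop one bond.

## Monte Carlo sampling

`runSimulation()` is a Metropolis sampler with two non-local move types
chosen with equal probability:

* **crankshaft** — rotate the joints strictly between two randomly chosen
  joints a < b about the a-b axis by a uniform angle in
  [-maxRotationAngle, maxRotationAngle];
* **pivot** — rotate the whole tail beyond a random pivot joint about a
  uniformly random axis through it. The anchored joint never moves.

Both moves are rigid rotations, so bond lengths are preserved exactly and a
proposal can only create hard-sphere overlaps between moved and unmoved
joints; the overlap scan exploits this (O(k(N-k)) per move). A proposal is
accepted with probability min(1, exp(-dE)) and rejected outright if it
overlaps. One sweep is N attempted moves. The initial state is a straight
rod along x, which is always overlap-free; an equilibration phase is
discarded before samples are retained at a fixed sweep interval.

Defaults and their rationale:

* `maxRotationAngle = pi/2`. At the bending stiffnesses studied
  (kappa from 2 to 20) acceptance stays far above 1%, so the optional
  auto-tuning toward ~50% acceptance (`autoTune = TRUE`, frozen halfway
  through equilibration) is off by default — a fixed amplitude keeps runs
  exactly reproducible across schedules.
* Full-scale schedule (N = 200): 20000 equilibration sweeps, 10000 sampling
  sweeps at interval 100. Desk-scale schedule (N = 50, the `"desk"`
  profile): 4000 equilibration sweeps, 24000 sampling sweeps at interval 12,
  i.e. 2000 retained configurations per run. These were calibrated once
  against the closed-form references below — not against any particular
  inversion outcome — so that the bending-only and force-only ensemble
  averages reproduce to within Monte Carlo error.
* All randomness flows through R's RNG; a run is bitwise reproducible from
  its seed, and dataset rows use per-row seeds derived from
  (master seed, row index) so any row can be regenerated in isolation.

Three closed forms pin the sampler down (they are the first acceptance
layer and are also recomputed by `scripts/acceptance.R`):

* bending only: consecutive-tangent correlation coth(kappa) - 1/kappa
  (0.9000 at kappa = 10), and tangent correlations decay as its k-th power;
* no energy at all (self-avoidance off): <R^2> = N l_b^2;
* stretch only: per-bond extension is the Langevin function
  coth(f l_b) - 1/(f l_b) (0.163953 at f = 0.5).

## The scattering function

For M = N+1 point scatterers (all joints, the anchored one included) the
normalised intensity is I(Q) = |sum_j exp(i Q.r_j)|^2 / M^2, evaluated on a
rectangular grid of Q = (Q_x, 0, Q_z) — the slice measured in the
flow-velocity gradient plane. The complex amplitude factorises over the two
grid axes, A = E_x E_z^T with E_x[a, j] = exp(i qx_a x_j), so a whole map is
two small complex outer-product exponentials and one matrix product; the
O(M^2) pair sum is kept only as a test oracle. By construction 0 <= I <= 1,
I(0) = 1 and I(Q) = I(-Q); these are validity conditions of every
`ScatteringMap`.

The default grid reproduces the full-scale protocol: 51 points per axis on
[-50 pi/L, 50 pi/L] (2601 points). Q = 0 must be a grid point (odd point
count), both for the normalisation check and so the flattened vector has a
well-defined centre. Flattening is row-major with Q_x outer and Q_z inner;
the order is fixed, documented in `flattenMap()`, and guarded by a grid
signature stored with every dataset and trained model: a map sampled on any
other grid is refused at prediction time rather than silently inverted.

Ensemble maps are plain arithmetic means over the retained samples — no
orientational average (anisotropy is the signal), no instrument resolution,
no incoherent background, no absolute calibration.

## Datasets

`buildDataset()` draws parameter combinations uniformly — kappa ~ U(2, 20),
f ~ U(0, 0.5), gamma L ~ U(0, 2), with gamma = gammaL/L applied per
simulation — runs one simulation per row, and stores the flattened maps as
the rows of a matrix F together with six per-row targets: kappa, f, gammaL
and the ensemble means of R^2/L^2, Rg^2/L^2 and R_xz/L^2. The L exponent
for the gyration quantities is configurable (`normExponent`), since both
by-L and by-L^2 conventions appear in practice; the dimensionless L^2
normalisation is the default. Rows are simulated on clean maps; a
multiplicative-noise hook exists (`noiseSD`) but defaults to off. Failed
rows are excluded with a message and recorded in the manifest.

`splitDataset()` partitions rows 70/30 by default (1680 rows split as
1176/504 at full scale). Datasets persist as a plain-text directory —
`F.csv`, `targets.csv`, `manifest.json` — with doubles rendered as %.17g so
the round trip is bitwise exact.

## SVD feasibility

`decomposeScattering()` computes the thin SVD F = U diag(d) V^T of the raw
(uncentred) matrix; the squared singular values are proportional to the
variance of the data along the corresponding right singular vector, so the
uncentred decomposition doubles as a principal-component analysis of the
map ensemble (a `center` flag exists for comparison). Each right vector's
largest-magnitude entry is made positive so projections do not flip sign
across LAPACK builds. On any dataset built by the package the spectrum
decays fast — the tenth singular value is below half the first — and the
projections FV0..FV2 arrange the maps so that nearby points have similar
parameters, which is what makes a smooth inversion map plausible in the
first place.

## Gaussian-process inversion

One independent regressor per target maps the flattened map x to a scalar
y. The prior is a GP with constant mean m (set to the training-target mean)
and kernel

k(x, x') = exp(-|x - x'|^2 / (2 l^2)) + sigma^2 delta_{x,x'},

with correlation length l and noise scale sigma; sigma^2 sits on the
covariance diagonal and sigma is the reported hyperparameter. Inputs are
the raw intensities — no log transform or feature standardisation — so
correlation lengths are comparable across targets. Because the RBF part has
unit amplitude, targets are standardised internally to unit variance about
their mean (predictions are mapped back); the reported sigma is therefore
relative to the target's standard deviation, one common scale for all six
targets. `scaleTargets = FALSE` disables this for raw-scale work.

Hyperparameters maximise the log marginal likelihood

log p(y) = -1/2 (y-m)^T K^{-1} (y-m) - 1/2 log|K| - n/2 log 2pi,

optimised in log space by L-BFGS-B with the analytic gradient, from five
seeded random starts plus one default start, within l in [1e-2, 1e3] and
sigma in [1e-8, 1]. A fixed jitter of 1e-10 is added to the covariance
diagonal during fitting and caching so the Cholesky factorisation stays
stable when the optimum sits at the sigma floor (the role the `alpha`
parameter plays in scikit-learn's GP regressor). The local likelihood
surface around each optimum is checked to be unimodal in the tests.
Prediction is the posterior mean m + K*^T K^{-1} (y - m).

On the desk-scale study (400 maps, N = 50, 21 x 21 grid, 70/30 split) the
held-out r^2 is at least 0.9 for the energy parameters and at least 0.85
for all six targets, and a two-scale pattern emerges: the three
conformation targets optimise to longer correlation lengths and smaller
noise scales than the three energy parameters — the scattering map
determines the chain's shape more directly than the energies that produced
it. These numbers are recomputed, not quoted, by the test suite and by
`scripts/acceptance.R`.

## Problem sizes

Three bundled profiles fix the study conditions:

| profile | maps | N   | grid    | configs/map | purpose |
|---------|------|-----|---------|-------------|---------|
| smoke   | 20   | 20  | 11 x 11 | 10          | seconds-long contract check |
| desk    | 400  | 50  | 21 x 21 | 2000        | the scaled-down study run by the tests and acceptance script |
| paper   | 1680 | 200 | 51 x 51 | 100         | the full-scale protocol (hours of CPU; rows are independent and trivially parallel) |

The desk profile is the package's chosen desk-scale surrogate of the
full protocol: large enough that all six regressors train stably, small
enough to rerun routinely. The full-scale profile is executed by the same
code path (`runPipeline("paper")`); its shapes (1680 x 2601 matrix) are
verified structurally in the tests without running the full simulation.

## What the generator does and does not emulate

The synthetic data are exact samples of the stated model: discrete bead-rod
chain, hard-sphere self-avoidance, static stretch and shear couplings,
clean ensemble-averaged maps on the training grid. Real RheoSANS data
differ in ways the model deliberately ignores: instrument resolution and
background, absolute intensity scale, charged-monomer interactions,
nonuniform (Hagen-Poiseuille) flow, and detector grids that do not match
the training grid (regridding is out of scope; the grid-signature check
makes the mismatch loud). Passing tests therefore demonstrate correctness
of the forward model and the inversion machinery — not that a regressor
trained on this model transfers to an experimental system whose physics
differs from it.

## Numerical choices and degenerate inputs

* Overlap comparisons use strict `<` with a 1e-12 relative slack;
  bond lengths are validated to 1e-9 relative tolerance.
* Energy evaluation is O(N) per proposal and identical (to 1e-12) between
  the R reference implementation and the C++ sampler path.
* A crankshaft axis through coincident joints cannot occur under the bond
  length invariant; pivot axes are drawn from normalised Gaussians, with a
  deterministic fallback for the measure-zero all-zero draw.
* Constant targets make the GP noise scale run to its floor and predictions
  collapse to the constant; zero reference variance makes `r2Score()` error
  rather than return NaN.
* `makeQGrid()` rejects even point counts (no Q = 0 point), and dataset
  construction refuses intensity rows outside [0, 1] (validity).

## Limitations

Single chains only (no brushes, stars, melts); no torsional stiffness or
charged-monomer (Yukawa) interactions; equilibrium sampling only; inversion
requires the input map on the training Q grid; only posterior means are
reported (no predictive-variance calibration); the desk-scale accuracy
figures are specific
to the desk conditions and improve with the full-scale protocol.
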