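---
title: "Multi-ensemble estimators and their synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-ensemble estimators and their synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mekin)
```

# Scope and model

`mekin` estimates equilibrium thermodynamics and transition kinetics of
rare-event processes from trajectory data collected in several
thermodynamic ensembles at once: one unbiased ensemble plus an arbitrary
number of biased ones (harmonic umbrella windows along a collective
variable, or reweighted well-tempered metadynamics). The motivating use
case is ligand (un)binding from a high-affinity complex, where unbiased
sampling alone never crosses the unbinding barrier reversibly, but the
package is agnostic to what the coordinates mean.

Three layers make up the package:

1. **Synthetic data** — Brownian dynamics on analytic model potentials and
   discrete Markov chains with exactly known biased counterparts. These are
   first-class, tested code: they define the ground truth against which
   every estimator is validated.
2. **Discretization** — inverse-distance and coordination-number features,
   tICA, k-means, and the assembly of the three frame-aligned arrays
   (state index, ensemble index, bias-energy matrix) that the
   multi-ensemble estimator consumes.
3. **Estimators** — TRAM, reversible MSMs with validation diagnostics,
   transition path theory, PMF/standard binding free energy, metadynamics
   post-processing, and ensemble-comparison statistics.

## Units

All internal energies are reduced (kT, `beta = 1`). Inputs quoted in
kcal/mol convert through `kcal_to_kt()`; at 300 K, kT = 0.59616 kcal/mol.
This matters most for umbrella force constants: a "10 kcal/mol" restraint
at 1 CV-unit displacement is 8.39 kT of bias energy, which is why the TRAM
solver works in log space throughout.

# The TRAM estimator

Frames are discretized into states `i` and labelled by ensemble `k`; each
frame also carries the bias energy `b^k(x)` it *would* feel in every
ensemble (zero in the unbiased column, `c_k (x - y_k)^2 / 2kT` for an
umbrella window). Transition counts `c_ij^k` are collected at a lag within
contiguous same-ensemble segments only. The estimator maximizes the
product of the per-ensemble reversible MSM likelihood and the
local-equilibrium likelihood of the frames, which reduces to a coupled
system of self-consistency equations in the local free energies `f_i^k`
and Lagrangian multipliers `v_i^k` (see the README for the equations). At
the solution:

- `p_ij^k` is a reversible transition matrix for every ensemble (detailed
  balance with respect to `exp(-f^k)` holds by construction of the
  estimator, and is asserted to 1e-8 in the tests);
- the per-frame weights `mu(x)` reweight *all* frames — biased and
  unbiased — to the unbiased ensemble, summing to 1;
- with a single ensemble and zero bias, the whole system collapses to the
  reversible MSM maximum-likelihood problem; the test suite asserts
  agreement with the independent MSM fixed-point estimator to 1e-6.

## Numerical choices

- **Initialization**: `f_i^k = -ln(N_i^k / N^k)` from occupation counts;
  `v_i^k` from symmetrized count row sums. Nothing in the validation
  suite was sensitive to these choices beyond iteration counts.
- **Convergence**: `max |df|` below `tol` (default 1e-8 kT), iteration
  budget 1e5. The increment history is returned; a non-decreasing tail
  triggers a warning, never silent acceptance.
- **Log-space accumulation** everywhere: umbrella energies far from a
  window center reach hundreds of kT, so the linear-space equations are
  numerically unusable.
- **Connectivity**: the model is restricted to the largest strongly
  connected component of the count graph *pooled over ensembles*; states
  with frames but no pooled connectivity are dropped and reported. Within
  a single biased ensemble, unvisited states are handled exactly through
  `N_i^k = 0` in the `R_i^k` aggregate.
- **Counting**: sliding-window counting by default (maximal data use),
  strided counting by flag. Biased ensembles contribute transition counts
  by default (the full likelihood); `count_biased = FALSE` restricts them
  to local-equilibrium terms only, since practice varies on this point.
- **States are 0-based** and bins are half-open `[lo, hi)` throughout.

# Markov state models and their diagnostics

`msm()` estimates the reversible maximum-likelihood transition matrix by
the standard self-consistent fixed-point iteration on symmetric flux
variables (tolerance 1e-10 on the stationary vector). Diagnostics follow
the usual workflow: implied timescales `-tau / ln(lambda)`, VAMP-2 scores
(sum of squared slow eigenvalues) for hyperparameter selection, and the
Chapman–Kolmogorov test comparing `P(tau)^g` with a re-estimation at lag
`g*tau`. The test suite includes a deliberately non-Markovian observable
(a hidden-state lumping of a metastable chain) to confirm the C-K test
actually discriminates.

tICA uses the symmetrized lagged-covariance estimator (real eigenvalues,
bounded by 1 up to the 1e-10 ridge on the instantaneous covariance) and no
kinetic-map scaling. Biased and unbiased data are *never* pooled into one
tICA fit: separate fits are concatenated per frame via `combine_tics()`,
so the clustering space carries both the unbiased slow modes and the
biased-ensemble geometry. k-means uses k-means++ seeding, 5 restarts and
deterministic nearest-center assignment with ties to the lowest index.

# Transition path theory

Committors solve the boundary-value linear system by dense direct solve —
exact up to linear algebra, no iteration tolerance; at the state counts
this package targets (tens to thousands) sparse methods are unnecessary.
The rate is the discrete TPT flux expression and the reported MFPT is its
reciprocal `1/k_AB`, the quantity commonly quoted for macrostate
interconversion timescales. Note `1/k_AB` equals the source-to-sink mean
first-passage time only in the metastable regime (probability
concentrated on the source side); the validation fixture is built in that
regime — a 7 kT barrier — where the identity holds to better than 1e-6
against the fundamental-matrix MFPT, and Monte-Carlo first-passage
sampling agrees to a few percent. Kinetics feed from the *unbiased*
ensemble's TRAM transition matrix (`tram_msm(fit, 0)`), the physically
meaningful one; any other ensemble can be selected explicitly.

# Thermodynamic post-processing

`weighted_pmf()` bins TRAM weights on a regular grid (`W = -ln` weight
mass, empty bins `+Inf`, minimum anchored at 0; invariant under weight
rescaling). `standard_binding_dG()` implements the volumetric-correction
route to a standard-state binding free energy: bound bins are those below
1 kcal/mol above the minimum (configurable), the bulk plateau `dW`
references the depth, and `V_o = 1661` cubic Angstrom is the 1 M
standard-state volume. The decomposition `dG = dG_pmf + dG_V` holds
exactly by construction and is asserted, not derived, in tests.

Two deliberately open points are resolved as follows. The bulk region is
a required user input (a mask), because no general rule delimits "bulk"
on an arbitrary grid. The bulk averaging policy defaults to the `n_bins`
*best-sampled* (lowest-W) finite bulk bins: averaging the highest-PMF
bulk bins — a literal reading of common practice descriptions — would
average the worst-sampled bins; that reading remains available as
`policy = "highest"`, and both can be reported.

For well-tempered metadynamics, hills are recorded as (time, center,
width, height); heights decay as `exp(-V_meta/(k_B dT))`, which the toy
generator reproduces and the tests verify as a monotone non-increasing
sequence at any fixed CV value. The free-energy estimate applies the
`(T + dT)/dT` prefactor to the negated final bias. Reweighting uses
final-bias weights `exp(+V_meta(s_t)/kT)`; time-dependent reweighting
(moving-offset estimators) is documented as out of scope — for converged
toy runs the final-bias estimator recovers the Boltzmann density to a
total-variation distance below 0.1.

# Ensemble-comparison statistics

Symmetric K-L divergence is computed per feature on shared pooled-range
histograms with a pseudocount of `1/(n_frames * n_bins)` per bin (50 bins
by default), then aggregated per residue by summing features that involve
the residue. Weighted event probabilities (e.g. the three-way side-chain
contact "triad" indicator, strict `< 5` Angstrom on all three distances)
and contact probabilities are plain weighted frame fractions. Mutual
information between dihedral series uses periodic histograms with
Miller–Madow bias correction, clipped at zero; with 30 bins and 1e5
frames the independence null stays below 0.02 nats while a rho = 0.9
Gaussian pair is recovered within 10% of the closed form. Bootstrap
errors resample whole (unbiased) trajectories without replacement,
keeping 95% per replicate with 3 replicates by default — a deliberately
coarse spread estimate, reported as-is and documented as such.

# The synthetic generator: what it emulates, and what not

The generator reproduces the *statistical structure* the estimators
assume: many short unbiased trajectories with rare barrier crossings,
umbrella-restrained trajectories in known ensembles, detailed-balanced
discrete chains under state biases (square-root reweighting of
off-diagonals, preserving exact analytic stationary laws), and
well-tempered hill deposition. It does **not** emulate inertial dynamics
(overdamped only — the estimators need correct stationary and kinetic
structure, not momentum realism), multidimensional molecular geometry,
force-field detail, or sampling pathologies like hidden slow orthogonal
degrees of freedom. Passing tests therefore demonstrate estimator
correctness on data satisfying the estimators' assumptions; they cannot
certify behaviour on real MD data that violates them.

## Study conditions

The canonical validation system is the symmetric double well
`U(x) = 5 (x^2 - 1)^2` kT (barrier 5 kT): 10 unbiased trajectories of
5e4 Brownian steps plus 21 umbrella windows (`kappa = 20` kT) spanning
[-1.5, 1.5] with 2e4 steps each, discretized into 40 uniform bins on
[-1.6, 1.6], TRAM lag 3 saved frames. The asymmetric variant for the
data-fraction study adds a linear tilt of 3 kT per unit length (a 6 kT
well offset), with 24 unbiased trajectories of 3e4 steps, 11 windows and
30 bins — a size at which the full experiment (full-data fits plus three
subsampled refits of both estimators) completes in minutes on one CPU.
Many short runs are preferred over few long ones here: each independent
start contributes a transient that knits the state network together, so
the full-data reference is reliably connected while a 25% subsample
(6 trajectories) usually is not — which is precisely the regime the
comparison is about.

Two design points of the data-fraction experiment deserve emphasis.
First, its unbiased trajectories are seeded along the transition pathway
(starts spread over [-1.2, 1.2]), emulating the common protocol of
spawning unbiased runs from configurations discovered by biased
sampling. This is not cosmetic: with a 6 kT well offset the
deep-to-shallow direction is ~8 kT uphill and is essentially never
sampled by well-seeded trajectories at desk scale, in which case the
full-data MSM's connected set collapses to the deep well and its
"slowest timescale" measures fast intra-well relaxation — a meaningless
reference for the comparison. Pathway seeding gives the full-data MSM a
connected, physically sensible reference (it agrees with TRAM's to
within tens of percent), and the comparison then probes what it should:
how each estimator's kinetics degrade as unbiased data is removed.
Second, connectivity restrictions differ by estimator on purpose: the
multi-ensemble model's transition matrix couples states wherever the
*symmetrized* count is positive, so its active sets use the undirected
count graph, while the plain MSM keeps the standard directed
strongly-connected-component convention.

The integrator timestep is `dt = 0.002` with `D = 1`, from the standard
Euler–Maruyama accuracy criterion `beta D max(U'') dt <= 0.1` (the
double-well curvature reaches ~40 kT per unit length squared inside the
sampled domain). Coarser steps visibly bias the sampled stationary
density away from Boltzmann, which then shows up as apparent estimator
error; this is an integrator property, not an estimator one. Saving
stride is 20 steps, so the TRAM lag of 3 frames is 0.12 reduced time
units.

## Known limitations

- `1/k_AB` as an MFPT is meaningful in the metastable regime only.
- The three-replicate bootstrap quantifies spread, not a calibrated
  confidence interval.
- Histogram MI underestimates strongly peaked dependencies; the
  Miller–Madow correction removes only the leading bias term.
- The TRAM solver's fixed-point iteration has no global convergence
  guarantee; non-convergence is reported via the `converged` flag and
  increment history rather than hidden.
- Final-bias metadynamics reweighting assumes a converged bias.
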