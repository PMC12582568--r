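# mekin

Multi-ensemble estimation of thermodynamics and kinetics from biased and
unbiased trajectories.

## The problem

Rare-event processes — a high-affinity ligand leaving its receptor, a slow
conformational switch — cannot be characterized from unbiased molecular
dynamics alone: transitions out of deep free-energy minima are essentially
never sampled reversibly. The standard workaround is to mix data from
several thermodynamic ensembles: short unbiased trajectories for kinetics,
plus harmonically restrained umbrella-sampling windows (and possibly
well-tempered metadynamics) that enforce local equilibrium in poorly
sampled regions. `mekin` provides the estimators that turn such a mixed
dataset into free energies, transition rates and ensemble-comparison
statistics, together with a synthetic-data module that generates
ground-truth-known datasets of the same structure so that every stage of
the analysis can be validated against analytic results.

The audience is computational biophysicists and methods developers working
with Markov state models and multi-ensemble reweighting who want a compact,
fully testable R implementation.

## What is implemented

**TRAM (transition-based reweighting analysis method).** Discretized into
states *i* and ensembles *k*, the maximum-likelihood problem combining the
MSM transition likelihood with the local-equilibrium likelihood reduces to
the coupled self-consistency equations for local free energies *f_i^k* and
Lagrangian multipliers *v_i^k*:

```
sum_j (c_ij^k + c_ji^k) / (exp[f_j^k - f_i^k] v_j^k + v_i^k) = 1
R_i^k  = sum_j (c_ij^k + c_ji^k) v_j^k / (v_j^k + exp[f_i^k - f_j^k] v_i^k)
         + N_i^k - sum_j c_ji^k
sum_{x in X_i} exp(f_i^k - b^k(x)) / sum_l R_i^l exp(f_i^l - b^l(x)) = 1
```

whose solution yields per-ensemble reversible transition matrices
`p_ij^k = (c_ij^k + c_ji^k) / (exp[f_j^k - f_i^k] v_j^k + v_i^k)` and
per-frame unbiased stationary weights
`mu(x) = 1 / sum_k R_i(x)^k exp[f_i(x)^k - b^k(x)]`. The solver iterates
these updates in log space (bias energies of tens of kT are routine) until
`max |df| < tol`.

**Around it:** reversible MSM estimation (maximum likelihood with detailed
balance), implied timescales, VAMP-2 scores and the Chapman–Kolmogorov
test; tICA and k-means discretization including the combined
biased/unbiased tIC representation; transition path theory (committors by
direct linear solve, rates `k_AB`, mean first-passage times `1/k_AB`);
weighted PMFs and standard binding free energies with volumetric
correction `dG = -kT ln[ integral_b exp(-beta W) dr / V_o ] - dW`;
well-tempered metadynamics hill bookkeeping, free-energy reconstruction
`dG(S) = -(T+dT)/dT V_meta(S)` and final-bias reweighting; and
ensemble-comparison statistics (symmetric Kullback–Leibler divergence
profiles, weighted contact/event probabilities, trajectory bootstrap,
histogram mutual information with Miller–Madow correction).

**Synthetic data.** Overdamped Langevin dynamics on analytic model
potentials (double well, harmonic, tilted variants), umbrella-window
ladders, well-tempered metadynamics runs, and discrete Markov chains with
exactly detailed-balanced biased counterparts — all with explicit seeds.

## Worked example

Recover the free-energy profile of a 5 kT double well from 10 short
unbiased trajectories plus 21 umbrella windows, then validate against the
analytic reference:

```r
library(mekin)

pot  <- potential_spec("double_well", h = 5)        # U = 5 (x^2 - 1)^2 kT
wins <- make_umbrella_set(seq(-1.5, 1.5, length.out = 21), force_constant = 20)
ds   <- generate_double_well_dataset(pot, wins, n_unbiased = 10,
                                     unbiased_steps = 50000, seed = 42)

edges  <- seq(-1.6, 1.6, length.out = 41)
states <- discretize_cv(ds$trajectories, edges)
data   <- assemble_multi_ensemble(states, ds$ensemble_ids, ds$windows,
                                  ds$trajectories, n_states = 40)

fit <- tram(data, lag = 3)
fit
#> TRAM model: 39 states, 22 ensembles, lag 3 frames; converged after 797 iterations

st  <- stationary_from_tram(fit)
ref <- analytic_reference(pot, edges)
sel <- ref < 8
est <- rep(NA_real_, 40); est[st$states + 1] <- st$free_energy
mean(abs((est - min(est[sel]))[sel] - (ref - min(ref[sel]))[sel]))
#> [1] 0.1035263
```

The fitted object holds the per-ensemble transition matrices and per-frame
stationary weights; the recovered `-ln(pi)` profile deviates from the
analytic binned free energy by about 0.1 kT on average over all bins below
8 kT — umbrella windows supply the thermodynamics across the barrier while
the unbiased trajectories pin the kinetics. Kinetics follow directly:

```r
m0  <- tram_msm(fit)                   # unbiased-ensemble transition matrix
ms  <- macrostate_set(left = 0:14, right = 25:39)
macrostate_mfpt_table(m0, ms, lag_time = 3)
#>        to
#> from       left   right
#>   left       NA 1102.68
#>   right 1133.97      NA
```

(MFPTs in saved-frame units; the two wells of the symmetric potential
exchange on equal timescales, as they must.)

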