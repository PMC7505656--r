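# cadcluster

Quantifying lateral (cis) interactions between membrane-tethered proteins
— the motivating system is the E-cadherin ectodomain on a supported lipid
bilayer — from single-molecule FRET tracking data and from coarse-grained
kinetic Monte Carlo (kMC) simulation of 2D clustering.

Lateral protein–protein interactions on membranes are too weak to measure
in solution, yet they drive cluster assembly at cell–cell junctions.
cadcluster implements a complete analysis chain for the two observables
that *are* accessible in single-molecule experiments:

* **Dissociation kinetics from FRET time series.** Each per-frame
  observation of a donor molecule is classified high-FRET (associated
  with an acceptor-bearing cluster) or low-FRET by a line fitted to the
  donor–acceptor intensity heat map. State sequences are modeled by a
  three-state Markov chain (high / low / off) in which each trajectory
  draws its own transition probabilities from beta distributions —
  heterogeneity across cluster sizes and local environments is part of
  the model, not noise. Marginalizing the per-trajectory probabilities
  gives a closed-form likelihood; the mean dissociation rate constant is

  `k̄_d = (ψ(a_HL + b_HL) − ψ(b_HL)) / Δt`

  with standard errors from the Cramér–Rao bound.
* **State-resolved mobility.** Complementary cumulative squared
  displacement distributions (CCSDD) are fitted by a constrained Gaussian
  mixture `P(R² ≥ r²) = Σ cᵢ exp(−r²/4ΔtDᵢ)`; the mixture mean
  `D̄_short = Σ cᵢ Dᵢ` is the average short-time diffusion coefficient,
  with bootstrap uncertainty.
* **Mobility-based cluster sizes.** Per-trajectory diffusion inverts
  through the Einstein relation and additive (free-draining) friction to
  an apparent cluster size `N = 1/(D_T f_L)` with `f_L = 0.5 s/µm²`;
  size distributions are fitted by `A·exp(−N/N₀)` for the characteristic
  cluster size `N₀`.
* **kMC clustering simulator.** An off-lattice diffusion–reaction
  simulator (compiled core) of rod-shaped molecules on a periodic
  membrane patch, with polarized *specific* bonds (donor site → acceptor
  site, valence 1 + 1, hence linear oligomers) and isotropic
  *nonspecific* bonds, probabilities `rate × Δt` per step.
* **Synthetic-data generator.** Ground-truth-labeled corpora that emulate
  the statistical structure the analysis assumes, so every stage is
  testable at desk scale.

See `vignettes/methods.Rmd` for models, assumptions, parameter defaults
and design decisions.

## Worked example

Simulate a labeled corpus, assign FRET states from the fitted intensity
threshold, and estimate dissociation kinetics and state-resolved
diffusion:

```r
library(cadcluster)

truth <- fret_truth()   # beta shapes (2,50)/(2,25), p_off 0.02,
                        # D_high 0.44, D_low 0.569 um^2/s
data <- simulate_fret_trajectories(truth, n_traj = 1000, dt = 0.05, seed = 1)

thr <- fit_fret_threshold(data)
data <- assign_fret_states(data, thr)

kin <- filter_trajectories(data, "kinetics", dt = 0.05,
                           intensity_percentile = 100)
dwl <- filter_trajectories(data, "dwell", dt = 0.05,
                           intensity_percentile = 100)
p_off <- estimate_poff(dplyr::count(dwl, traj_id)$n)
fit <- fit_beta_markov(count_transitions(kin), p_off = p_off, dt = 0.05)
fit
#> <beta_markov_fit>
#>   p(L->H) ~ Beta(2.185, 57.45); p(H->L) ~ Beta(2.19, 28.75)
#>   p_off = 0.01897, dt = 0.05 s, n_traj = 956, logLik = -13130.1823
#>   r_LH = 0.7528 s^-1; kd_bar = r_HL = 1.493 s^-1

cc <- compute_ccsdd(filter_trajectories(data, "diffusion", dt = 0.05,
                                        intensity_percentile = 100),
                    state = "high", dt = 0.05)
fit_ccsdd(cc, M = 3)
#> <ccsdd_fit> state: high  n: 17492
#>   c1 = 0.0046  D1 = 0.4383 um^2/s
#>   c2 = 0.9954  D2 = 0.4387 um^2/s
#>   dshort = 0.4387 um^2/s (M requested 3, effective 2)
```

The recovered dissociation rate constant (`kd_bar = 1.49 s⁻¹`) matches the
generator's mean rate `(ψ(27) − ψ(25))/0.05 ≈ 1.57 s⁻¹` within its
standard error, and the high-state `D̄_short = 0.439 µm²/s` recovers the
generating 0.44 µm²/s. The intensity cutoff is disabled
(`intensity_percentile = 100`) because the synthetic corpus contains no
bright contaminants — see the vignette.

A mutant-mode clustering simulation (nonspecific interactions only) and
its characteristic cluster size:

```r
cfg <- kmc_config(n_molecules = 100, box_nm = sqrt(100 / 1250) * 1000,
                  dt = 1e-8, on_ns = 2e6, off_ns = 1e4,
                  t_end = 0.06, min_run_time = 0.03, rxn_every = 4)
ens <- kmc_run(cfg, replicas = 2, seed = 1)
st <- kmc_cluster_statistics(ens, window = 0.4, bin_width = 10)
st$fit$N0        # characteristic cluster size, molecules
autoplot(ens)    # mean-cluster-size traces
```

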