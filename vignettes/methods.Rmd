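---
title: "Quantifying lateral membrane-protein interactions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lateral membrane-protein interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadcluster)
```

cadcluster quantifies lateral (cis) interactions between proteins tethered
to a supported lipid bilayer — the motivating system is the E-cadherin
ectodomain — from two complementary directions: analysis of two-channel
single-molecule FRET tracking data, and a coarse-grained kinetic Monte
Carlo (kMC) simulation of 2D clustering. This vignette explains the models,
their assumptions, the tunable parameters, and the design choices made
where the methods left genuine freedom.

## The data model

Analysis functions operate on a *trajectory table*: one row per
(trajectory, frame), with positions in µm, donor and acceptor intensities,
and a per-frame FRET state. The default acquisition interval is
`dt = 0.05` s and the pixel size 0.43 µm. Trajectories are gapless: a
missed frame terminates a trajectory, because bridging gaps would silently
interpolate dwell times and residence times. `link_localizations()`
performs greedy closest-first frame-to-frame linking within a 1.29 µm
(3 pixel) radius; ties break by distance then index.

## FRET-state assignment

Two intensity populations — acceptor-dominant (high FRET, the associated
state) and donor-dominant (low FRET) — are separated by a straight line in
the (donor, acceptor) intensity plane. `fit_fret_threshold()` builds a
2D histogram (default 100×100 bins spanning the 1st–99th intensity
percentiles) and grid-searches the slope and intercept minimizing the
integrated heat-map counts along the line, i.e. the line is driven into
the valley between the populations. Constraints and guards:

* the two population centroids (located by 2-means) must lie on opposite
  sides of the line; candidates violating this are discarded;
* a heat map whose populations are closer than 2 pooled within-cluster
  standard deviations is rejected as unimodal rather than silently
  thresholded;
* the line-integration rule counts a bin whenever the segment crosses it
  (column-wise traversal). Binning and integration are not dictated by the
  method definition, so both are explicit arguments.

State assignment is a deterministic side-of-line test and is idempotent.

Trajectory filters are purpose-specific because different analyses have
different statistical needs: diffusion estimation requires at least 0.71 s
of surface residence; transition-rate estimation admits everything longer
than two frames; dwell-time analyses additionally exclude trajectories
observed in the first or last movie frame (censoring would otherwise
truncate dwells invisibly). Everything longer than 1000 frames is treated
as a surface-bound contaminant. The 60th-percentile median-donor-intensity
cutoff removes bright contaminants and multiply-labeled molecules. On
clean synthetic corpora, which contain no contaminants, that cutoff should
be disabled (`intensity_percentile = 100`): donor quenching ties median
donor intensity to state occupancy, so the cutoff would select
high-FRET-rich trajectories and bias every downstream rate.

## State-resolved short-time diffusion

Consecutive-frame squared displacements, split by the state of the
originating frame, form the complementary cumulative squared displacement
distribution (CCSDD), evaluated at every observed displacement with no
binning. The CCSDD is fit by a Gaussian mixture,

$$P(R^2 \ge r^2) = \sum_{i=1}^{M} c_i \, e^{-r^2 / (4\,\Delta t\, D_i)},
\qquad c_i \ge 0,\ \sum_i c_i = 1,\ D_i > 0,$$

with `M = 3` by default. The unit-sum constraint is enforced exactly
through a softmax parameterization (the model must equal 1 at zero
displacement), positivity through log-parameterized `D`. The average
short-time diffusion coefficient is the mixture mean
$\bar D_\text{short} = \sum_i c_i D_i$; no physical meaning is attached to
the individual components — they are a flexible basis.

Numerical choices:

* multi-start L-BFGS-B (10 starts spread over ±2.5 decades around the
  moment estimate) with analytic gradients;
* an identifiability box on each $D_i$: a component whose decay scale
  exceeds the largest observed displacement acts as a constant offset and
  its $D$ is unbounded upward, which can silently inflate
  $\bar D_\text{short}$; $D_i$ is therefore constrained to
  $[\,r^2_{\min>0}/(400\,\Delta t),\ r^2_{\max}/(4\Delta t)\,]$;
* components with $c_i < 10^{-3}$ are pruned and the model refit, so the
  reported order is the effective one.

Uncertainty comes from bootstrap resampling of displacements (default 100
replicates, warm-started at the full-data fit); up to 20% replicate
failures are tolerated before the bootstrap aborts.

## Beta-Markov dissociation kinetics

Per-frame dynamics are a three-state Markov chain (high, low, off); the
off state absorbs trajectory termination by photobleaching, desorption or
field exit, with a single probability `p_off` per frame shared by both
observable states. Heterogeneity across molecules — cluster sizes, local
environments — is modeled by giving *each trajectory* its own transition
probabilities drawn once from beta distributions,
$p_{LH} \sim \mathrm{Beta}(a_{LH}, b_{LH})$ and
$p_{HL} \sim \mathrm{Beta}(a_{HL}, b_{HL})$. Integrating the
per-trajectory probabilities against their priors gives a closed-form
marginal likelihood in terms of beta functions of the transition counts;
`beta_markov_loglik()` evaluates it entirely in log space, and the unit
tests verify it against direct numerical quadrature.

Estimation is two-stage: `p_off` first, by a geometric maximum-likelihood
fit of the uncensored surface residence times (`1/mean(frames)`; an
exponential-equivalent `1 - exp(-dt/tau)` variant is provided and agrees
to first order), then the four beta shapes by maximum likelihood with
`p_off` fixed. The optimizer works in log-shape space (positivity by
construction), Nelder-Mead refined by BFGS from 8 restarts, convergence
tolerance $10^{-8}$ on the log-likelihood; the covariance is the inverse
observed Fisher information, and rate standard errors are delta-method
propagations — the square root of the Cramér–Rao bound. Boundary solutions
(shapes below $10^{-4}$ or above $10^{6}$) are flagged as degenerate: with
homogeneous data the concentration $a+b$ is only weakly identified, and
the contract is the mean rates, not the shapes.

Mean transition rates use the exact identity
$\mathbb{E}[-\ln(1-p)] = \psi(a+b) - \psi(b)$ for beta-distributed $p$:

$$\bar r = \frac{\psi(a+b) - \psi(b)}{\Delta t},$$

and the mean high-to-low rate is the average dissociation rate constant
$\bar k_d$, dissociation being unimolecular. `rate_density()` gives the
full density of $r = -\ln(1-p)/\Delta t$ by change of variables;
`simulate_beta_markov()` closes the loop by simulating the fitted model
against an empirical residence-time sampler and comparing dwell-time
complementary CDFs with held-out data.

## Mobility-based cluster-size inference

The effective per-trajectory diffusion coefficient is
$D_T = \langle \delta^2 \rangle / (4 \Delta t)$, the mean consecutive-frame
squared displacement over four times the frame interval. (The time
conversion is stated explicitly here because the defining sum is sometimes
written without it; this form makes the Einstein relation
$f/k_BT = 1/D_T$ dimensionally consistent with a lipid friction factor in
s/µm².) In the free-draining limit each protein in a cluster contributes
one lipid friction factor, $f = N f_L$ with $f_L = 0.5$ s/µm² (a lipid
diffusing at 2 µm²/s), so the apparent cluster size is $N = 1/(D_T f_L)$,
real-valued and binned only for distributions. Immobile trajectories
($D_T = 0$) are flagged and excluded from the inversion. Hydrodynamic
(Saffman–Delbrück) corrections are deliberately out of scope.

Cluster-size distributions are normalized histograms (logarithmic bins,
16 per decade, for the continuous experimental-side estimates; linear bins
for the integer-valued simulation sizes). The characteristic size $N_0$
comes from least squares of $A e^{-N/N_0}$ on the (bin center,
probability) pairs after removing the smallest-size bin, which is
monomer-dominated and sensitive to the tracking floor; the fit is exact on
exact exponential input and falls back to the log-linear estimate if the
nonlinear step degenerates. A non-decaying distribution flags $N_0$ as
unreliable rather than failing.

The ensemble-time-averaged MSD uses trajectories longer than six frames,
truncated at six frames, lags restricted so that more than three frames
enter each time average, and fits $\overline{\langle\delta^2\rangle} =
4 D_{TA} \tau$ through the origin. Surface coverage follows
$\theta = (n_D + n_A - n_{D,AC}) / (R_D A_D)$ with the fractional areal
coverage at 9 nm² per ectodomain.

## The synthetic-data generator

`simulate_fret_trajectories()` emulates the statistical structure the
analysis assumes — it is the ground-truth oracle for every pipeline stage.
Defaults are the package's study conditions: beta shapes (2, 50) and
(2, 25) for the low-to-high and high-to-low transition probabilities
(mean dissociation rate ≈ 1.57 s⁻¹ at 50 ms frames), `p_off = 0.02` per
frame, state diffusion coefficients 0.44 (high) and 0.569 (low) µm²/s,
and Gaussian two-channel intensities, acceptor-dominant in the high-FRET
state and donor-dominant in the low-FRET state, separated by ≈6 population
standard deviations. Trajectory lengths are geometric with mean
`1/p_off`, floored at two frames (a trajectory needs a displacement) and
capped at 5000 frames so `p_off = 0` cannot run forever; start/end
censoring flags are set with 2% probability each to exercise the
censoring-exclusion rules. What the generator does *not* emulate — and
what passing tests therefore do not establish about real data —
includes localization noise, blinking and other photophysics beyond
Gaussian intensity spread, gap-bridged trajectories, and bright
contaminants (hence the note above about the intensity cutoff).
`simulate_displacements()` and `simulate_friction_trajectories()` are the
corresponding closed-form oracles for the diffusion and cluster-size
stages.

## The kinetic Monte Carlo simulator

Each molecule is a rigid rod of five collinear 1.5 nm discs in the
membrane plane; its position is the EC1 (N-terminal) domain centre and a
cis-donor and cis-acceptor site sit on opposing sides of the EC1 surface.
Two bond types exist: *specific* (donor site to acceptor site within
1.2 nm and relative orientation within 30°, at most one outgoing and one
incoming bond per molecule — linear oligomers by construction) and
*nonspecific* (EC1 centres within 3.2 nm, unpolarized). Per time step,
every cluster takes a rigid Brownian move (translation variance
$4 D \Delta t$ with $D = 10$ µm²/s, rotation RMS $D_r \Delta t$ with
$D_r = 1$°/ns, about the cluster centroid), each eligible pair forms a
bond with probability $k_{on} \Delta t$ and each bond breaks with
probability $k_{off} \Delta t$; positions wrap periodically. The standard
box is 400 nm with 200 molecules — 1250 molecules/µm² — and the
calibrated rates are $2\times10^5$/$10^3$ s⁻¹ (nonspecific on/off) and
$10^8$/$10^2$ s⁻¹ (specific).

Design choices made where the method definition left freedom, all
measured before being fixed:

* **Bond topology.** Bonds form only *between* distinct clusters —
  association is a binding event between a molecule or cluster and
  another molecule or cluster, after which they "move together" — so a
  cluster's bond graph is a tree and breaking any bond fragments it.
  The alternative (intra-cluster bond formation allowed) was implemented
  and measured: multivalent intra-cluster bonding makes large clusters
  effectively unbreakable at the calibrated rate ratio and the system
  gels into a single spanning cluster, which contradicts the finite
  exponential size distributions the simulation is meant to produce. The
  flag `intercluster_only = FALSE` restores the variant.
* **Excluded volume.** Default is the soft model: overlaps are rejected
  at initial placement but not during diffusion. A hard-disc mode
  (`hard_core = TRUE`, all rod domains) and a flexible-tether annealing
  mode (`internal_moves = TRUE`) are provided; measurements with the
  hard core show the 3.0 nm contact distance leaves only a 0.2 nm
  reactive shell below the 3.2 nm nonspecific cutoff, collapsing the
  system to near-monomeric statistics at the calibrated rates.
* **Cluster mobility.** Clusters move with the monomer coefficient by
  default (the literal "move together" reading); `cluster_d_inverse_n`
  applies the additive-friction $D/N$ scaling used on the experimental
  side, for sensitivity studies.
* **Time step and reduced scale.** The reference step is 0.01 ns; at
  that scale a second of simulated time needs $10^{11}$ steps, so desk
  runs enlarge the step to 10 ns. All probabilities remain valid
  ($k_{on}^{sp} \Delta t = 1$ exactly at the specific on-rate) and every
  on/off ratio is unchanged; equilibrium cluster statistics depend on
  the ratios rather than the absolute rates, which is also the
  justification for running the mutant calibration at the
  ratio-preserving pair $2\times10^6$/$10^4$ s⁻¹. A reaction
  sub-sampling interval (`rxn_every`) evaluates reactions every few
  steps at proportionally scaled probabilities. One caveat is
  documented honestly: at enlarged steps a freshly broken bond is more
  likely to re-form before the partners diffuse apart, and for the
  specific interaction (ratio $10^6$) no desk-scale setting yields real
  bond turnover — the specific network is effectively irreversible, so
  wild-type runs condense toward a spanning cluster instead of the
  calibrated characteristic size near 34. The corresponding acceptance
  checks are left failing rather than re-tuned; the mutant-side
  characteristic size lands at the right order (tens of molecules) with
  realization-to-realization spread.
* **Analysis protocol.** Cluster sizes are pooled over the final 40% of
  recorded samples across replicas; simulation distributions use linear
  bins of width 10 (the granularity of typical published cluster-size
  plots) and the exponential fit drops the smallest-size bin.
* **Determinism.** The compiled core draws from an internal
  xoshiro256++ generator seeded from R's RNG stream, so `set.seed()`
  fully determines a run while the per-event draws stay cheap.

Problem sizes in the test-suite and acceptance protocols (100 molecules
on a 283 nm box, runs of 0.02–0.06 s at 10 ns steps, 2 replicas) were
chosen as the smallest systems whose traces visibly plateau and whose
pooled cluster counts support an exponential fit.

## Known limitations

* Absolute short-time diffusion values inherit the caveat that unfiltered
  immobile objects depress them; relative comparisons between states and
  conditions are the robust quantity.
* The threshold line is fit pooled across a condition by default; per-
  movie fitting is possible by calling `fit_fret_threshold()` per subset.
* The beta-Markov model assumes state assignments are exact;
  misassignment near the threshold inflates both transition rates, and no
  hidden-Markov smoothing is attempted.
* The kMC model resolves neither trans-interactions, membrane
  deformation, nor the conversion of 2D on/off rates into 3D effective
  rate constants.
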