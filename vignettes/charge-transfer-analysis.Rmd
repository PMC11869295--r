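---
title: "Free-energy pathways and charge-transfer kinetics of a minimal superoxide oxidoreductase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy pathways and charge-transfer kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stringpcet)
```

## What this package models

Superoxide oxidase (SOO) is a minimal membrane oxidoreductase that oxidizes
superoxide on the periplasmic side and delivers the electrons across two
heme *b* cofactors to reduce a quinone to quinol on the cytoplasmic side.
The computational analysis of its mechanism combines four layers, and
`stringpcet` implements all of them at desk scale:

1. **A finite-temperature string method** that locates minimum free-energy
   pathways of the proton-coupled electron transfer (PCET) forming the
   quinol, on a two-dimensional landscape spanned by two proton-transfer
   reaction coordinates (RC1, RC2, in Angstrom).
2. **Free-energy reconstruction** of the 2D landscape from harmonically
   restrained (umbrella) sampling, by three independent estimators: 2D WHAM,
   MBAR and a variational maximum-likelihood profile.
3. **Closed-form rate physics**: the empirical electron-tunneling distance
   ruler, transition-state-theory (TST) barrier/rate conversion with the
   kBT/h = 6 ps^-1 prefactor, and Nernst concentration corrections of redox
   potentials.
4. **A chemical master equation** of the complete two-electron
   superoxide-to-quinol cycle, whose turnover is read off the quinol
   half-time as k = ln 2 / t-half.

Because first-principles energetics of the real enzyme require QM/MM
electronic-structure machinery that is out of scope here, the sampling
layers operate on *surrogate analytic surfaces* with known topography.
Every statistical estimate in the package can therefore be checked against
an exact geometric ground truth.

## The surrogate landscape

`make_surface("pcet-double-well")` builds a PCET-like double well: a
reactant minimum near (-0.8, -0.8) and a product minimum near (+0.8, +0.8),
connected through two metastable "stepwise" channels running through the
off-diagonal corners (one proton transferred first, then the other), while
the concerted diagonal is ridged off. Three quantities are planted by a
deterministic calibration at construction:

* the minimum-energy-path barrier of the lower channel (default 12
  kcal/mol, the barrier of the kinetically preferred stepwise pathway),
* the barrier of the alternative channel (default 15 kcal/mol, the
  slower stepwise/concerted alternatives being 3-4 kcal/mol higher),
* the reaction free energy (default +7.5 kcal/mol, the local endergonicity
  of the quinol-forming step that is paid back by the upstream
  electron-transfer driving force).

The calibration runs a secant loop on the amplitudes of the shaping
Gaussian components against grid searches (a 1D saddle search plus a
minimax flood-fill for each channel) and stops when all three targets are
met to 0.02 kcal/mol. The functional family is a separable quartic double
well plus generalized Gaussian components and an optional harmonic
confinement; the quartic base was adopted because a pure Gaussian mixture
could not realize two transversely stable channels with *exactly two*
minima -- lifting the corner basins of the quartic topology with
anisotropic corner bumps does, as `find_stationary_points()` verifies.

```{r surface}
s <- make_surface("pcet-double-well")
s$stationary$barrier       # planted, recovered by the grid oracle
grid_barrier(s, c(-0.8, -0.8), c(0.8, 0.8), n_grid = 161)$barrier
```

The `"mueller-brown"` preset provides the standard rugged benchmark (three
minima, two saddles) and `"harmonic-well"` gives closed-form moments for
validating the sampler and the estimators.

## Restrained sampling

`sample_window()` draws from the biased Boltzmann density
exp(-(U + bias)/kBT) at T = 310 K (kBT = 0.6160 kcal/mol, one constant
shared across all modules). The dynamics are overdamped Langevin
(Euler-Maruyama proposals) with a Metropolis acceptance step. The
acceptance correction is the package's own design choice: a plain
Euler-Maruyama chain has a stationary-density bias of order k*dt (about
10% in variance at k = 200 kcal/mol/A^2 and dt = 1e-3), which would
contaminate every downstream free-energy estimate; with the correction the
stationary density is exact at any stable step size, while the dynamics
remain overdamped Langevin. Step sizes that overflow are halved
deterministically and retried, so a run is reproducible from its seed
alone. Seeds are explicit everywhere; no global random state is consumed.

Harmonic restraints of 50-200 kcal/mol/A^2 mimic restrained QM/MM windows;
100-200 samples per string iteration and a few thousand samples per
free-energy window mimic the sub-picosecond windows of the original
protocol.

## The string method

A string is an ordered set of nodes (12 for concerted-style, 19 for
stepwise-style paths) with pinned endpoints. Each iteration:

1. estimates the *drift* at every node -- the biased sample mean under a
   restraint centered at the node, minus the node (or its noiseless
   quadrature counterpart with `method = "quadrature"`),
2. refits a smooth curve through the displaced nodes -- each coordinate
   against normalized arclength, either a fourth-order polynomial or a
   natural cubic interpolating spline (the default, which has the smaller
   fitting error on strongly curved stepwise paths),
3. redistributes the nodes to equal arclength by bisection on the
   cumulative arclength (relative tolerance 1e-6, leftmost root).

Convergence follows the sum-of-squares / maximum-deviation rule: both the
total squared node displacement and the maximum per-node squared
displacement between consecutive iterations must stay below 0.008 and 0.05
Angstrom^2 for at least three consecutive iterations. The maximum
deviation is implemented as a squared displacement (units as the
thresholds are stated); endpoints are pinned by default because the
reactant and product basins are known, with a free-endpoint mode available.

Two practical notes. First, strings are initialized per channel (through a
`via` point near the relevant corner), mirroring how distinct candidate
mechanisms are probed by separate initial pathways; a string started on
the symmetric diagonal drifts only slowly off the ridge and the
convergence rule would stop it early. Second, on steep benchmark surfaces
(Mueller-Brown) the restraint must out-curve the saddle's negative mode;
k = 800 in the surface's units with dt = 1e-4 converges reliably, and the
50-200 range triggers a warning rather than an error for exactly this
reason.

## Free-energy reconstruction

`wham2d()` iterates the standard self-consistent histogram equations on a
50 x 50 grid covering the sampled range padded by 5% (bins with fewer than
10 samples are flagged unoccupied and reported as NA, never silently
zero); iteration stops when window free energies move less than 1e-7
kcal/mol. `mbar_fes()` solves the MBAR equations on per-sample bias
energies by damped Newton iteration with a gauge fix, then bins the
unbiased weights. `variational_profile()` maximizes the biased-sample
likelihood over a coarse bilinear knot basis (L-BFGS-B with analytic
gradients) and reports each bin as the Boltzmann average of the fitted
profile over a 3x3 sub-grid -- the same quantity a histogram estimator
measures, which makes bin-wise comparisons between the histogram and basis
estimators meaningful. All landscapes are referenced so the lowest
occupied bin is zero.

Windows for a landscape are placed along the converged string (41 windows
by default in the pipeline; window spacing should stay within about two
thermal standard deviations sqrt(kBT/k) or the window free energies
random-walk), or on the classic 13 x 13 grid of 169 windows via
`make_umbrella_grid()`. `path_barrier()` interpolates the landscape
bilinearly along the densified path; basins are the lowest occupied bins
within 0.3 Angstrom of the endpoints. `fes_bootstrap()` and
`block_uncertainty()` provide moving-block bootstrap uncertainties (blocks
of a twentieth of a window by default, long enough to span the chain
autocorrelation at the default step sizes).

Estimator concordance is assessed on well-sampled bins (at least 30
samples) because the agreement bound of 0.5 kcal/mol is otherwise
dominated by pure shot noise of barely occupied bins (kBT/sqrt(10) is
already 0.19 kcal/mol). On the Mueller-Brown benchmark the concordance
analysis uses a well-sampled stretch of the converged string rather than
the full path: the surface is so stiff relative to kBT = 0.616 kcal/mol
that sampling tubes are a few hundredths wide and windows along the full
path sit several thermal standard deviations apart — no reweighting
estimator converges across such gaps, which is a property of the
benchmark at this temperature, not of any particular estimator.

## Rates, thermodynamics and the kinetic model

`moser_dutton_rate()` implements the empirical tunneling ruler
log10 k = 13 - (1.2 - 0.8 rho)(R - 3.6) - 3.1 (dG + lambda)^2 / lambda,
with the standard protein parameters lambda = 0.7 eV and rho = 0.76; the
same quadratic form is applied on the endergonic branch. Its calibration
surface is the printed rate set of the enzyme: ~800 /s at the 17-Angstrom
distal superoxide site, ~1e7 /s at the 9-Angstrom proximal site, and a
~100 ns interheme timescale at 11 Angstrom with -0.108 eV driving force.

`nernst_shift()` computes E = Em - 59 mV x log10([red]/[ox]), the sign
chosen so that depleting the reduced species *raises* the effective
potential: with [superoxide] = 1e-10 M against [O2] = 1e-6 M the -160 mV
couple shifts to about +80 mV. The 59 mV/decade slope is used verbatim
(the exact 310 K value would be 61.5 mV/decade; the slope is an argument).
`driving_force()` converts potential differences with F = 23.061
kcal/mol/V, and `tst_rate()`/`tst_barrier()` convert between barriers and
rates with the 6 ps^-1 prefactor (exact inverses).

`build_soo_network()` enumerates (heme 2 ox/red) x (heme 1 ox/red) x
(Q, semiquinone, quinol) -- 12 states -- and wires: superoxide delivery
(pseudo-first-order, default 1e8 /s, in series with the proximal tunneling
step; this delivery rate is the model's main free knob), reversible
interheme transfer, reversible first reduction of Q, and the final
irreversible PCET (quinol unbinding makes it one-way). Reverse rates come
from detailed balance, k_fwd/k_rev = exp(-dG/kBT). `integrate_network()`
solves the master equation with a stiff integrator on 1e4 log-spaced
output points, conserving probability to 1e-8, and `turnover()`
interpolates the quinol half-time linearly. Because the delivery rate is
not pinned by any printed value, the predicted overall turnover (~2e4 /s
from a 12 kcal/mol barrier) is an order-of-magnitude statement, to be read
against a reported overall rate of roughly 1e4 /s, not a bit-exact target.

```{r kinetics}
rt <- soo_rate_table()
net <- build_soo_network(rt, tst_rate(12))
tv <- turnover(integrate_network(net, 1e-2))
tv
```

## Ensemble statistics

The trajectory layer reproduces the distributional observables of the
membrane simulations: `axial_density()` (membrane partitioning, with a
core/bulk ratio), `radial_distribution()` (shell-normalized g(r) about a
reference atom such as a heme edge atom), `site_occupancy()` (both
frame-fraction and species-fraction conventions are reported, since
"binding probability" can mean either), `com_distance_series()` (bound/
unbound segmentation of a center-of-mass distance) and
`potential_shift_profile()` (the Nernst correction applied bin-wise along
the membrane normal). Orthorhombic minimum-image boundaries only.

The seeded generators in `make_partition_trajectory()`,
`make_shell_trajectory()`, `make_dwell_trajectory()`,
`make_telegraph_trajectory()` and `make_uniform_gas()` plant exact ground
truths (a 12:1 core enrichment, a 40% site dwell, a 9-Angstrom shell, exact
switch points). They emulate *distributions*, not dynamics: there is no
diffusion, no correlation between frames, and no force field, so passing
these tests validates the estimators, not any claim about real membranes.

## Problem sizes and reproducibility

The shipped analyses use 19-node strings with 200 samples per node per
iteration, 41 free-energy windows of 5000 samples, 50 x 50 bins, 24
block-bootstrap replicates, and a 301-point-per-axis grid for the
geometric oracle; `run_pipeline()` defaults are of the same order. These
sizes give barrier estimates with bootstrap standard errors near 0.1
kcal/mol on the surrogate surfaces. Every stage takes an explicit seed;
`run_pipeline()` derives per-stage seeds by a fixed affine rule and writes
a manifest with MD5 checksums, so identical configuration plus seed
reproduce identical outputs. No command-line wrapper is shipped: this is
an R analysis package, and the exported functions plus `run_pipeline()`
are its interface.

## Known limitations

* Surrogate surfaces stand in for QM/MM energetics; the planted 12/15
  kcal/mol barriers are modeling inputs, not predictions.
* The sampler targets the stationary biased density; time correlations are
  handled only through block bootstrapping, not through statistical-
  inefficiency estimation.
* WHAM evaluates window biases at bin centers, which softens steep
  transverse walls on coarse grids; MBAR and the variational profile do
  not share this approximation, and the three agreeing within 0.5 kcal/mol
  is itself one of the package's checks.
* The kinetic model is deterministic (no stochastic simulation) and its
  superoxide delivery rate is a free parameter.
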