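---
title: "Methods: event-driven DMD, replica exchange and free-energy landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-driven DMD, replica exchange and free-energy landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dmdrex)
```

# The model and the procedure

`dmdrex` implements the computational protocol used to map the thermal
unfolding of a helix-bundle protein: event-driven discrete molecular
dynamics (DMD) over multistep square-well potentials, replica-exchange
(REX) sampling across a temperature ladder, WHAM reconstruction of the
density of states and heat-capacity curve, potential-of-mean-force (PMF)
surfaces over the (RMSD, Rg) reaction coordinates, and leader-algorithm
clustering of the low-free-energy basins. The full-scale application of
this protocol (a united-atom apolipoprotein E model, 24 replicas,
6x10^6 steps) costs tens of thousands of CPU hours; the package instead
ships a synthetic coarse-grained four-helix bundle that reproduces the
protocol's qualitative physics at desk scale, so every stage can be
exercised and tested in minutes.

## Units

Lengths are in Angstrom, energies in kcal/mol, masses in Da, and
temperature in kcal/(mol kB) ("reduced"); the Kelvin view divides by
kB = 0.002 kcal/mol/K, so the ladder 0.35-0.81 spans 175-405 K. With this
unit system the intrinsic time unit is sqrt(Da A^2 / (kcal/mol)) = 48.9 fs,
which is why one DMD step corresponds to ~50 fs and 2x10^4 steps to ~1 ns;
`convert_time()` and `convert_temperature()` encode both mappings exactly.

## Event-driven dynamics

All interactions are piecewise-constant pair potentials
(`step_potential()`): beads fly ballistically between events, and an event
is the root of `|r + v t|^2 = d^2` at the boundary distances adjacent to a
pair's current shell. Collisions decompose the relative velocity along the
line of centres; the tangential part is untouched (angular momentum
conservation) and the radial part either crosses the step (when
`mu v_r^2 / 2` exceeds the energy step, with sign-preserving speed
`sqrt(v_r^2 - 2 dU / mu)`) or reflects. Hard cores and the two walls of
the covalent-bond well always reflect. Temperature is imposed by an
Andersen thermostat: Poisson-scheduled full-velocity redraws of single
beads from the Maxwell-Boltzmann distribution, default 0.1 kicks per bead
per time unit. With the thermostat off, total energy, momentum and angular
momentum are conserved to floating-point accuracy (the suite verifies
<= 1e-9 kcal/mol per event).

The production engine (C++) schedules events on a binary heap with lazy
invalidation via per-bead collision counters. Pairs are predicted only up
to a rolling horizon (default 5 t.u.); a periodic *resync* event
re-predicts every pair, so no event can be missed while far pairs stay off
the heap. A conservative distance bound (relative speed times
time-to-horizon) additionally skips the quadratic for pairs that cannot
reach a boundary before the next resync. These devices change only
*when* predictions are computed, never which events occur; because DMD is
chaotic, recomputing an event time from a different floating-point base
can still reorder near-simultaneous events, so individual trajectories are
bit-reproducible only at fixed settings and seed. The suite pins the
physics down with a naive reference engine (`dmd_run_reference()`), an
O(n^2)-per-event loop that must produce the identical event sequence over
short horizons. Simultaneous events are ordered by (time, bead, pair
index); grazing contacts (discriminant below 1e-12) are treated as no
crossing.

## The synthetic bundle

`topology_mini_bundle()` defines 56 beads: four 10-bead helices, a 6-bead
hinge and a 10-bead flexible tail, a scaled-down analogue of the
apolipoprotein E segment layout (whose full 299-residue preset,
`topology_apoe()`, is retained). Helices use canonical C-alpha geometry
(1.5 A rise, 100 degree turn, 2.3 A radius, right-handed in chain order)
and are packed antiparallel on a 10 A square; hinge and tail extend away
from the bundle. The force field is Go-like: consecutive beads sit in an
infinitely deep well at 3.8 A +/- 2%; pairs within 7.5 A in the built
geometry at sequence separation >= 3 get a single attractive square well
(depth 1 kcal/mol) centred on their reference distance; everything else is
a 4 A hard core.

Two choices here are the package's own, made after the naive variant
failed to behave like a helix bundle:

* **Intra-helix (i, i+2) restraint wells.** A distance-only chain has no
  angular stiffness at all, so helices unravel even at the bottom of the
  ladder. Pairs (i, i+2) inside one helix therefore carry the same kind of
  attractive well as a native contact -- the standard DMD surrogate for
  backbone angle rigidity. They are counted as native contacts.
* **Well width 1.0 A.** With 1.5 A wells the interior virtual dihedrals
  fluctuate so widely that helicity plateaus near 80%; 1.0 A keeps the
  cold bundle >= 95% helical while leaving the folding transition inside
  the ladder.

The three helix-helix junctions cannot satisfy a 3.8 A bond (the closest
approach of neighbouring helix surfaces is ~5.4 A), so junction bonds get
a flat-bottomed tether well reaching from the bond floor to the built
junction distance. The tail has no attractive contacts beyond its
anchoring to H4 and stays disordered -- mirroring the flexible C-terminal
domain that the reaction coordinates deliberately exclude
(`helix_beads()` is the default selection everywhere).

With these defaults the bundle has 103 native contacts and idealized
energy -103 kcal/mol, and its heat-capacity peak falls near 0.38-0.40
reduced (~190-200 K), inside the replica ladder.

## Replica exchange

24 replicas on the inclusive grid 0.35 to 0.81 by 0.02 run independently
between swap barriers (default every 10^3 t.u.; the full-scale protocol
leaves the interval unspecified). At each barrier, adjacent temperature
pairs -- alternating even and odd sweeps -- attempt a Metropolis swap with
probability `min(1, exp((beta_i - beta_j)(E_i - E_j)))`. Bookkeeping
exchanges *temperatures* rather than configurations, rescaling velocities
by `sqrt(T_new / T_old)`; this is equivalent to the configuration-swap
view and cheaper. Frames and energy series are collected per temperature,
which is what WHAM and the landscape stages consume. `run_rex()` accepts a
custom propagator, so the swap machinery is tested against systems with
closed-form Boltzmann statistics (a slow two-level sampler must recover
exact occupancies through swaps alone). `replica_mobility()` counts the
distinct ladder temperatures each replica visits.

## WHAM, heat capacity and diagnostics

Energy series are histogrammed on a shared grid with 1 kcal/mol bins
(the width used for every energy histogram in the protocol), after
discarding the leading 1/12 of each series as equilibration -- the scaled
analogue of dropping the first 5x10^5 of 6x10^6 steps. The density of
states solves

    Omega(E) = sum_k n_k(E) / sum_k N_k exp(f_k - beta_k E)
    f_k = -log sum_E Omega(E) exp(-beta_k E) dE

by direct substitution in log space to a 1e-7 tolerance on the free
energies, with Omega normalised so its maximum bin is 1. Disconnected
histogram islands produce a diagnostic warning (the inter-island constant
is undetermined). `heat_capacity()` evaluates
`Cv(T) = (<E^2> - <E>^2) / (kB T^2)` (units of kB) and detects peaks and
local minima after a 3-point moving-average smooth on a 1 K grid. The
uncertainty band is a block bootstrap (20 contiguous blocks, 50
replicates) -- the full-scale protocol's "variance of the specific heat"
estimator is unspecified, so the bootstrap is stated as this package's
choice. `convergence_windows()` recomputes Cv on trailing windows and
reports first-peak drift; `energy_normality()` applies a moment-based
omnibus (Jarque-Bera form) at the 1% level, since near-Gaussian energy
marginals at every temperature are what justify the canonical treatment.

`heat_capacity()` defaults to the 0.4-0.8 analysis window of the
full-scale protocol. The *pipeline* default is the ladder interior
0.36-0.80 instead: the toy bundle's folding peak sits just below 0.4, and
WHAM cannot be trusted beyond the sampled temperature range in either
direction.

## Landscapes and state labels

RMSD uses closed-form least-squares superposition (Kabsch) with proper
rotations enforced; the reference is the run's starting structure. Rg is
mass-weighted (uniform masses here, so geometric). The PMF is
`-kB T log W` over 1 A x 1 A bins of (RMSD, Rg), shifted so the occupied
minimum is zero; empty bins are NA, never zero, and the partition-function
constant is absorbed into the shift. Basins are 4-connected components of
bins within a depth cutoff (default 1 kcal/mol) around the global minimum.
State temperatures follow the Cv extrema: T1 is the lowest analysis
temperature, T2 the minimum below the first peak, T3 the minimum between
the first two peaks, T4 the final minimum; a single-transition system has
no minima, in which case the pipeline adds the top analysis temperature
("Thigh") so the unfolded ensemble still gets a landscape.

## Conformer analytics

Leader clustering is a single pass in frame order (first leader within the
cutoff wins); the cutoff is the modal 1 A bin centre of the all-pairs RMSD
distribution, ties taking the lower bin. A cluster's centroid is its
member with minimal summed RMSD to co-members -- the protocol says
"centroid" without defining it. Distance-map objects store the ensemble
mean above the diagonal and the *population* standard deviation below.
Only the C-alpha distance mode is computable on a bead model; the
side-chain-centroid mode named by some full-scale figure captions is
exposed as an explicit unsupported-mode error. The secondary-structure
surrogate classifies residue i from the virtual dihedral of beads
(i-1..i+2): helix for 30-70 degrees with canonical flanking virtual
angles (75-105 degrees), extended for |tau| >= 150, loop otherwise --
documented as a CG stand-in, not an all-atom hydrogen-bond assignment.
SASA is Shrake-Rupley-style with a 960-point Fibonacci sphere per bead
(probe 1.4 A, bead radius 2 A = half the hard core); points exactly on a
neighbour's surface are assigned to the lower bead index so coincident
spheres count their shared surface once. The inter-domain angle theta uses
three anchor beads and the dihedral phi four (standard signed convention:
0 degrees is an anti-parallel domain arrangement, +/-180 parallel), with
N-to-C directionality.

# What the generator does and does not emulate

The synthetic modules provide three kinds of ground truth: the bundle
geometry (known contacts, known idealized energy), per-temperature energy
series drawn *exactly* from two-level / harmonic Boltzmann distributions
(so WHAM faces data whose density of states is known in closed form), and
(RMSD, Rg) samples from Gaussian mixtures (so the PMF machinery faces
basins with analytic depth differences, `-kB T log` of the weight ratio).
Passing tests therefore demonstrate that the *machinery* is exact or
statistically calibrated. They do not show that a 56-bead Go model
reproduces any quantitative property of a real 299-residue protein: there
is no solvation model, no electrostatics, no side chains, no sequence
specificity, and the tail's flexibility is by construction. Full-scale
isoform-specific numbers (peak temperatures of specific variants, salt
bridge occupancies) are out of reach at this scale and are not claimed.

# Problem sizes and seeds

The test suite runs the complete protocol at the sizes the package is
designed for: 24 replicas x 2x10^5 t.u. for the integration run (a ~10 ns
equivalent per replica), 10^4-t.u. conservation checks, and 10^4-sample
statistical tests at 3-standard-error tolerances (blocked standard errors
where samplers are autocorrelated). All randomness flows through explicit
seeds: the engine has its own deterministic RNG stream (xoshiro256++ with
Box-Muller normals), and every R-level stage seeds R's RNG, so a
configuration reruns bit-identically.

# Known limitations

* The thermostat rate and swap interval are package defaults; the
  full-scale protocol does not state them.
* Event ordering is deterministic but chaotic: changing the scheduling
  horizon (or any floating-point detail) legitimately yields a different
  member of the same statistical ensemble.
* WHAM here is one-dimensional in energy (no 2-D WHAM, no MBAR), and the
  uncertainty band is a bootstrap, not an analytic estimator.
* The helicity assignment and SASA are coarse-grained surrogates and
  should not be compared numerically against all-atom DSSP or atomic-radii
  SASA values.
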