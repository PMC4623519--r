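# dmdrex

Event-driven discrete molecular dynamics (DMD) with replica exchange and
the free-energy analyses used to map protein thermal unfolding — in R,
with the event loop in C++.

## What problem this solves, and for whom

Characterising how a helix-bundle protein melts — where its heat-capacity
peaks sit, which metastable intermediates it visits, what those
conformers look like — requires a specific computational protocol:
sample the molecule across a ladder of temperatures with replica-exchange
DMD, combine the energy histograms with WHAM into one density of states,
locate transitions on the heat-capacity curve, project the ensembles onto
(RMSD, Rg) free-energy surfaces, and cluster the low-energy basins into
representative structures. `dmdrex` implements that whole chain as a
tested, reusable package for method developers and students of protein
thermodynamics, exercised end-to-end on a synthetic coarse-grained
four-helix bundle (a scaled-down apolipoprotein E analogue) that runs in
minutes on one CPU.

## The method in brief

* **DMD engine.** Pair interactions are multistep square wells
  (thresholds d1 < … < dK, constant energies between). Beads fly
  ballistically between events; at a boundary the radial relative
  velocity either crosses (`v_r' = ±sqrt(v_r² − 2ΔU/μ)` when
  `μ v_r²/2 > ΔU`) or reflects, conserving energy, momentum and angular
  momentum exactly. An Andersen thermostat redraws single-bead velocities
  from the Maxwell–Boltzmann distribution at Poisson times.
* **Replica exchange.** Replicas at temperatures 0.35–0.81 kcal/(mol·kB)
  (175–405 K, increments of 0.02) periodically attempt Metropolis
  temperature swaps, `P = min(1, exp[(βi − βj)(Ei − Ej)])`.
* **WHAM.** The density of states Ω(E) solves
  `Ω(E) = Σk nk(E) / Σk Nk exp(fk − βk E)` self-consistently with
  `fk = −log ΣE Ω(E) e^{−βk E} ΔE`; heat capacity follows as
  `Cv(T) = (⟨E²⟩ − ⟨E⟩²)/(kB T²)` with block-bootstrap uncertainty.
* **Landscapes.** `PMF(RMSD, Rg) = −kB T log W(RMSD, Rg) + C`, with C
  shifting the occupied minimum to zero; basins are connected bin
  components around the minimum, clustered by the single-pass leader
  algorithm at the modal pairwise-RMSD cutoff.

## Worked example

```r
library(dmdrex)

built  <- build_mini_bundle(topology_mini_bundle(), go_parameters())
built$model
#> <dmd_model> 56 beads, 55 bonds, 103 native contacts
potential_energy(built$model, built$state$positions)
#> [1] -103        # kcal/mol: -(well depth) x (native contacts)

ladder <- build_ladder(0.35, 0.81, 0.02)
ladder
#> <temperature_ladder> 24 temperatures, 0.35-0.81 (175-405 K)

ens <- run_rex(built$model, built$state, ladder, n_timesteps = 2e4, seed = 7)
ens
#> <replica_ensemble> 24 replicas, 20000 t.u., 230 swap attempts (80% accepted)
replica_mobility(ens)$mean
#> [1] 9.125       # distinct temperatures visited per replica

fit <- wham_solve(energy_histograms(ensemble_energy_series(ens)))
cv  <- heat_capacity(fit, seq(0.36, 0.80, by = 0.002))
cv
#> <cv_curve> 221 temperatures; peaks at 235 K
```

The model print-out shows the Gō parameterisation (every native contact
of the idealized bundle is one attractive well, so the starting structure
sits at −103 kcal/mol). The REX summary reports the swap statistics; a
healthy ladder accepts a large fraction of swaps and each replica visits
many temperatures. The Cv curve's peak marks the bundle's folding
transition — this short 20 000-step demonstration places it near 235 K;
the production-length run in `scripts/acceptance.R` (2×10⁵ steps)
resolves it near 200 K, inside the ladder, with a native-like cold basin
(centroid RMSD to the start ≈ 1.3 Å) and an expanded unfolded basin
(Rg ≈ 14 Å vs ≈ 8 Å when folded).

The one-call version of the full workflow, writing a report directory
(Cv TSV, PMF surfaces, cluster tables, centroid PDBs, manifest):

```r
report <- run_pipeline(run_config(seed = 1), output_dir = "report")
```

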