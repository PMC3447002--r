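# paracortex

An agent-based simulator of T cell motility, chemotaxis and trafficking
in the lymph node paracortex (the T cell zone), for researchers studying
lymphocyte recirculation, residence times and chemotactic egress.

T cells in the paracortex are densely packed and highly motile: they
perform a persistent random walk (mean speed ~8–16 µm/min), enter from
blood via high endothelial venules, and leave through discrete exit
portals into the lymphatic sinuses, with a mean transit (residence) time
of 12–24 h. During an immune response, inflammation drives a several-fold
increase in influx and the T cell population expands and contracts
accordingly. `paracortex` models all of this on a cubic lattice:

* **Packed blob.** The T zone is a sphere of lattice sites (grid spacing
  6.3 µm from 60% volume occupancy) where available sites always equal
  cells; two cells may share a site for a single 15 s step, which lets
  cells pass each other without unphysical pile-ups.
* **Motility.** A persistent random walk with per-step jump probabilities
  `p(i) ∝ exp(κ cos φᵢ)/|uᵢ|` over the 26 Moore directions, plus a stay
  probability `p₀`.
* **Chemotaxis.** An attraction vector **C** mixes a chemotaxis-only jump
  distribution `p_c(i) ∝ cos²θᵢ/|uᵢ|` (counter-directed jumps zeroed)
  into the walk with weight `α = min(1, |C|)`:
  `p*(i) = (1−α) p(i) + α p_c(i)`. Exit portals attract with the bounded
  inverse-square law `g(r) = min(1, K_E/r²)`; multiple influences add as
  vectors.
* **Trafficking.** Cells enter within 0.7 R of the centre at Poisson rate
  `F_in`; any cell in the 27-site Moore neighbourhood of a portal leaves
  with probability `P_E = 0.02` per step. The portal count follows the
  calibrated power law `N_E · T_res = a N^b` (≈ linear in N), scaled by
  `0.02/P_E` and by the chemotactic reduction factor `β(K_E)` (floor 0.5
  when portal neighbourhoods saturate at double occupancy).
* **Inflammation.** An external signal drives growth-factor production,
  which raises relative vascularity V through a Hill function, which
  scales influx (`F_in = V·N₀/T_res`) — reproducing lymph node expansion
  and recovery.

## A worked example

Steady-state trafficking in a 10,000-cell blob configured for a 12 h
residence time:

```r
library(paracortex)
set.seed(99)
sim <- run_simulation(simulation_config(N0 = 10000, duration_days = 6))
sim
#> <paracortex_sim> N0 = 10000, 6.00 simulated days
#>   final population 10004 (100.0% of N0), 7 portals
#>   119887 entries, 119883 exits recorded

transit_statistics(sim, burn_in_h = 24, entry_before_h = 72)
#> <transit_stats> mean transit 11.90 h over 39897 closed records (18 still inside)
```

The population holds within ~1% of its initial size for six simulated
days, and the mean transit time of the ~40k cells that entered after the
24 h burn-in is 11.90 h — within 1% of the configured 12 h residence
time, confirming that the calibrated exit-portal law balances the influx.

The chemotaxis scheme's worked example — attraction at 30° from the
x-axis on a 2D lattice:

```r
round(chemo_only_probabilities(c(0.866, 0.5)), 3)
#> [1] 0.439 0.386 0.146 0.000 0.000 0.000 0.000 0.028
```

and the directional chemotaxis index rises from 0 to ~0.74 as the
attraction strength goes from 0 to 1:

```r
set.seed(1)
chemotaxis_index(1, n_steps = 10, n_traj = 1000)   # ~0.737
```

Result objects are tibble-first: `tidy()` returns the population time
series, `glance()` a one-row summary, and `autoplot()` standard ggplots;
`ci_sweep()`, `calibrate_exit_constants()`, `single_portal_scenario()`
and `tagged_subset_experiment()` cover the calibration and scenario
analyses. A thin command-line front end with `run`, `calibrate-exits`,
`calibrate-beta`, `ci-sweep` and scenario subcommands ships in
`inst/cli/paracortex-sim.R`.

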