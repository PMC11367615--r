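# mhrcal

Simulation, calibration and dose-rate screening for the **Multi-Hit Repair
(MHR)** model of radiation-induced cell damage.

Radiobiologists fitting dynamic damage-repair models to clonogenic-survival
and comet-assay data face a chronic problem: many different parameter sets
(i.e. many different repair dynamics) explain the same data. This package
implements a complete workflow to address that ambiguity:

* **Forward model** — the MHR compartment chain. Population $L_i$ holds the
  fraction of cells with $i$ hits; hits are induced at rate $\alpha R(t)$
  during a square dose-rate pulse, repaired at rate $c_r e^{-\mu_\Gamma
  \Gamma}$ where the transient biological dose equivalent $\Gamma$ tracks
  radiation-induced loss of repair capacity ($\dot\Gamma = R - \gamma
  \Gamma$), and damaged cells are eliminated at rate $c_e$. The surviving
  fraction is the final $L_0$. Stiff-capable compiled integration with
  exact square-pulse handling.
* **Assay mapping** — comet tail intensities binned into populations (4 %
  half-open bins) and model distributions renormalized for comparison.
* **Objectives & calibration** — comet, clonogenic ($\log_{10}$) and
  combined ($\varepsilon_{clono} + \xi\,\varepsilon_{comet}$) error
  functions, and an iterative ABC-style ensemble: uniform priors, Gaussian
  perturbation, greedy error-decreasing acceptance, per-member early stop.
* **Nine theoretical dose-rate discriminators** — dose-rate ordering of
  survival, growth of the log-survival gap with dose, the low-dose-rate
  exponential limit, fractionation sparing, data coverage, and LQ/LQL
  shape constraints — used to discard unrealistic parameter sets.
* **Target-site hit-cluster Monte Carlo** — interprets $L_k$ as "at least
  one cluster of $k$ hits": per-site hit accumulation in 0.5 Gy steps with
  the retention threshold calibrated to 40 hits/Gy, plus an exact
  binomial-maximum oracle.
* **Synthetic-data generator** — survival and comet datasets with known
  ground truth, so every pipeline stage is testable without external data.

## Worked example

Simulate the worked-example parameter set, screen it, and run the cluster
simulation:

```r
library(mhrcal)

p <- mhr_params(alpha = 0.26, c_r = 7.76, c_e = 0.83,
                mu_gamma = 0.31, gamma = 0.31)

# acute 6 Gy at 6 Gy/min, followed 10 h
traj <- simulate_mhr(p, irradiation(6, 6))
surviving_fraction(traj)
#> [1] 0.5938004

# the full theoretical screen (no survival data, so VII is skipped)
evaluate_discriminators(p)
#> Theoretical discriminator report
#>   I    pass
#>   II   pass
#>   III  pass
#>   IV   pass
#>   V    pass
#>   VI   pass
#>   VII  not evaluated
#>   VIII pass
#>   IX   pass
#>   overall: pass

# hit-cluster interpretation: 6 Gy, 1e4 target sites, q solved to 0.998
res <- summarize_clusters(simulate_cluster_cells(
  cluster_sim_config(n_target = 1e4, dose_gy = 6, n_cells = 1e5, seed = 7)))
res
#> Cluster simulation summary (100000 cells)
#>   modal population: L2
#>   population fractions: L1=0.0721, L2=0.91, L3=0.0174, L4=4e-05
```

The surviving fraction is the fraction of cells still able to form
colonies 10 h after the exposure. The screen confirms this parameter set
produces realistic dose-rate behavior. The cluster summary says that after
6 Gy nearly all nuclei carry at most two hits per target site: ~91 % of
cells sit in $L_2$, ~7 % in $L_1$ and ~2 % in $L_3$, with the largest
per-site cluster defining the population.

A thin command-line wrapper around the same functions is installed at
`system.file("cli/mhr", package = "mhrcal")` with subcommands `simulate`,
`calibrate`, `discriminate`, `cluster-sim` and `synth`; every run writes a
JSON provenance record next to its output.

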