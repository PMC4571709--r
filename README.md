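# trophoweb

Topology, modularity and species roles in directed food webs.

## What it is for

Poleward-shifting generalist fish are re-wiring high-latitude marine food
webs. Assessing that change requires comparing the *structure* of regional
webs: how densely they are connected, how strongly they decompose into
modules, and which species hold the modules together. `trophoweb` implements
that comparison pipeline for directed (prey → predator) food webs:

- **Sub-web construction** — induce regional webs from a pooled meta-web on
  regional species lists, and model invasions by adding newcomer species
  with their full meta-web diets (`induced_subweb()`, `add_species()`).
- **Structural metrics** — S, L, linkage density L/S, connectance L/S²,
  % cannibals, % species in loops, mean path length, mean clustering,
  short-weighted trophic levels SWTL = (shortest + prey-averaged)/2,
  omnivory, and cumulative degree distributions with exponential-rate fits
  (`metrics_report()`, `trophic_levels()`, `degree_summary()`).
- **Modularity** — for a partition into modules *s*,

  M = Σ_s [ I_s/L − (d_s/2L)² ],

  maximized by a compiled simulated-annealing search with node, merge and
  split moves (`anneal_partition()`), tested for significance against
  degree-preserving double-edge-swap null webs with the permutation
  correction p = (1 + #{M_null ≥ M_emp})/(n + 1)
  (`null_modularity_test()`).
- **Species roles** — within-module degree z = (k_is − mean_s)/SD_s and
  participation coefficient PC = 1 − Σ_t (k_it/k_i)², classified with the
  thresholds z = 2.5 and PC = 0.625 into peripherals, connectors, module
  hubs and network hubs, with 95% CIs over annealing replicates
  (`role_profiles()`).
- **Module–trait association** — a permutation test on the discriminant
  (Pillai-type) separation of modules by habitat (B/P/BP) and trophic level
  (`module_trait_association()`).
- **Spatial centrality** — station-wise mean meta-web degree of the species
  present, aggregated on a regular 50 km grid
  (`station_mean_degree()`, `grid_aggregate()`).
- **Synthetic generators** — a niche-model baseline, planted-partition
  benchmarks, and a full synthetic meta-web (~230 species, ~2200 links, two
  overlapping regional pools, planted super-generalists) so the entire
  pipeline runs and is tested without any data download
  (`niche_model_web()`, `planted_module_web()`, `synthetic_metaweb()`).

The methods vignette (`vignettes/foodweb-topology.Rmd`) documents the
model conventions, numerical choices and known limitations.

## Worked example

```r
library(trophoweb)

sim <- synthetic_metaweb(seed = 1)        # meta-web + two regional pools
cfg <- comparison_config(n_replicates = 10, n_null = 49, seed = 1,
                         schedule = reduced_schedule())
rep <- run_comparison(sim$meta, sim$region1, sim$region2,
                      newcomers = sim$generalists, config = cfg)
print(rep)
```

```
Food-web comparison report
  metric          region1    region2 region2_updated
  S                   172        166        170
  L                  1340        985       1212
  LD                 7.79       5.93       7.13
  C                  0.05       0.04       0.04
  ...
  modularity         0.31       0.38       0.34
  Whole-percent differences (first-named web as denominator):
     metric diff_1_2 diff_3_2
         LD       24       17
          C       20        0
 modularity      -23      -12
  region1: M = 0.31, null 0.22 +/- 0.004, p = 0.02
  region2: M = 0.38, null 0.26 +/- 0.004, p = 0.02
  region2_updated: M = 0.34, null 0.23 +/- 0.004, p = 0.02
```

Reading the output: region 1 (the warm pool holding the planted
generalists) is more densely connected (LD 7.79 vs 5.93) and less modular
(M 0.31 vs 0.38) than region 2; adding the four generalists to region 2
(`region2_updated`) pulls its structure toward region 1 — modularity drops
by 12% while connectance and linkage density rise. All three webs are
significantly more modular than their degree-preserving nulls. The role
table confirms the planted design:

```r
r <- rep$webs$region1$roles
r[r$role == "network_hub", c("id", "z_mean", "pc_mean", "role", "degree")]
```

```
       id z_mean pc_mean        role degree
7   bas06   2.59   0.813 network_hub     55
9   bas08   2.77   0.814 network_hub     52
169  gen1   3.76   0.806 network_hub     57
170  gen2   3.65   0.811 network_hub     56
171  gen3   3.18   0.788 network_hub     49
172  gen4   4.51   0.730 network_hub     65
```

The four planted generalists (`gen1`–`gen4`) sit in the network-hub region
of the z–PC plane (z ≥ 2.5, PC ≥ 0.625), alongside a few widely-eaten
basal resources — exactly the configuration in which habitat-coupling
generalists reduce modularity.

Users holding deposited empirical web files (edge-list and attribute CSVs)
can run the same analysis on them with `read_web()` /
`analyze_web_files()`; a thin command-line wrapper is installed at
`inst/scripts/trophoweb`.

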