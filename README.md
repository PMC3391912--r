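# termitory

Seasonal lattice simulation of subterranean termite foraging territories,
with rank-size analysis and SOM/Ward partitioning of the climate-parameter
plane.

Subterranean termite colonies (the motivating system is the Formosan
subterranean termite, *Coptotermes formosanus*) expand their foraging
territory while conditions allow and contract towards the nest in winter.
`termitory` models this as a stochastic cellular automaton on an `L x L`
lattice: each cell of a fixed random landscape carries a tunneling-ease
probability `P_trans ~ U(0, 1)`; `N` founding pairs seed territories that
grow by synchronous local rules during summers of duration `T` and shrink
each winter to `sigma` percent of their size (cells farthest from the
founding cell removed first), regrowing from a few distally chosen
reactivation points. `T` and `sigma` are the two climate variables: longer
summers and milder winters both intensify competition for space.

The downstream statistic is the **two-regime rank-size slope `m`**: per
parameter combination, replicate territory sizes are sorted descending,
averaged rank-wise into `<A>`, and the front (large-territory) region of
the semi-log curve `ln <A>` vs rank is fitted by a two-segment least
squares with a free breakpoint; `m` is the absolute front slope — larger
`m`, more inequality among the large territories. Records `(T, sigma, m)`
from a factorial sweep are finally clustered with a 6x7 Kohonen
self-organizing map followed by Ward's minimum-variance linkage, giving a
partition of the `(T, sigma)` plane by slope regime.

The package is aimed at spatial ecologists and methodologists studying
climate effects on territorial social insects, and at anyone needing a
compact, fully reproducible growth–shrinkage lattice model with its
analysis chain.

## Worked example

```r
library(termitory)

cfg <- sim_config(L = 100, N = 30, T_summer = 10, sigma = 30, rng_seed = 1)
res <- run_simulation(cfg)
res
#> <territory_sim> 17 cycle(s) (steady), 30 territories, 2729 termite cells

sizes <- territory_sizes(res$final_grid)
head(sort(sizes, decreasing = TRUE))
#>  24  30  23  10   7   2
#> 147 122 118 117 114 112

# replicate-averaged rank-size distribution and its front slope
reps <- lapply(1:20, function(r) {
  cfg$rng_seed <- r
  territory_sizes(run_simulation(cfg)$final_grid)
})
d <- rank_size_distribution(reps)
fit_two_segment_slope(d)
#> <slope_fit> breakpoint=27 m_front=0.0305 m_rear=0.1859 sse=0.01412
```

The run reached its quasi-steady seasonal regime after 17 cycles with
2729 occupied cells across 30 territories (the named vector lists the
six largest territories and their labels). Ranking the 20-replicate mean
sizes, the 27 larger territories fall off gently at `m = 0.031` per rank
on the log scale, while the few smallest territories — crushed by early
local competition — drop much faster (`0.186`); large-territory
inequality is what the climate variables move. (`run_sweep()` automates
this over a `(T, sigma, N)` grid with substream-seeded replicates;
`train_som()` + `ward_cluster()` + `project_clusters()` turn the sweep
into the parameter-plane partition.)

A command-line driver is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "termitory", package="termitory"))')" \
  simulate --config cfg.json --seed 7 --out out/
```

with subcommands `simulate`, `sweep`, `analyze` and `som`.

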