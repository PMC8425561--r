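# scentmark

Spatially explicit agent-based simulation of pollinators foraging for
nectar on a continuous toroidal meadow, with and without the use of
repellent scent marks.

## The problem

Bumblebees, honeybees and several solitary bees leave short-lived scent
marks on the flowers they visit. Because nectar refills gradually, a
fresh mark reliably signals an empty flower, and rejecting marked
flowers lets a forager skip wasted handling time. This package simulates
a population of such foragers to ask two questions: how much does the
cue improve individual foraging efficiency as exploitation competition
(pollinators per flower) varies, and what does the coupled behavior do
to the community — the distribution of standing nectar, the visitation
rate of flowers, and the spread of pollen?

## The model in brief

- Meadow: continuous 2-D torus of side `size_map` (default 50), with
  `round(flower_density * size_map^2)` flowers (default 250) and
  `round(pollinator_ratio * n_flowers)` pollinators.
- Flower state after an accepted visit: nectar `min(1, c * tau)`, scent
  `max(0, 1 - c * tau)` with refill coefficient `c` per step and `tau`
  the time since the visit — the mark is the exact complement of the
  refill state until saturation.
- Pollinators search by a correlated random walk (unit steps; Gaussian
  turning angle with sd `2 * pi * inertia`), land on a free, novel flower
  within the detection radius (1), and then decide: scent users accept
  with probability `1 - scent` (Bernoulli), non-users always accept. An
  accepted visit harvests everything and costs `cost` handling steps
  (default 5). One pollinator per flower, randomized update order,
  single seeded RNG stream, bit-exact replay from `(config, seed)`.

Outputs per run: the full visit-event log, per-agent end states, and
summary metrics — mean and CV of nectar collected, nectar per accepted
visit, remaining nectar, visits per flower, and pollen carryover (for
each focal flower, the distinct flowers its visitors subsequently
reach).

## Worked example

```r
library(scentmark)

cfg <- sim_config(pollinator_ratio = 2, refill_coef = 0.0025,
                  use_scent = TRUE, seed = 3)
res <- run_simulation(cfg)
summary(res)
#> Per-run summary metrics
#>   250 flowers, 500 pollinators, 5491 accepted visits
#>   nectar collected/pollinator: mean 1.7065, CV 0.4194
#>   nectar per accepted visit:   0.1554
#>   nectar remaining/flower:     mean 0.0771, CV 0.7432
#>   accepted visits/flower:      mean 21.9640, CV 0.2154
#>   pollen carryover/flower:     mean 5.2202, CV 0.1081
```

Re-running with `use_scent = FALSE` at the same seed gives 28,160
accepted visits (112.6 per flower — a 5.1-fold increase), 0.0309 nectar
per visit (5 times less) and carryover 21.98: scent users visit far
fewer flowers, each visit is far more rewarding, and pollen moves much
less. Sweep helpers reproduce the full competition × refill × strategy
surfaces:

```r
tab <- run_sweep(design_competition_sweep(replicates = 10, base_seed = 101))
sweep_cell_means(tab, "mean_visits_per_flower")
plot_competition_sweep(tab, "mean_nectar_collected")
```

A global sensitivity analysis (uniform parameter sampling + regression-
forest importance ranking) is available via `sensitivity_design()` /
`run_sensitivity()`, and a thin command-line wrapper with `run`,
`sweep`, `sense` and `summarize` subcommands ships in
`inst/cli/scentmark.R`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantity from
scratch against the installed package: it runs 10 replicate simulations
per strategy at two pollinators per flower (default meadow, refill
0.0025), measures the mean number of accepted visits per flower with and
without scent-mark use, and writes the no-scent/scent fold reduction as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
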