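# crowdga

Genetic-algorithm analysis of visual crowding in dense displays, in
silico.

In peripheral vision, flanking elements impair target identification
(*crowding*), classically within Bouma's window — a radius of about half
the target's eccentricity. With dense displays, however, human
interference maps *shrink*: when a genetic algorithm (GA) evolves a dense
flanker array against an observer's tilt-discrimination accuracy, the
improvement is driven almost exclusively by the target's nearest
neighbours. `crowdga` reproduces this paradigm with simulated observers
and asks which architectures can both obey Bouma's law in sparse displays
and shrink their interference range in dense ones.

The package is aimed at computational-vision researchers who want a
fast, fully reproducible desk-scale version of the paradigm: every
stimulus is synthetic, every run is seed-replayable, and the whole
pipeline (calibration → GA + neutral control → statistics) runs in
seconds on one CPU.

## What's inside

* **Stimuli** — 15 × 19 bar grids (284 binary vertical/horizontal
  flankers + a ±5° target at 6° eccentricity, 0.75° spacing), sparse
  4-flanker displays, lossless text/JSON/CSV serialization.
* **Observers** — one 2AFC contract, three architectures:
  * *Bouma pooling*: the target signal $t_w\sin 2\theta$ is diluted to
    $t_w\sin(2\theta) / (t_w + \sum_f w(d_f)\,s_{c(f)})$ by every flanker
    within the 3° pooling window, with Gaussian distance weights $w$ and
    similarity gains $s_\mathrm{V} = 1 > s_\mathrm{H}$;
  * *popcode*: orientation channels tiling $[-90°, 90°)$, spatial kernel
    weighting, doubled-angle population-vector read-out in a ±45° band
    around vertical;
  * *two-stage grouping*: deterministic collinear same-class grouping
    first, then pooling/popcode interference restricted to the target's
    perceptual group.
* **GA** — 20 displays → best 4 parents → 12 children (uniform crossover,
  4% uniform-reassignment mutation) × 6 generations × 4 sessions × 10
  simulated subjects, plus the neutral (random-selection) drift control.
* **Measures** — performance over generations; per-slot Welch-t selection
  maps (GA vs neutral, α = 0.05 uncorrected, signed effect sizes); sparse
  Bouma's-law curves; vertical-proportion curves.
* **Reporting** — YAML experiment configs, `run_experiment()` bundles
  with pass/fail summary, ggplot heatmaps/curves, and a thin CLI
  (`inst/cli/crowdga.R`).

## Worked example

```r
library(crowdga)

set.seed(1)
observer <- calibrate_noise(grouping_observer())  # 67% at 30% vertical
observer
#> <grouping_two_stage observer> noise_sd = 0.1799
#>   interference stage: bouma_pooling, out_group_gain = 0
#>   calibrated: accuracy 0.670 at p_vertical = 0.3

ga      <- run_condition(observer, ga_config(selection_mode = "fitness"), seed = 11)
neutral <- run_condition(observer, ga_config(selection_mode = "neutral"), seed = 12)

performance_measure(ga)
#>   abscissa mean_accuracy     sd n_runs
#> 1        1         0.659 0.0202     10
#> 2        2         0.810 0.0245     10
#> ...
#> 6        6         0.824 0.0151     10
```

Accuracy climbs ~16 points from generation 1 to 6: the GA works against
this observer. Where did the improvement come from?

```r
map <- selection_measure(ga, neutral)
map[order(map$p)[1:5], c("row", "col", "dist_deg", "prop_ga", "prop_neutral", "p", "effect")]
#>     row   col dist_deg prop_ga prop_neutral         p effect
#> 1     1     8     5.25  0.448         0.194 0.0000260  0.254
#> 2     9     8     0.75  0.0208        0.317 0.000308  -0.296
#> 3     1    16     7.97  0.371         0.183 0.00205    0.188
#> 4     5    14     5.03  0.238         0.460 0.00209   -0.223
#> 5     7     8     0.75  0.0229        0.327 0.00358   -0.304
```

The target's two collinear neighbours (rows 7 and 9 of column 8) are
driven almost entirely horizontal (`prop_ga` ≈ 0.02 vs the neutral drift
level ≈ 0.32, effects ≈ −0.3): evolution cut the target out of its
vertical group. The other significant slots are the expected α-rate
scatter of an uncorrected test over 284 locations — smaller effects, far
from the target, not reproducible across reruns (see the methods
vignette). `plot_selection_map(map)` draws the red/blue map;
`sparse_measure(observer)` and `proportion_measure(observer)` give the
two remaining measures.

For a single call that runs everything and writes CSV/JSON artifacts:

```r
res <- run_experiment(experiment_config(out_dir = "results"))
res
```

## Documentation

The methods vignette (`vignettes/crowding-ga-methods.Rmd`) describes the
models, their assumptions, every tunable parameter with its default and
rationale, the statistical conventions of the selection map, and known
limitations.
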