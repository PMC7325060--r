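# osteosim

`osteosim` is a stochastic, agent-based simulator of osteolytic
prostate-cancer bone metastases and their response to Radium-223, a
bone-seeking alpha emitter. It is aimed at computational-oncology
researchers who want to explore how lesion size and distance from the bone
interface shape radiopharmaceutical efficacy, and at modellers who need a
tested hexagonal-lattice cellular-automaton engine with calibration and
analysis tooling around it.

## The model in brief

A lesion lives on an N×N hexagonal grid (one site = one cell diameter,
δ = 500/24 ≈ 20.83 µm) partitioned into tumour, a cell-free tumour–bone
margin, and bone. Every tumour cell carries a 24-hour clock; when the clock
completes, one Monte-Carlo draw assigns mitosis, apoptosis or quiescence:

- Control: p_mit = α₁ = 0.4, p_apop = α₂ = 0.1, uniform over the lesion.
- Radium-223: the bone becomes the drug reservoir, so the probabilities
  depend on each cell's minimum distance d to bone and on the decaying
  activity ζ(t) = e^(−λt) (11-day half-life):

      p_mit  = α₁ / (1 + (α₁/φ_mit(d) − 1) ζ(t))
      p_apop = α₂ / (1 − (1 − α₂/φ_apop(d)) ζ(t))

  with logistic distance profiles φ(d) = K / (1 + ((K−φ₀)/φ₀) e^(−rd)):
  near the bone, apoptosis is quadrupled (φ_apop(0) = 0.4) and mitosis
  nearly abolished (φ_mit(0) = 0.02); both relax to the control rates far
  from the bone and as the activity decays.

Mitoses and apoptoses reshape the lesion through minimum-distance-path
shifts, irreversible bone digestion, and an edge-smoothing pass that keeps
the mass ellipse-like. On top of single runs the package provides seeded
ensembles, the coefficient-of-variation rule for choosing the replicate
count, one-at-a-time sensitivity analysis of α₁/α₂, an NRMSE validation
statistic, Control-vs-Rad223 comparisons, and a distance-dependence study
that pushes the tumour 1–20 pixels (≈ 21–417 µm) away from the bone.
The methods vignette (`vignettes/model-and-methods.Rmd`) documents the
model, the default calibration and its anchors, and known limitations.

## Worked example

```r
library(osteosim)

# one treated micro-lesion (two cells, 120x120 grid), 15-day follow-up
traj <- run_simulation(lesion_config(2, 1), engine_config("Rad223"), seed = 1)
glance(traj)
#> # A tibble: 1 × 6
#>   initial_size final_size final_normalized hours status     cap_hits
#>          <int>      <int>            <dbl> <int> <chr>         <int>
#> 1            2          0                0   329 eradicated      328

# Control vs Rad223 at M = 200 replicates per arm
cmp <- compare_regimens(lesion_config(2, 1), m = 200, base_seed = 1)
cmp[, c("fold_decrease", "normalized_difference",
        "eradication_pct", "eradication_se")]
#>   fold_decrease normalized_difference eradication_pct eradication_se
#> 1       129.962                 50.94            65.5       3.361361
```

The single run above was eradicated in hour 329 (`final_normalized` 0; the
`cap_hits` column counts hours in which the edge-smoothing iteration cap was
logged, which for a two-cell lesion is every hour by construction). In the
comparison, untreated ensembles grow ~51-fold by day 15 while treated ones
shrink: a ~130-fold mean size decrease, a normalized difference of ~51
units, and eradication of the treated lesion in 65.5% ± 3.4% of runs.

A command-line interface wraps the same functions:

```sh
inst/exec/osteosim compare --m 200 --base_seed 1 --out results/
inst/exec/osteosim distance --a_tumor 2 --b_tumor 1 --m 200 --out results/
inst/exec/osteosim calibrate --model decay --table activity.tsv --out results/
```

Every command writes delimited-text results plus a JSON manifest (config
echo, seed, RNG algorithm, package version) sufficient to reproduce the run
bit-exactly.

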