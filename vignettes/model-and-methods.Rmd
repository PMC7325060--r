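---
title: "An agent-based model of bone-metastasis growth and Radium-223 response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of bone-metastasis growth and Radium-223 response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteosim)
```

## The model

`osteosim` simulates an osteolytic prostate-cancer bone metastasis as a
stochastic cellular automaton on a regular hexagonal lattice. Each lattice
site is one cell diameter across; the scaling factor `hex_delta()` = 500/24
= 20.83 µm per site comes from the observation that 24 aligned tumour cells
span 500 µm. The grid is partitioned into three domains:

* **tumour** — one agent per site, initialized as the set of sites whose
  centroid falls inside a centred ellipse with axes `[a_tumor x b_tumor]`
  (in pixels); the smallest lesion `[2 x 1]` is special-cased as exactly two
  adjacent cells;
* **cell-free tumour–bone margin** — the ring of resorbed bone that always
  separates tumour from bone by at least one site (default thickness one
  pixel; the distance study widens it to 5–20 pixels);
* **bone** — a passive continuum that is digested irreversibly: sites can
  leave the bone domain but never return to it.

Every cell carries a 24-hour internal clock, initialized uniformly at random
in 1…24 h. The simulation advances in 1-hour steps; a cell whose clock
reaches 24 h becomes *event-eligible*, its clock resets, and a single
uniform Monte-Carlo draw assigns it one of three fates — apoptosis (with
probability `p_apop`), mitosis (`p_mit`), or quiescence — by comparing the
draw against the apoptosis band first. Eligible cells are assessed together
and the resulting events are executed in one uniformly shuffled sequence,
each against the current, already-mutated state.

Event execution distinguishes edge from interior cells:

* **Mitosis at the edge**: the daughter occupies a uniformly chosen
  non-tumour neighbour, then digests any adjacent bone, restoring the
  one-pixel margin.
* **Mitosis in the interior**: a minimum-distance path (MDP — a shortest
  lattice path, ties broken uniformly at random) is drawn from the mother to
  the nearest bone site; every tumour cell on the path shifts one step
  outward, the daughter takes the vacated site next to the mother, and the
  outermost displaced cell digests the bone around its new position.
* **Apoptosis at the edge**: the cell vacates its site, which becomes margin
  permanently.
* **Apoptosis in the interior**: an MDP to the nearest non-tumour site is
  drawn; cells shift one step inward to fill the vacancy so no hole is left
  inside the mass, and the outer terminal site becomes margin.

After the events, an **edge-smoothing** pass keeps the lesion ellipse-like:
any tumour cell with more than three non-tumour neighbours is swapped with
the non-tumour neighbour that itself has the fewest non-tumour neighbours
(ties resolved by distance to the current tumour centroid, then uniformly at
random), the margin is re-established, and the pass repeats until no trigger
remains or an iteration cap of ten times the current tumour perimeter is
reached (a cap hit is recorded in the run metadata, never raised as an
error). For lesions of only a few cells every cell permanently has more than
three non-tumour neighbours, so the cap is reached each hour by
construction; the swaps then amount to a slow, unbiased random walk of the
mass inside its resorption hole. This is an inescapable consequence of the
stated trigger and is one reason the smallest lesion needs a generous
120-pixel grid. Numerically, the centroid used in the tie-break is
re-accumulated exactly at each smoothing pass and near-equal distances
(within 1e-9) are treated as ties: resolving them by floating-point residue
instead would give the walk a systematic drift.

A run terminates when the follow-up time is reached (default 15 days = 360
steps), the tumour is eradicated (zero cells), or tumour/margin touches the
grid border — reported as a flagged `boundary_arrest` outcome, not an error.
The published grid sides (`default_grid_size()`: 120 for `[2 x 1]` up to 800
for `[500 x 416]`) are sized to make arrests rare.

## Event probabilities

Under **Control**, every cell has the same daily probabilities, `p_mit` =
α₁ = 0.4 and `p_apop` = α₂ = 0.1.

Under **Radium-223**, the bone acts as the reservoir of an alpha-emitting
radioisotope whose particles travel less than ~100 µm, so the effect on each
cell depends on its minimum Euclidean distance `d_min` to the bone (computed
against the current bone set at assessment time) and decays with time:

* the day-0 distance profiles are logistic solutions of
  φ′(d) = r φ(d) (1 − φ(d)/K), i.e.
  φ(d) = K / (1 + ((K − φ₀)/φ₀) e^{−r d});
* the activity ζ(t) = R₀ e^{−λt} starts at R₀ = 1 and halves every 11 days
  (λ = ln 2 / 11 ≈ 0.063 per day; a `decay_params(lambda = 0.06)` switch
  reproduces the printed decay-constant magnitude instead);
* the treated probabilities interpolate between the distance profile at
  administration and the control rates as the activity dies:
  `p_mit = α₁ / (1 + (α₁/φ_mit(d) − 1) ζ(t))` and
  `p_apop = α₂ / (1 − (1 − α₂/φ_apop(d)) ζ(t))`.

At ζ = 1 these equal φ(d) exactly; as ζ → 0 they relax to α₁ and α₂. The
apoptotic profile must satisfy φ_apop(d) ≥ α₂ everywhere (enforced with a
diagnostic), and a configuration whose probabilities could sum above one is
rejected at run start.

### Default calibration

The intravital data behind the distance profiles exist only as published
figures, so the package ships anchor-based defaults rather than refitted
values, and exposes every coefficient in the configuration:

| parameter | default | anchor |
|---|---|---|
| φ_mit: φ₀, K, r | 0.02, 0.4, 0.02/µm | mitosis negligible at the bone interface, recovering the control rate (K = α₁) with a transition near 150 µm and φ_mit(400 µm) ≈ 0.39 |
| φ_apop: φ₀, K, r | 0.4, 0.1, 0.005/µm | apoptosis quadrupled at the interface (φ₀ = 4 α₂), decaying to the control rate; r is set so φ_apop(400 µm) ≈ 0.11, within ~10% of α₂, encoding the loss of any therapeutic effect beyond 400 µm |
| ζ: R₀, λ | 1, ln 2/11 | unit activity at administration, 11-day half-life |

Two numerical points deserve emphasis. First, the decreasing branch of this
logistic family is steepest at d = 0 — it has no near-bone plateau — so the
apoptotic rate constant must be much smaller than the mitotic one for the
two transitions to span the same distance band; a rate of 0.02/µm on the
decreasing branch would put the half-transition at ~11 µm and effectively
remove the near-bone apoptosis boost. Second, even at 400–450 µm the profile
leaves a residual ~1%-per-day net growth penalty; compounded over fifteen
daily cycles this keeps a visible therapy effect at the largest stand-off
distance studied. A single logistic of this family cannot be simultaneously
quadrupled near the bone and fully decayed by 400 µm; this is a known
limitation of the anchor-based defaults and the main reason the package's
distance study retains more far-field effect than the published one.

### Daughter-cell clocks

The published description is silent on the clock a newborn cell receives.
The package defaults to `daughter_clock_mode = "zero"`: a daughter completes
a full 24-hour cycle before its first event, which is the only choice
consistent with a fixed cell-cycle timespan of 24 h. The alternative
`"random"` (uniform 1…24 h, mirroring the initialization) makes first
daughter cycles shorter and raises mean 15-day control growth from
1.3¹⁵ ≈ 51-fold to ≈ 108-fold — bracketing, but not matching, the ~60–70-fold
control growth implied by the published fold/difference pairs. Because the
count process is exactly a clock-explicit branching process (division and
death are never blocked by geometry), this scale is set entirely by the
clock semantics and cannot be tuned independently; the residual gap between
51-fold and the published scale is carried through every downstream
difference statistic and is visible in the package's own results.

## Engine correctness strategy

The tumour-count dynamics are geometry-independent: every assessed division
and death executes regardless of the spatial configuration. The strongest
correctness check therefore compares Control ensembles of the full spatial
engine against an independent, geometry-free, clock-explicit branching
simulation written in plain R (`tests/testthat/helper-oracles.R`): mean
final normalized size and extinction fraction must agree within three
standard errors at M = 1000. The geometric layer is checked separately:
exhaustive-scan oracles for `d_min` (the engine's interface-restricted scan
is exact because the nearest bone site always has a non-bone neighbour),
brute-force path enumeration for the MDP, an independent rasterization count
for the initial ellipse, flood-fill hole detection after interior apoptosis,
and structural invariants (domain partition, margin separation, bone
monotonicity, exact count ledger, smoothing postcondition) after every step
of randomized short runs.

## Calibration fitters

`fit_logistic()` and `fit_decay()` minimise the root-mean-square deviation
between model and calibration table. The default objective is the canonical
RMSD, `sqrt(mean((φ − φ̂)²))`; a `"literal"` mode reproduces the per-point
form `Σ sqrt((1/N)(φᵢ − φ̂ᵢ)²)` for comparability, and the mode used is
recorded in the fit object. The global search is a small seeded differential
evolution (rand/1/bin, population 40, 150 generations) over box constraints
(K, φ₀ ∈ (0, 1], r ∈ [1e-4, 0.5]/µm), polished by `stats::nlminb`; the decay
fit seeds from a log-linear regression with random multi-starts. Degenerate
tables (all responses equal, or a single time point) return a flagged flat
fit with a warning rather than an error. `generate_calibration_fixture()`
produces synthetic tables — logistic in distance over 0–500 µm or
exponential in time over 0–15 days, with additive Gaussian noise truncated
to [0, 1] — emulating the summary data that the published curves were fitted
to; real intravital tables, which these fixtures stand in for, may have
heteroscedastic noise and uneven distance coverage that the fixtures do not
model, so passing recovery tests demonstrate the fitters, not the biology.

## Ensemble statistics and analyses

* `run_ensemble()` runs M independent simulations with consecutive seeds;
  eradicated members contribute zero size from eradication onward, arrested
  members carry their last size and are flagged, and the arrest fraction is
  reported.
* `coefficient_of_variation()` implements C_V = (1/M) Σ σ_{Sᵢ}/μ as a
  percentage. The published definition leaves σ_{Sᵢ} operational detail
  open; here σ_{Sᵢ} is the root-mean-square deviation of member i from the
  ensemble mean trend over all hourly points, and the normalizing μ is the
  time-average of the mean trend. This choice is recorded in the output so
  alternatives can be compared. `choose_M()` returns the smallest candidate
  M whose C_V does not exceed the 2% threshold, sharing members across
  candidates for economy.
* `sensitivity_scan()` perturbs one coefficient at a time over ±50% in 10%
  steps (eleven values, reproducing the published perturbation vectors
  exactly) and normalizes mean final size on the α₁ = 0.4, α₂ = 0.1
  baseline.
* `nrmse()` implements the validation statistic
  100/mean(x_M) · sqrt(Σ(x_M − x_D)²/L) with the default observation days
  0, 2, 5, 9, 12, 15; the in-vivo reference curve is not tabulated anywhere,
  so the statistic is exercised on synthetic series only.
* `compare_regimens()` and `distance_study()` implement the two prediction
  analyses: fold decrease and normalized difference of mean final normalized
  sizes at day 15, eradication percentage with a binomial standard error,
  and the margin-thickness sweep (1, 5, 10, 15, 20 px ≈ 21–417 µm, the five
  distance bins of the published study).

## Problem sizes used in the shipped checks

The package's own test suite and the acceptance script run the study
conditions at the published ensemble sizes where those are the quantity
under test: M = 1000 for the `[2 x 1]` comparisons and eradication, M = 200
for the `[8 x 7]` comparisons, M = 1000 for the branching-oracle
equivalence. The distance study's eradication series uses M = 1000; the
sensitivity scan uses the `[2 x 1]` lesion at M = 80 (counts are
geometry-independent, and the `[8 x 7]` grid truncates the +50% α₁ arm by
boundary arrest, so the small lesion is the cleaner instrument for the
monotonicity check — the published M = 20 on `[8 x 7]` remains the
function's default). Medium and large lesions (`[64 x 53]` and beyond) are
fully supported by the same code paths but are not part of the shipped
checks; their ensembles take hours, and the published grid for `[128 x 106]`
is ambiguous (the grid-size table leaves its cell blank; the package uses
300, shared with `[64 x 53]`, which cannot contain a 60-fold grown lesion —
runs of that size end in a flagged boundary arrest).

## Known limitations

* Bone is passive: no osteoclast/osteoblast agents, no remodelling beyond
  irreversible digestion; no dosimetry or repeated dosing.
* The count process is a branching process by construction, so the absolute
  growth scale is fixed by the clock semantics (51-fold under the default
  daughter clock); published quantities that depend on the absolute scale
  (difference statistics) inherit the ~25% gap discussed above, while
  scale-free quantities (fold decrease, eradication) do not.
* The single-logistic distance family cannot reproduce both the near-bone
  apoptosis quadrupling and a complete loss of effect by 400 µm; the
  far-field residual keeps a measurable therapy effect at the largest
  stand-off distance.
* Edge smoothing has no stable configuration for lesions of a few cells; the
  capped swap walk makes micro-lesions drift slowly inside their resorption
  hole, which enlarges the margin and weakens the distance effect over time.

## A minimal session

```{r example, eval = FALSE}
library(osteosim)

# one treated micro-lesion trajectory
traj <- run_simulation(lesion_config(2, 1), engine_config("Rad223"), seed = 1)
glance(traj)

# regimen comparison at the published ensemble size
cmp <- compare_regimens(lesion_config(2, 1), m = 1000, base_seed = 1)
cmp[, c("fold_decrease", "normalized_difference", "eradication_pct")]

# distance dependence of eradication
distance_study(lesion_config(2, 1), m = 200, base_seed = 1)
```
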