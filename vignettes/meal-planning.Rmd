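---
title: "Energy-balance accounting and genetic-algorithm meal recommendation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-balance accounting and genetic-algorithm meal recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriga)
```

## The problem

Calorie-tracking tools tell a user how many calories remain for the day, but
stop short of answering the question the user actually has: *what can I still
eat?* nutriga closes that loop. It keeps a daily ledger of energy and
macronutrient budgets and then searches a food-composition database for a
meal — a combination of foods, household serving measures and serving counts
— that fills the remaining budget as exactly as possible without exceeding
it, while honoring health constraints (a low-glycemic-index rule for diabetic
users, a cholesterol cap for users with elevated cholesterol).

## Energy and macronutrient accounting

Meal energy uses the Atwater general factors (4 kcal/g for protein and
carbohydrate, 9 kcal/g for fat) over per-100 g food-composition records. A
component consisting of $N$ servings of a food, each serving a household
measure weighing $q$ grams, contributes

$$Z = N \cdot \frac{q}{100}\,(4p + 4c + 9h)$$

kilocalories, where $p$, $c$, $h$ are the food's per-100 g protein,
carbohydrate and fat in grams. A meal's energy is the sum over its
components. Macronutrients are reported as *grams actually consumed*, i.e.
also scaled by $N\,q/100$; this keeps them commensurable with the
gram-denominated daily targets, so deficit arithmetic closes (a summation of
raw per-100 g values would compare quantities of different dimension).
Some foods in the built-in database are recorded at the serving level
rather than decomposed per 100 g; their serving measures carry a direct
kcal-per-serving value that is used in place of the Atwater computation.

The daily requirement starts from the Mifflin-St Jeor basal metabolic rate

$$\mathrm{BMR} = 10W + 6.25H - 5a + s,$$

with weight $W$ in kg, height $H$ in cm, age $a$ in years and $s = +5$ for
males, $-161$ for females, scaled by a physical-activity-level multiplier
(1.2 for little-to-no exercise up to 1.9 for extremely active; these PAL
values are the conventional ones and are overridable). The calorie total
$Q$ is split 50/20/30 across carbohydrate/protein/fat calories, giving gram
targets $C = 0.5Q/4$, $P = 0.2Q/4$, $F = 0.3Q/9$; by construction
$4C + 4P + 9F = Q$ up to rounding, and the package tests enforce this
closure within 0.5 kcal. The split fractions are parameters for users who
prefer a different macronutrient distribution.

Exercise expenditure uses the MET formula $E = k\,\beta W t$ with $\beta$
the metabolic equivalent and $t$ minutes. The default coefficient is
$k = 0.175$; note that the conventional value in the MET literature is
0.0175 kcal·kg⁻¹·min⁻¹, a factor of ten smaller (0.175 makes a 30-minute
moderate walk for an 85 kg person cost ~1560 kcal, which is physiologically
implausible). The coefficient is therefore an explicit argument of
`exercise_energy()` and `log_exercise()` so users can choose the
conventional scale.

### The ledger and the daily reset

A `day_ledger` holds one calendar day. The running calorie deficit follows
the telescoped recurrence $d = Q + \sum E - \sum Z$; macronutrient deficits
are the gram targets minus grams consumed. Overconsumption drives deficits
negative — it is recorded, not rejected — but the predictor floors the
available budget at zero. At the end of the day any residual budget is
deliberately *not* carried over: the model assumes residual energy cannot be
meaningfully quantified and zeroes it, so `end_of_day_reset()` simply opens
a fresh ledger whose deficits equal the (re-computed, e.g. after a weight
update) daily requirement.

## The genetic algorithm

A candidate meal is a chromosome: a base component plus a tail of up to
`max_additional_components` additional components, each gene a
(food, serving measure, serving count) triple. The objective is the slack
$f = D - Z$, the unused part of the available budget $D$; the optimum is the
feasible meal with the smallest slack. Feasibility requires

* $Z \le D$ (never exceed the calorie budget),
* consumed carbohydrate/protein/fat each within the corresponding deficit,
* every item's glycemic index at most 55 when the low-GI constraint is
  active (the bound is per item: one high-GI food disqualifies the meal),
* total meal cholesterol strictly below 300 mg when that constraint is
  active.

Fitness is $1/(1+f)$ for feasible chromosomes — maximal exactly when the
meal fills the budget — and $1/(1+|f|+10^4)$ for infeasible ones. The large
additive penalty ranks every infeasible chromosome below every feasible one
while still ordering infeasible chromosomes among themselves, which lets
early populations evolve toward feasibility instead of being rejected
outright.

Selection is by tournament (size 3 by default; fitness-proportional
roulette is available via `selection_mode`). Crossover exchanges the whole
additional-component tail between two parents at the base/tail boundary,
conserving the pair's component multiset. Mutation hits each gene position
independently with probability `mutation_prob`; a hit redraws the serving
measure and serving count, and — by default (`mutate_foods = TRUE`) —
replaces the gene's food with a uniform draw from the database. This gene
replacement is what supplies genuinely new food material during the search:
with serving-only mutation (`mutate_foods = FALSE`, also provided) the set
of foods in the population can only shrink over generations, and whole
regions of the meal space become permanently unreachable once their foods
leave the gene pool. Each generation is built entirely from new offspring;
a duplicate offspring (same component multiset, measures and counts as one
already produced this generation) carries no new information and is replaced
by a fresh random chromosome, which keeps the effective sampling rate of the
meal space high on small databases.

The defaults — population 30, 500 generations, crossover probability 0.65,
mutation probability 0.01 — are the configuration adopted after the
sensitivity sweep over population sizes \{20, 30, 40, 50, 70, 100\} and
mutation rates \{0.001, 0.01, 0.08, 0.1, 0.5, 0.9\}. A best-ever archive
outside the breeding population (plain elitism, size `top_k`) guarantees
the reported solution is the best feasible chromosome ever evaluated; the
run stops early once that archive has not improved for `patience` (default
50) consecutive generations. An all-infeasible run returns a no-solution
marker rather than an error, as does a zero budget.

### How good is the search?

The test suite compares the GA against exhaustive enumeration of *every*
expressible meal on six-food databases with serving counts capped at 2 and
at most two additional components (a few hundred candidate meals). Two
properties are asserted: the GA never reports a slack below the enumeration
optimum (the oracle is a hard bound), and across 100 seeded random deficit
states on six foods of the built-in database the GA's slack lands within 5%
of the optimum in at least 95 runs under the default configuration. On
larger synthetic databases only the bound is asserted, since the
enumeration space grows combinatorially.

## The built-in and synthetic databases

`builtin_fixture_db()` ships 21 Ghanaian foods with per-100 g records,
glycemic indices and household measures (soup ladle, stew ladle, 1 ball,
1 egg, ...). A few recorded values required care:

* One pepper condiment's source row lists the same number in the fat and
  energy columns; the stored fat is 0.10 g/100 g, the only value under which
  the Atwater energy reproduces the recorded 48.10 kcal.
* Three foods (a rice staple, rabbit, smoked tuna) have recorded per-serving
  energies that are not Atwater-consistent with their per-100 g macros; the
  recorded energies are kept as direct serving-level values.
* The recorded breakfast-diary energies sum to 1017.14, while their stated
  total is 1017.50; the cassava-granule row (55.04 for two servings) closes
  the total exactly if read as 55.40 — a digit transposition — and is stored
  as 27.70 kcal/serving.
* One recommendation group's stated protein and fat totals disagree with
  their own rows; row values are stored, and totals are always recomputed
  as row sums.
* Glycemic-index and cholesterol values that the sources do not provide are
  stored as 0 and are placeholders, not measurements.

`generate_synthetic_db(n, seed)` emulates the shape of a food-composition
table joined with a household-measure atlas: nine food categories with
category-conditioned macro ranges (staples carbohydrate-heavy, meats
protein/fat-heavy with nonzero cholesterol, ...), GI in [0, 110],
cholesterol in [0, 400] mg/100 g, and 1–3 measures per food with weights in
[5, 400] g, all deterministic under the seed. It reproduces the *marginal*
shape of real composition tables but none of their correlation structure
(e.g. fat and cholesterol co-varying within meats) or culinary coherence,
so tests passing on synthetic data demonstrate the arithmetic and the
optimizer, not nutritional realism.

## Numerical choices

* Internal arithmetic is unrounded; energies and grams are rounded to 2
  decimals only at reporting boundaries (recommendation tables round rows
  first and total the rounded rows, so printed totals always equal printed
  row sums).
* The daily calorie total is rounded half-up to the nearest kcal; gram
  targets half-up to 2 decimals.
* Floating-point feasibility comparisons use a 1e-9 kcal/g tolerance; the
  cholesterol bound is strict (`<`), matching its "less than 300 mg"
  definition.
* Ties in tournament selection break toward lower meal energy, then earlier
  population index, making runs fully reproducible under a fixed seed.
* One ledger per calendar date; timestamps outside the ledger's date are
  rejected rather than silently reassigned.

## Test problem sizes

The suite keeps everything at desk scale: the oracle-equivalence check runs
100 GA runs on a six-food database, constraint soundness draws 1000
random deficit states against the 21-food fixture with a reduced GA
configuration (population 10, 15 generations — soundness of the returned
solution is independent of how hard the GA searches), and the
population-by-mutation sweep runs the full 6×6 grid at a 60-generation cap
with patience 12, reporting convergence generations rather than wall-clock
seconds, which are hardware-dependent and not meaningful to assert on.

## Limitations

* Micronutrients beyond glycemic index and cholesterol are out of scope; the
  energy model uses the 4/4/9 Atwater factors only (no fiber or alcohol
  terms).
* Hypertension and blood-sugar fields are recorded on profiles but drive no
  constraint — no rule is defined for them.
* The recommender is meal-type agnostic (no breakfast/dinner heuristics) and
  has no notion of user preference; it optimizes budget fit only.
* Exercise energy relies on user-entered MET levels, not measured activity.
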