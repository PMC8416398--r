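# nutriga

Daily energy-balance tracking and genetic-algorithm meal recommendation for
dietary decision support.

Calorie trackers tell a user how much of their daily budget is left; nutriga
also answers the follow-up question — *which meal, in which household
servings, fills that budget without exceeding it or the user's health
constraints?* It is aimed at nutrition-informatics developers, dieticians
and students of dietetics who want the computation core of an
obesity-management tool as a scriptable R package.

## What it computes

* **Meal energy** by Atwater general factors over per-100 g composition
  records: a component of `N` servings, each a household measure of `q`
  grams, contributes `Z = N · (q/100) · (4p + 4c + 9h)` kcal; macronutrients
  are reported as grams consumed (scaled by `N · q/100`).
* **Daily requirement** from the Mifflin-St Jeor BMR,
  `10W + 6.25H − 5a + s` (`s = +5` male, `−161` female), times a
  physical-activity-level multiplier (1.2–1.9), split 50/20/30 into gram
  targets for carbohydrate/protein/fat so that `4C + 4P + 9F = Q`.
* **Exercise expenditure** `E = k·MET·W·t` with a configurable coefficient.
* **A per-day deficit ledger** with the telescoped recurrence
  `d = Q + ΣE − ΣZ`, macro deficits in grams, and an explicit end-of-day
  reset (no carryover of residual budget).
* **A genetic algorithm** that searches the food database for the feasible
  meal minimizing the slack `f = D − Z` (unused budget), under componentwise
  macro bounds, an optional per-item glycemic-index limit of 55 (diabetes)
  and an optional 300 mg meal-cholesterol cap (elevated cholesterol).
  Fitness is `1/(1+f)` for feasible meals, penalized for infeasible ones;
  selection is by tournament, crossover swaps whole additional-component
  tails, and mutation re-draws servings and foods at random gene positions.

A 21-food Ghanaian fixture database and a seeded synthetic-database
generator ship with the package, so everything runs without downloads. A
command-line interface (`inst/cli/nutriga.R`) wraps profile setup, diary
logging, daily reports and prediction.

## Worked example

An 85 kg, 177 cm, 24-year-old male with little-to-no exercise logs a
breakfast and asks for a recommendation:

```r
library(nutriga)
db   <- builtin_fixture_db()
prof <- user_profile(age_years = 24, sex = "male", height_cm = 177,
                     weight_kg = 85, activity_level = "extremely_inactive")
daily_requirement(prof)
#> <daily_requirement> 2210 kcal | carb 276.25 g | protein 110.50 g | fat 73.67 g

led <- day_ledger(prof, "2026-01-05")
breakfast <- meal(
  meal_component(db_food(db, "waakye"),    n_servings = 2),
  meal_component(db_food(db, "salad"),     n_servings = 2),
  meal_component(db_food(db, "spaghetti"), n_servings = 2),
  meal_component(db_food(db, "gari"),      n_servings = 2),
  meal_component(db_food(db, "fried-fish")),
  meal_component(db_food(db, "tomato-stew")),
  meal_component(db_food(db, "egg")),
  meal_component(db_food(db, "shito"),     n_servings = 2))
led <- log_meal(led, breakfast, "2026-01-05 08:30:00")
led
#> <day_ledger> 2026-01-05: 1 meal(s), 0 exercise(s)
#>   consumed 1017.50 kcal of 2210; expended 0.00 kcal
#>   deficits: 1192.50 kcal | carb 123.25 g | protein 50.50 g | fat 40.67 g

recommend_meals(prof, led, db, ga_config(seed = 7))
#> <meal_recommendation>
#>   -- meal option 1 --
#>   Meal entry             Serving       N      kcal   carb g   prot g    fat g
#>   Okro stew              100 g         1    135.60     5.00     2.80    11.60
#>   Hot pepper             portion       1     48.10    10.70     1.10     0.10
#>   Banku                  Small ball    2    669.92    47.60     4.80     0.80
#>   Banku                  Small ball    1    334.96    23.80     2.40     0.40
#>   Total                                    1188.58    87.10    11.10    12.90
#>   residual after option 1: 3.92 kcal | carb 36.15 g | protein 39.40 g | fat 27.77 g
```

The requirement line is the daily budget (BMR 1841.25 kcal × PAL 1.2,
rounded, with its 50/20/30 gram split). After breakfast the ledger shows
1192.50 kcal and (123.25, 50.50, 40.67) g still available; the recommended
meal consumes 1188.58 kcal of it, leaving 3.92 kcal of slack while staying
inside every macronutrient budget. With a diabetic or high-cholesterol
profile the same call additionally enforces per-item GI ≤ 55 or meal
cholesterol < 300 mg and says so in the notes.

The same flow is available from a shell:

```sh
Rscript inst/cli/nutriga.R init-profile --out profile.yaml --age 24 --sex male \
    --height 177 --weight 85
Rscript inst/cli/nutriga.R log-meal --profile profile.yaml --db foods.csv \
    --ledger diary.jsonl --date 2026-01-05 --item waakye::2 --item egg
Rscript inst/cli/nutriga.R predict --profile profile.yaml --db foods.csv \
    --ledger diary.jsonl --seed 7
```

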