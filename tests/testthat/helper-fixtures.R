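# Shared builders for the worked-example meals and profiles.

fixture_db <- builtin_fixture_db()

comp <- function(db, id, n = 1L, measure = 1L) {
  meal_component(db_food(db, id), measure = measure, n_servings = n)
}

# Kenkey base meal: Kenkey + Okro soup + Hot pepper + Tilapia
kenkey_parent_meal <- function(db = fixture_db) {
  meal(comp(db, "kenkey-ga"), comp(db, "okro-soup"),
       comp(db, "hot-pepper"), comp(db, "tilapia"))
}

# Rice-ball base meal: Rice ball + Palm nut soup x2 + Rabbit + Smoked tuna x2
riceball_parent_meal <- function(db = fixture_db) {
  meal(comp(db, "rice-ball"), comp(db, "palm-nut-soup", 2L),
       comp(db, "rabbit"), comp(db, "smoked-tuna", 2L))
}

# The worked breakfast diary: eight entries totalling 1017.50 kcal
breakfast_meal <- function(db = fixture_db) {
  meal(comp(db, "waakye", 2L), comp(db, "salad", 2L), comp(db, "spaghetti", 2L),
       comp(db, "gari", 2L), comp(db, "fried-fish"), comp(db, "tomato-stew"),
       comp(db, "egg"), comp(db, "shito", 2L))
}

# The worked main-course recommendation: Banku + Okro stew + Tilapia + Lamb
recommended_main_meal <- function(db = fixture_db) {
  meal(comp(db, "banku"), comp(db, "okro-stew"),
       comp(db, "tilapia"), comp(db, "lamb-mutton"))
}

# The drinks group of the same recommendation
recommended_drinks_meal <- function(db = fixture_db) {
  meal(comp(db, "apple-juice", 2L), comp(db, "wheat-bread"))
}

# 85 kg, 177 cm, 24-year-old male with little-to-no exercise
reference_profile <- function(...) {
  user_profile(age_years = 24, sex = "male", height_cm = 177, weight_kg = 85,
               activity_level = "extremely_inactive", ...)
}

# His day ledger after logging the worked breakfast
reference_ledger_after_breakfast <- function(db = fixture_db) {
  led <- day_ledger(reference_profile(), "2026-01-05")
  log_meal(led, breakfast_meal(db), "2026-01-05 08:30:00")
}

# tiny handmade foods for unit tests
plain_food <- function(id = "plain", carb = 10, protein = 5, fat = 2, gi = 20,
                       chol = 0, weights = 100, labels = NULL) {
  if (is.null(labels)) labels <- paste0("m", seq_along(weights))
  food_item(id, id, "other", carb, protein, fat, gi, chol,
            measures = data.frame(label = labels, weight_g = weights))
}
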