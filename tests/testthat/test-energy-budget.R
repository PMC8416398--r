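test_that("Mifflin-St Jeor BMR matches direct arithmetic", {
  expect_equal(bmr(reference_profile()), 1841.25)
  expect_equal(bmr(user_profile(35, "female", 163, 55)), 1232.75)
  m <- user_profile(40, "male", 170, 70)
  f <- user_profile(40, "female", 170, 70)
  expect_equal(bmr(m) - bmr(f), 166) # sex constants +5 vs -161
})

test_that("daily requirement applies PAL and the 50/20/30 split", {
  req <- daily_requirement(reference_profile())
  expect_equal(req$calories_kcal, 2210)
  expect_equal(req$carbohydrate_g, 276.25)
  expect_equal(req$protein_g, 110.5)
  expect_equal(req$fat_g, 73.67)

  active <- user_profile(24, "male", 177, 85, activity_level = "extremely_active")
  expect_equal(daily_requirement(active)$calories_kcal, 3498) # round(1.9*1841.25)

  expect_error(daily_requirement(reference_profile(), pal = c(sedentary = 1.375)),
               "no PAL multiplier")
})

test_that("requirement satisfies the Atwater closure over random profiles", {
  set.seed(21)
  for (i in 1:25) {
    prof <- user_profile(runif(1, 18, 80), sample(c("male", "female"), 1),
                         runif(1, 145, 200), runif(1, 45, 120),
                         activity_level = sample(names(pal_multipliers()), 1))
    req <- daily_requirement(prof)
    closure <- 4 * req$carbohydrate_g + 4 * req$protein_g + 9 * req$fat_g
    expect_lt(abs(closure - req$calories_kcal), 0.5)
    expect_true(all(unlist(req) > 0))
  }
})

test_that("exercise energy is coefficient * MET * W * t", {
  expect_equal(exercise_energy(1, 1, 1), 0.175)
  expect_equal(exercise_energy(3.5, 85, 30), 1561.875)
  expect_equal(exercise_energy(3.5, 85, 0), 0)
  # conventional coefficient is one tenth of the default
  expect_equal(exercise_energy(3.5, 85, 30, coefficient = 0.0175),
               exercise_energy(3.5, 85, 30) / 10)
})

test_that("ledger deficit telescopes exactly over any log sequence", {
  led <- reference_ledger_after_breakfast()
  expect_equal(calorie_deficit(led), 1192.50)
  md <- macro_deficits(led)
  expect_equal(unname(md), c(123.25, 50.5, 40.67))

  led2 <- log_exercise(led, met = 4, duration_min = 25, "2026-01-05 17:00:00",
                       coefficient = 0.0175)
  expect_equal(calorie_deficit(led2),
               1192.50 + exercise_energy(4, 85, 25, 0.0175))

  # property: d = Q + sum(E) - sum(Z) after arbitrary interleavings
  set.seed(31)
  db <- generate_synthetic_db(10, seed = 5)
  for (rep in 1:10) {
    led <- day_ledger(reference_profile(), "2026-02-01")
    z <- 0; e <- 0
    for (step in 1:6) {
      if (runif(1) < 0.5) {
        m <- meal(comp(db, sample(db$id, 1), sample(1:3, 1)))
        z <- z + meal_energy(m)
        led <- log_meal(led, m, "2026-02-01 10:00:00")
      } else {
        met <- runif(1, 1, 8); mins <- runif(1, 5, 60)
        e <- e + exercise_energy(met, 85, mins)
        led <- log_exercise(led, met, mins, "2026-02-01 10:00:00")
      }
    }
    expect_equal(calorie_deficit(led),
                 led$requirement$calories_kcal + e - z, tolerance = 1e-9)
  }
})

test_that("empty meals leave the deficit unchanged; timestamps are checked", {
  led <- day_ledger(reference_profile(), "2026-01-05")
  d0 <- calorie_deficit(led)
  led <- log_meal(led, meal(), "2026-01-05 09:00:00")
  expect_equal(calorie_deficit(led), d0)
  expect_error(log_meal(led, meal(), "2026-01-06 00:30:00"), "outside ledger date")
  expect_error(log_exercise(led, 3, 30, "2026-01-04 23:00:00"), "outside ledger date")
})

test_that("end-of-day reset starts fresh and re-derives the requirement", {
  led <- reference_ledger_after_breakfast()
  nxt <- end_of_day_reset(led, "2026-01-06")
  expect_equal(calorie_deficit(nxt), nxt$requirement$calories_kcal)
  expect_equal(unname(macro_deficits(nxt)),
               c(nxt$requirement$carbohydrate_g, nxt$requirement$protein_g,
                 nxt$requirement$fat_g))
  # resetting the fresh ledger again yields the same state
  again <- end_of_day_reset(nxt, "2026-01-07")
  expect_equal(again$requirement, nxt$requirement)
  expect_equal(calorie_deficit(again), calorie_deficit(nxt))

  lighter <- reference_profile()
  lighter$weight_kg <- 80
  nxt2 <- end_of_day_reset(led, "2026-01-06", profile = lighter)
  expect_equal(nxt2$requirement$calories_kcal,
               round(1.2 * bmr(lighter)))
  expect_error(end_of_day_reset(led, "2026-01-05"), "strictly after")
})

test_that("ledger and profile serialization round-trip", {
  led <- reference_ledger_after_breakfast()
  led <- log_exercise(led, 3.5, 20, "2026-01-05 18:00:00")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_ledger(led, path)
  back <- read_ledger(path)
  expect_equal(back$date, led$date)
  expect_equal(calorie_deficit(back), calorie_deficit(led), tolerance = 1e-9)
  expect_equal(macro_deficits(back), macro_deficits(led), tolerance = 1e-9)
  expect_equal(length(back$meal_entries), 1L)
  expect_equal(length(back$exercise_entries), 1L)

  ppath <- withr::local_tempfile(fileext = ".yaml")
  write_profile(reference_profile(diabetes = "medium"), ppath)
  prof <- read_profile(ppath)
  expect_equal(prof$weight_kg, 85)
  expect_equal(prof$diabetes, "medium")
})
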