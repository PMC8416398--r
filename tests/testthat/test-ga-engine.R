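state_2000 <- deficit_state(2000, 280, 120, 80)

test_that("evaluation scores slack and applies every active constraint", {
  main <- recommended_main_meal()
  ev <- evaluate(main, state_2000)
  expect_equal(ev$energy_kcal, 826.86, tolerance = 1e-6)
  expect_equal(ev$objective, 2000 - 826.86, tolerance = 1e-6)
  expect_true(ev$feasible)
  expect_equal(ev$fitness, 1 / (1 + ev$objective))

  # a meal that exactly fills the budget has fitness 1
  exact <- meal(meal_component(plain_food("x", carb = 25, protein = 0, fat = 0)))
  st <- deficit_state(100, 50, 10, 10)
  ev2 <- evaluate(exact, st)
  expect_equal(ev2$objective, 0)
  expect_equal(ev2$fitness, 1)

  # per-item GI bound makes the meal infeasible for a diabetic-style state
  diab <- deficit_state(2000, 280, 120, 80, gi_limit = 55)
  high_gi <- meal(meal_component(plain_food("hg", gi = 70)))
  ev3 <- evaluate(high_gi, diab)
  expect_false(ev3$feasible)
  expect_lt(ev3$fitness, 1e-4) # penalized

  # macro excess is infeasible even with calorie slack
  fatty <- meal(meal_component(plain_food("ft", carb = 0, protein = 0, fat = 50),
                               n_servings = 2L))
  ev4 <- evaluate(fatty, deficit_state(2000, 280, 120, 80))
  expect_false(ev4$feasible)

  # cholesterol bound is strict
  chol_st <- deficit_state(2000, 280, 120, 80, cholesterol_limit_mg = 300)
  chol_meal <- meal(meal_component(plain_food("ch", chol = 150), n_servings = 2L))
  expect_false(evaluate(chol_meal, chol_st)$feasible)
})

test_that("selection probabilities are fitness-proportional and normalized", {
  st <- deficit_state(10, 100, 100, 100)
  m0 <- meal(meal_component(plain_food("a", carb = 2.5, protein = 0, fat = 0)))  # Z=10, slack 0
  m1 <- meal(meal_component(plain_food("b", carb = 2.25, protein = 0, fat = 0))) # Z=9, slack 1
  pop <- list(evaluate(m0, st), evaluate(m1, st))
  expect_equal(selection_probability(pop), c(2 / 3, 1 / 3))
  expect_equal(selection_probability(pop[1]), 1)
  uniform <- list(evaluate(m0, st), evaluate(m0, st), evaluate(m0, st))
  expect_equal(selection_probability(uniform), rep(1 / 3, 3))
})

test_that("tournament selection returns the fittest entrant", {
  st <- deficit_state(1000, 300, 150, 100)
  db <- generate_synthetic_db(8, seed = 2)
  cfg <- ga_config(population_size = 12, seed = 5)
  pop <- init_population(db, cfg, st)
  # a tournament over the whole population always returns the global best
  fits <- vapply(pop, `[[`, numeric(1), "fitness")
  for (i in 1:5) {
    win <- tournament_select(pop, tournament_size = length(pop))
    expect_equal(win$fitness, max(fits))
  }
  expect_error(tournament_select(pop, length(pop) + 1), "exceeds population")
  set.seed(99)
  w1 <- tournament_select(pop, 3)
  set.seed(99)
  w2 <- tournament_select(pop, 3)
  expect_equal(w1, w2)
})

test_that("initial populations have the configured size and are reproducible", {
  db <- generate_synthetic_db(10, seed = 6)
  st <- deficit_state(1500, 250, 100, 70)
  cfg <- ga_config(population_size = 30, seed = 17)
  p1 <- init_population(db, cfg, st)
  p2 <- init_population(db, cfg, st)
  expect_length(p1, 30)
  expect_equal(p1, p2)
  sizes <- vapply(p1, function(e) length(e$meal), integer(1))
  expect_true(all(sizes >= 1 & sizes <= 1 + cfg$max_additional_components))

  solo <- food_db(list(plain_food("only")))
  cfg0 <- ga_config(population_size = 5, max_additional_components = 0, seed = 1)
  p3 <- init_population(solo, cfg0, st)
  expect_true(all(vapply(p3, function(e) length(e$meal), integer(1)) == 1L))
})

test_that("crossover swaps whole tails and conserves the component multiset", {
  ch <- crossover_meals(kenkey_parent_meal(), riceball_parent_meal(), 1)
  expect_equal(vapply(unclass(ch[[1]]), `[[`, character(1), "food_id"),
               c("kenkey-ga", "palm-nut-soup", "rabbit", "smoked-tuna"))
  expect_equal(vapply(unclass(ch[[2]]), `[[`, character(1), "food_id"),
               c("rice-ball", "okro-soup", "hot-pepper", "tilapia"))

  expect_equal(crossover_meals(kenkey_parent_meal(), riceball_parent_meal(), 0),
               list(kenkey_parent_meal(), riceball_parent_meal()))

  a <- meal(comp(fixture_db, "banku"))
  b <- meal(comp(fixture_db, "egg"))
  expect_equal(crossover_meals(a, b, 1), list(a, b)) # tail-less parents

  # multiset of components is conserved for random parents
  set.seed(41)
  db <- generate_synthetic_db(8, seed = 8)
  sig <- function(m) {
    s <- vapply(unclass(m), function(cp) paste(cp$food_id, cp$measure_label,
                                               cp$n_servings), character(1))
    sort(s)
  }
  for (i in 1:10) {
    p1 <- meal(lapply(sample(db$id, 3), function(id) comp(db, id)))
    p2 <- meal(lapply(sample(db$id, 2), function(id) comp(db, id)))
    kids <- crossover_meals(p1, p2, 1)
    expect_equal(sort(c(sig(kids[[1]]), sig(kids[[2]]))), sort(c(sig(p1), sig(p2))))
  }
})

test_that("mutation respects the rate and the mutate_foods switch", {
  db <- builtin_fixture_db()
  m <- kenkey_parent_meal()
  cfg <- ga_config(seed = 1)
  expect_equal(mutate_meal(m, 0, db, cfg), m)

  # serving-only mutation preserves the food composition even at rate 1
  cfg_fix <- ga_config(mutate_foods = FALSE)
  set.seed(5)
  mut <- mutate_meal(m, 1, db, cfg_fix)
  expect_equal(vapply(unclass(mut), `[[`, character(1), "food_id"),
               vapply(unclass(m), `[[`, character(1), "food_id"))

  # gene replacement introduces new foods eventually
  set.seed(6)
  changed <- FALSE
  for (i in 1:20) {
    mm <- mutate_meal(m, 1, db, cfg)
    if (!identical(vapply(unclass(mm), `[[`, character(1), "food_id"),
                   vapply(unclass(m), `[[`, character(1), "food_id"))) changed <- TRUE
  }
  expect_true(changed)

  set.seed(7); m1 <- mutate_meal(m, 0.5, db, cfg)
  set.seed(7); m2 <- mutate_meal(m, 0.5, db, cfg)
  expect_equal(m1, m2)
})

test_that("evolve is deterministic under a fixed seed", {
  db <- builtin_fixture_db()
  st <- deficit_state(1192.50, 123.25, 50.5, 40.67)
  cfg <- ga_config(population_size = 12, generations = 25, patience = 8, seed = 123)
  r1 <- evolve(db, st, cfg)
  r2 <- evolve(db, st, cfg)
  expect_equal(r1$best$meal, r2$best$meal)
  expect_equal(r1$log, r2$log)
})

test_that("evolve returns a no-solution marker when nothing can fit", {
  db <- builtin_fixture_db()
  res <- evolve(db, deficit_state(0, 100, 100, 100), ga_config(seed = 1))
  expect_null(res$best)
  expect_length(res$solutions, 0)
  expect_equal(res$generations_run, 0L)
})

test_that("every solution evolve returns is feasible for its state", {
  db <- builtin_fixture_db()
  cfg <- ga_config(population_size = 10, generations = 15, patience = 5,
                   mutation_prob = 0.05)
  set.seed(77)
  for (i in 1:40) {
    st <- random_state(with_limits = TRUE)
    cfg$seed <- i
    res <- evolve(db, st, cfg)
    for (sol in res$solutions) {
      expect_true(sol$feasible)
      expect_lte(sol$energy_kcal, st$available_kcal + 1e-9)
      mac <- meal_macros(sol$meal)
      expect_lte(mac[["carbohydrate"]], st$carb_deficit_g + 1e-9)
      expect_lte(mac[["protein"]], st$protein_deficit_g + 1e-9)
      expect_lte(mac[["fat"]], st$fat_deficit_g + 1e-9)
      if (!is.null(st$gi_limit)) expect_true(gi_within_limit(sol$meal, st$gi_limit))
      if (!is.null(st$cholesterol_limit_mg)) {
        expect_lt(meal_cholesterol(sol$meal), st$cholesterol_limit_mg)
      }
    }
  }
})

test_that("the compiled evaluation path agrees with the public one", {
  db <- generate_synthetic_db(10, seed = 13)
  st <- deficit_state(1200, 220, 90, 60, gi_limit = 55)
  cfg <- ga_config(population_size = 8, generations = 10, patience = 4, seed = 3)
  res <- evolve(db, st, cfg)
  # the archived best was scored internally; re-scoring its meal through the
  # public arithmetic must give the same slack and feasibility
  if (!is.null(res$best)) {
    ev <- evaluate(res$best$meal, st)
    expect_equal(ev$objective, res$best$objective, tolerance = 1e-9)
    expect_true(ev$feasible)
    expect_equal(tail(res$log$best_slack[!is.na(res$log$best_slack)], 1),
                 ev$objective, tolerance = 1e-9)
  }
})

test_that("fitness decreases strictly with slack on feasible meals", {
  st <- deficit_state(500, 1000, 1000, 1000)
  slacks <- c()
  fits <- c()
  for (carb in c(120, 100, 80, 60)) {
    m <- meal(meal_component(plain_food(paste0("c", carb), carb = carb,
                                        protein = 0, fat = 0)))
    ev <- evaluate(m, st)
    expect_true(ev$feasible)
    slacks <- c(slacks, ev$objective)
    fits <- c(fits, ev$fitness)
  }
  expect_true(all(diff(slacks) > 0))
  expect_true(all(diff(fits) < 0))
})

test_that("the GA never reports a better slack than exhaustive enumeration", {
  set.seed(314)
  for (r in 1:15) {
    db <- generate_synthetic_db(6, seed = 500 + r)
    st <- deficit_state(runif(1, 300, 1800), runif(1, 60, 250),
                        runif(1, 20, 120), runif(1, 15, 90))
    opt <- oracle_best_slack(db, st)
    res <- evolve(db, st,
                  ga_config(population_size = 20, generations = 60, patience = 15,
                            max_servings = 2, max_additional_components = 2,
                            mutation_prob = 0.05, seed = r))
    ga <- if (is.null(res$best)) Inf else res$best$objective
    expect_gte(ga, opt - 1e-9)
  }
})
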