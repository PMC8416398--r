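FLOAT_TOL <- 1e-9

#' Genetic-algorithm configuration
#'
#' Defaults follow the adopted configuration: population 30, 500 generations,
#' crossover probability 0.65, mutation probability 0.01, with tournament
#' selection of size 3. `patience` controls early stopping: the run ends once
#' the best feasible slack has not improved for that many consecutive
#' generations (the generation cap always applies).
#'
#' @param population_size Number of chromosomes per generation (>= 2).
#' @param generations Maximum number of generations (>= 1).
#' @param crossover_prob,mutation_prob Probabilities in \[0, 1\].
#' @param tournament_size Chromosomes drawn per tournament (>= 1).
#' @param max_additional_components Maximum number of components beyond the
#'   base food in a candidate meal.
#' @param max_servings Maximum serving count `N` per component.
#' @param seed Optional integer seed; fixes the whole run.
#' @param selection_mode `"tournament"` (default) or `"roulette"`
#'   (fitness-proportional).
#' @param patience Generations without improvement before early stop.
#' @param penalty Fitness penalty constant added for infeasible chromosomes.
#' @param top_k How many distinct feasible solutions to retain in the archive.
#' @param mutate_foods When `TRUE` (default) a mutation hit replaces the
#'   component at that gene position with a freshly drawn food, serving
#'   measure and count - the mechanism that supplies new food material during
#'   the search. When `FALSE` mutation only re-draws serving measures and
#'   counts, leaving the food composition of every chromosome fixed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 30L, generations = 500L,
                      crossover_prob = 0.65, mutation_prob = 0.01,
                      tournament_size = 3L, max_additional_components = 5L,
                      max_servings = 3L, seed = NULL,
                      selection_mode = c("tournament", "roulette"),
                      patience = 50L, penalty = 1e4, top_k = 1L,
                      mutate_foods = TRUE) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(population_size >= 2, generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            tournament_size >= 1, max_additional_components >= 0,
            max_servings >= 1, patience >= 1, penalty >= 0, top_k >= 1)
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         crossover_prob = crossover_prob, mutation_prob = mutation_prob,
         tournament_size = as.integer(tournament_size),
         max_additional_components = as.integer(max_additional_components),
         max_servings = as.integer(max_servings),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         selection_mode = selection_mode, patience = as.integer(patience),
         penalty = penalty, top_k = as.integer(top_k),
         mutate_foods = isTRUE(mutate_foods)),
    class = "ga_config"
  )
}

#' Read a GA configuration from YAML or JSON
#'
#' Fields absent from the file keep their [ga_config()] defaults.
#'
#' @param path A `.yaml`/`.yml` or `.json` file of config fields.
#' @return A `ga_config`.
#' @export
read_ga_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  fields <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
            else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
            else stop("unsupported config format: .", ext, call. = FALSE)
  do.call(ga_config, fields[intersect(names(fields), names(formals(ga_config)))])
}

#' Remaining-budget state the predictor optimizes against
#'
#' @param available_kcal Remaining calorie budget `D` (>= 0).
#' @param carb_deficit_g,protein_deficit_g,fat_deficit_g Remaining gram
#'   budgets per macronutrient (>= 0).
#' @param gi_limit Optional per-item glycemic-index bound (55 for diabetic
#'   users); `NULL` disables the constraint.
#' @param cholesterol_limit_mg Optional strict upper bound on total meal
#'   cholesterol (300 mg for high-cholesterol users); `NULL` disables it.
#' @return A list of class `deficit_state`.
#' @export
deficit_state <- function(available_kcal, carb_deficit_g, protein_deficit_g,
                          fat_deficit_g, gi_limit = NULL,
                          cholesterol_limit_mg = NULL) {
  stopifnot(available_kcal >= 0, carb_deficit_g >= 0, protein_deficit_g >= 0,
            fat_deficit_g >= 0)
  if (!is.null(gi_limit)) stopifnot(gi_limit > 0)
  if (!is.null(cholesterol_limit_mg)) stopifnot(cholesterol_limit_mg > 0)
  structure(
    list(available_kcal = available_kcal, carb_deficit_g = carb_deficit_g,
         protein_deficit_g = protein_deficit_g, fat_deficit_g = fat_deficit_g,
         gi_limit = gi_limit, cholesterol_limit_mg = cholesterol_limit_mg),
    class = "deficit_state"
  )
}

# Compiled numeric view of a food database: one row per (food, measure) pair
# with precomputed per-serving energy/macros/cholesterol. The GA inner loop
# works on integer chromosomes indexing this table.
meal_space <- function(db) {
  db <- validate_food_db(db)
  n_meas <- vapply(db$measures, nrow, integer(1))
  food <- rep.int(seq_len(nrow(db)), n_meas)
  mm <- do.call(rbind, db$measures)
  f <- mm$weight_g / 100
  atwater <- 4 * db$protein_g_100g[food] + 4 * db$carb_g_100g[food] +
    9 * db$fat_g_100g[food]
  unit_kcal <- ifelse(is.na(mm$kcal), f * atwater, mm$kcal)
  list(
    food = food,
    label = mm$label,
    weight_g = mm$weight_g,
    unit_kcal = unit_kcal,
    unit_carb = f * db$carb_g_100g[food],
    unit_protein = f * db$protein_g_100g[food],
    unit_fat = f * db$fat_g_100g[food],
    unit_chol = f * db$cholesterol_mg_100g[food],
    food_gi = db$glycemic_index,
    food_rows = split(seq_along(food), food),
    n_rows = length(food)
  )
}

random_chrom <- function(space, config) {
  len <- 1L + sample.int(config$max_additional_components + 1L, 1L) - 1L
  list(m = sample.int(space$n_rows, len, replace = TRUE),
       n = sample.int(config$max_servings, len, replace = TRUE))
}

eval_chrom <- function(chrom, space, state, penalty) {
  z <- sum(chrom$n * space$unit_kcal[chrom$m])
  carb <- sum(chrom$n * space$unit_carb[chrom$m])
  protein <- sum(chrom$n * space$unit_protein[chrom$m])
  fat <- sum(chrom$n * space$unit_fat[chrom$m])
  slack <- state$available_kcal - z
  feasible <- slack >= -FLOAT_TOL &&
    carb <= state$carb_deficit_g + FLOAT_TOL &&
    protein <= state$protein_deficit_g + FLOAT_TOL &&
    fat <= state$fat_deficit_g + FLOAT_TOL
  if (feasible && !is.null(state$gi_limit)) {
    feasible <- all(space$food_gi[space$food[chrom$m]] <= state$gi_limit)
  }
  if (feasible && !is.null(state$cholesterol_limit_mg)) {
    feasible <- sum(chrom$n * space$unit_chol[chrom$m]) <
      state$cholesterol_limit_mg
  }
  fitness <- if (feasible) 1 / (1 + slack) else 1 / (1 + abs(slack) + penalty)
  list(z = z, slack = slack, feasible = feasible, fitness = fitness)
}

cross_chroms <- function(c1, c2) {
  list(list(m = c(c1$m[1L], c2$m[-1L]), n = c(c1$n[1L], c2$n[-1L])),
       list(m = c(c2$m[1L], c1$m[-1L]), n = c(c2$n[1L], c1$n[-1L])))
}

mutate_chrom <- function(chrom, space, config) {
  hits <- which(stats::runif(length(chrom$m)) < config$mutation_prob)
  for (i in hits) {
    if (config$mutate_foods) {
      # gene replacement admits entirely new food material at any position
      chrom$m[i] <- sample.int(space$n_rows, 1L)
    } else {
      rows <- space$food_rows[[space$food[chrom$m[i]]]]
      chrom$m[i] <- rows[sample.int(length(rows), 1L)]
    }
    chrom$n[i] <- sample.int(config$max_servings, 1L)
  }
  chrom
}

chrom_to_meal <- function(chrom, space, db) {
  meal(lapply(seq_along(chrom$m), function(i) {
    mrow <- chrom$m[i]
    fi <- space$food[mrow]
    offset <- match(mrow, space$food_rows[[fi]])
    meal_component(db_food(db, db$id[fi]), measure = offset,
                   n_servings = chrom$n[i])
  }))
}

chrom_signature <- function(chrom) {
  o <- order(chrom$m, chrom$n)
  paste(chrom$m[o], chrom$n[o], sep = ":", collapse = ",")
}

#' Evaluate a candidate meal against a deficit state
#'
#' The objective is the slack `f = D - Z` (unused calorie budget). A meal is
#' feasible when the slack is non-negative, its consumed macros fit within the
#' macro deficits componentwise, every item meets the glycemic-index bound
#' when one is active, and total cholesterol is below the limit when one is
#' active. Fitness is `1 / (1 + f)` for feasible meals (in `(0, 1]`, maximal
#' when the meal exactly fills the budget) and `1 / (1 + |f| + penalty)` for
#' infeasible ones.
#'
#' @param meal A [meal()].
#' @param state A [deficit_state()].
#' @param penalty Infeasibility penalty constant (kcal scale).
#' @return A list of class `evaluated_meal` with `meal`, `energy_kcal`,
#'   `objective`, `feasible`, `fitness`.
#' @export
evaluate <- function(meal, state, penalty = 1e4) {
  stopifnot(inherits(meal, "meal"), inherits(state, "deficit_state"))
  z <- meal_energy(meal)
  macros <- meal_macros(meal)
  slack <- state$available_kcal - z
  feasible <- slack >= -FLOAT_TOL &&
    macros[["carbohydrate"]] <= state$carb_deficit_g + FLOAT_TOL &&
    macros[["protein"]] <= state$protein_deficit_g + FLOAT_TOL &&
    macros[["fat"]] <= state$fat_deficit_g + FLOAT_TOL &&
    (is.null(state$gi_limit) || gi_within_limit(meal, state$gi_limit)) &&
    (is.null(state$cholesterol_limit_mg) ||
       meal_cholesterol(meal) < state$cholesterol_limit_mg)
  fitness <- if (feasible) 1 / (1 + slack) else 1 / (1 + abs(slack) + penalty)
  structure(
    list(meal = meal, energy_kcal = z, objective = slack,
         feasible = feasible, fitness = fitness),
    class = "evaluated_meal"
  )
}

#' @export
print.evaluated_meal <- function(x, ...) {
  cat(sprintf("<evaluated_meal> %.2f kcal, slack %.2f, %s, fitness %.4g\n",
              x$energy_kcal, x$objective,
              if (x$feasible) "feasible" else "infeasible", x$fitness))
  invisible(x)
}

#' Random initial population
#'
#' Each chromosome is a random meal: a base food plus up to
#' `max_additional_components` additional foods, each with a serving measure
#' drawn from that food's household measures and a serving count in
#' `[1, max_servings]`. All chromosomes are evaluated against `state`.
#' Deterministic when `config$seed` is set.
#'
#' @param db A `food_db` (non-empty).
#' @param config A [ga_config()].
#' @param state A [deficit_state()].
#' @return A list of `population_size` [evaluate()]d meals.
#' @export
init_population <- function(db, config, state) {
  stopifnot(inherits(config, "ga_config"), inherits(state, "deficit_state"))
  if (!nrow(db)) stop("food database is empty", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  space <- meal_space(db)
  lapply(seq_len(config$population_size), function(i) {
    evaluate(chrom_to_meal(random_chrom(space, config), space, db), state,
             penalty = config$penalty)
  })
}

#' Fitness-proportional selection probabilities
#'
#' `P[j] = fitness[j] / sum(fitness)` over the population.
#'
#' @param population A list of [evaluate()]d meals.
#' @return Numeric vector of probabilities summing to 1.
#' @export
selection_probability <- function(population) {
  stopifnot(length(population) >= 1)
  fit <- vapply(population, `[[`, numeric(1), "fitness")
  fit / sum(fit)
}

#' Tournament selection
#'
#' Draws `tournament_size` distinct chromosomes uniformly and returns the one
#' with the highest fitness; ties are broken by lower meal energy, then by
#' earlier position in the population.
#'
#' @param population A list of [evaluate()]d meals.
#' @param tournament_size Number of entrants; at most the population size.
#' @return The winning `evaluated_meal`.
#' @export
tournament_select <- function(population, tournament_size = 3L) {
  if (tournament_size > length(population)) {
    stop("tournament_size exceeds population size", call. = FALSE)
  }
  idx <- sample.int(length(population), tournament_size)
  fit <- vapply(population[idx], `[[`, numeric(1), "fitness")
  z <- vapply(population[idx], `[[`, numeric(1), "energy_kcal")
  population[[idx[order(-fit, z, idx)[1L]]]]
}

#' Whole-tail single-point crossover
#'
#' With probability `crossover_prob`, the additional-component tails of the
#' two parent meals are exchanged (the base components stay put), so the
#' children are `base1 + tail2` and `base2 + tail1`; otherwise the children
#' are copies of the parents. Either way the multiset of components across
#' the pair is conserved.
#'
#' @param parent1,parent2 [meal()]s with at least one component.
#' @param crossover_prob Probability of performing the swap.
#' @return A list of two meals.
#' @export
crossover_meals <- function(parent1, parent2, crossover_prob = 1) {
  stopifnot(inherits(parent1, "meal"), inherits(parent2, "meal"),
            length(parent1) >= 1, length(parent2) >= 1)
  if (stats::runif(1) < crossover_prob) {
    p1 <- unclass(parent1); p2 <- unclass(parent2)
    list(meal(c(p1[1L], p2[-1L])), meal(c(p2[1L], p1[-1L])))
  } else {
    list(parent1, parent2)
  }
}

#' Chromosome mutation
#'
#' Each component position is independently hit with probability
#' `mutation_prob`. A hit re-draws the component's serving measure and
#' resamples its serving count in `[1, max_servings]`; under the default
#' `config$mutate_foods = TRUE` it also replaces the component's food with a
#' uniform draw from the database, which is how new food material enters the
#' population. With `mutate_foods = FALSE` the food composition is preserved
#' exactly.
#'
#' @param meal A [meal()].
#' @param mutation_prob Per-position mutation probability.
#' @param db The food database the meal was built from.
#' @param config A [ga_config()] (supplies `max_servings`, `mutate_foods`).
#' @return The possibly mutated meal.
#' @export
mutate_meal <- function(meal, mutation_prob, db, config) {
  stopifnot(inherits(meal, "meal"))
  if (!length(meal)) return(meal)
  comps <- unclass(meal)
  hits <- which(stats::runif(length(comps)) < mutation_prob)
  for (i in hits) {
    food <- if (config$mutate_foods) {
      db_food(db, db$id[sample.int(nrow(db), 1L)])
    } else {
      db_food(db, comps[[i]]$food_id)
    }
    midx <- sample.int(nrow(food$measures), 1L)
    comps[[i]] <- meal_component(food, measure = midx,
                                 n_servings = sample.int(config$max_servings, 1L))
  }
  meal(comps)
}

#' Run the genetic algorithm
#'
#' Evolves meals against a deficit state: tournament (or roulette) selection,
#' whole-tail crossover and serving-size mutation produce a full replacement
#' generation each iteration; an elitist archive outside the breeding
#' population retains the best feasible chromosomes ever seen. The run stops
#' at `config$generations` or earlier once the best feasible slack has been
#' stale for `config$patience` generations. An all-infeasible run returns a
#' no-solution marker rather than an error.
#'
#' @param db A `food_db` (non-empty).
#' @param state A [deficit_state()].
#' @param config A [ga_config()].
#' @return A list of class `ga_result`: `best` (an [evaluate()]d meal, or
#'   `NULL` when no feasible meal was found), `solutions` (up to
#'   `config$top_k` distinct feasible meals, best first), `log` (a data.frame
#'   with one row per generation: `generation`, `best_slack`, `mean_fitness`,
#'   `feasible_fraction`), `generations_run`, and `converged_at` (generation
#'   of the last improvement, `NA` if none).
#' @export
evolve <- function(db, state, config = ga_config()) {
  stopifnot(inherits(state, "deficit_state"), inherits(config, "ga_config"))
  if (!nrow(db)) stop("food database is empty", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  empty_log <- data.frame(generation = integer(), best_slack = numeric(),
                          mean_fitness = numeric(), feasible_fraction = numeric())
  if (state$available_kcal <= 0) {
    return(structure(list(best = NULL, solutions = list(), log = empty_log,
                          generations_run = 0L, converged_at = NA_integer_,
                          state = state),
                     class = "ga_result"))
  }
  space <- meal_space(db)
  npop <- config$population_size
  pop <- lapply(seq_len(npop), function(i) random_chrom(space, config))
  evals <- lapply(pop, eval_chrom, space = space, state = state,
                  penalty = config$penalty)

  # elitist archive: up to top_k distinct feasible chromosomes, best first
  archive <- list()
  archive_add <- function(chrom, ev) {
    if (!ev$feasible) return(invisible())
    sig <- chrom_signature(chrom)
    sigs <- vapply(archive, `[[`, character(1), "sig")
    if (sig %in% sigs) return(invisible())
    entry <- list(chrom = chrom, slack = ev$slack, z = ev$z, sig = sig)
    archive[[length(archive) + 1L]] <<- entry
    ord <- order(vapply(archive, `[[`, numeric(1), "slack"),
                 vapply(archive, `[[`, numeric(1), "z"))
    archive <<- archive[ord][seq_len(min(length(archive), config$top_k))]
    invisible()
  }
  for (i in seq_len(npop)) archive_add(pop[[i]], evals[[i]])

  fit <- vapply(evals, `[[`, numeric(1), "fitness")
  zs <- vapply(evals, `[[`, numeric(1), "z")

  pick_parent <- function() {
    if (config$selection_mode == "roulette") {
      sample.int(npop, 1L, prob = fit)
    } else {
      idx <- sample.int(npop, config$tournament_size)
      idx[order(-fit[idx], zs[idx], idx)[1L]]
    }
  }

  best_slack <- if (length(archive)) archive[[1L]]$slack else Inf
  stale <- 0L
  converged_at <- if (length(archive)) 0L else NA_integer_
  log_rows <- vector("list", config$generations)
  gens_run <- 0L

  for (gen in seq_len(config$generations)) {
    children <- vector("list", npop)
    seen <- new.env(parent = emptyenv())
    filled <- 0L
    while (filled < npop) {
      i1 <- pick_parent(); i2 <- pick_parent()
      pair <- if (stats::runif(1) < config$crossover_prob) {
        cross_chroms(pop[[i1]], pop[[i2]])
      } else {
        list(pop[[i1]], pop[[i2]])
      }
      for (child in pair) {
        if (filled >= npop) break
        child <- mutate_chrom(child, space, config)
        # duplicate offspring add no information; replace them with fresh
        # random chromosomes so the generation keeps supplying new material
        sig <- chrom_signature(child)
        if (!is.null(seen[[sig]])) {
          child <- random_chrom(space, config)
          sig <- chrom_signature(child)
        }
        seen[[sig]] <- TRUE
        filled <- filled + 1L
        children[[filled]] <- child
      }
    }
    pop <- children
    evals <- lapply(pop, eval_chrom, space = space, state = state,
                    penalty = config$penalty)
    fit <- vapply(evals, `[[`, numeric(1), "fitness")
    zs <- vapply(evals, `[[`, numeric(1), "z")
    for (i in seq_len(npop)) archive_add(pop[[i]], evals[[i]])

    gens_run <- gen
    new_best <- if (length(archive)) archive[[1L]]$slack else Inf
    log_rows[[gen]] <- data.frame(
      generation = gen,
      best_slack = if (is.finite(new_best)) new_best else NA_real_,
      mean_fitness = mean(fit),
      feasible_fraction = mean(vapply(evals, `[[`, logical(1), "feasible"))
    )
    if (new_best < best_slack - FLOAT_TOL) {
      best_slack <- new_best
      stale <- 0L
      converged_at <- gen
    } else {
      stale <- stale + 1L
    }
    if (stale >= config$patience) break
  }

  log_df <- do.call(rbind, log_rows[seq_len(gens_run)])
  if (is.null(log_df)) log_df <- empty_log
  solutions <- lapply(archive, function(entry) {
    evaluate(chrom_to_meal(entry$chrom, space, db), state,
             penalty = config$penalty)
  })
  structure(
    list(best = if (length(solutions)) solutions[[1L]] else NULL,
         solutions = solutions, log = log_df, generations_run = gens_run,
         converged_at = converged_at, state = state),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  if (is.null(x$best)) {
    cat("<ga_result> no feasible meal found\n")
  } else {
    cat(sprintf("<ga_result> best slack %.2f kcal after %d generation(s) (last improvement at %s)\n",
                x$best$objective, x$generations_run, x$converged_at))
    print(x$best$meal)
  }
  invisible(x)
}

#' Write a GA generation log as CSV
#'
#' @param result A `ga_result` from [evolve()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_ga_log <- function(result, path) {
  stopifnot(inherits(result, "ga_result"))
  utils::write.csv(result$log, path, row.names = FALSE)
  invisible(path)
}
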