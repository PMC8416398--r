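#' Build the deficit state for prediction
#'
#' Collapses the day's ledger and the user's health status into the state the
#' genetic algorithm optimizes against: the available calorie budget is the
#' current deficit floored at zero (an overconsumed day leaves no budget), as
#' are the macro deficits; a per-item glycemic-index bound of 55 is active for
#' any non-none diabetes level, and a 300 mg meal-cholesterol bound for
#' medium or high cholesterol levels.
#'
#' @param profile A [user_profile()].
#' @param ledger The user's [day_ledger()] for the current day.
#' @return A [deficit_state()].
#' @export
build_state <- function(profile, ledger) {
  stopifnot(inherits(profile, "user_profile"), inherits(ledger, "day_ledger"))
  md <- macro_deficits(ledger)
  deficit_state(
    available_kcal = max(0, calorie_deficit(ledger)),
    carb_deficit_g = max(0, md[["carbohydrate"]]),
    protein_deficit_g = max(0, md[["protein"]]),
    fat_deficit_g = max(0, md[["fat"]]),
    gi_limit = if (profile$diabetes != "none") 55 else NULL,
    cholesterol_limit_mg = if (profile$cholesterol %in% c("medium", "high")) 300 else NULL
  )
}

recommendation_rows <- function(m) {
  rows <- lapply(unclass(m), function(comp) {
    single <- meal(list(comp))
    mac <- meal_macros(single)
    data.frame(
      entry = comp$food_name, serving = comp$measure_label,
      n_servings = comp$n_servings,
      kcal = round(meal_energy(single), 2),
      carbohydrate_g = round(mac[["carbohydrate"]], 2),
      protein_g = round(mac[["protein"]], 2),
      fat_g = round(mac[["fat"]], 2),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Predict meals that fill the remaining daily budget
#'
#' Runs the genetic algorithm against [build_state()] and renders the result
#' as a recommendation: per-item rows (serving label, serving count, kcal and
#' macro grams) with group totals, the residual deficits a user would have
#' after eating the recommendation, and notes on the active health
#' constraints. When no feasible meal exists (e.g. zero remaining budget) the
#' recommendation is empty with an explanatory note.
#'
#' @param profile A [user_profile()].
#' @param ledger The day's [day_ledger()].
#' @param db A `food_db`.
#' @param config A [ga_config()]; set `top_k > 1` to get several distinct
#'   feasible meal groups.
#' @return A list of class `meal_recommendation`: `meals` (list of meals),
#'   `tables` (list of per-meal data.frames with a Total row), `totals`,
#'   `residual_deficits`, `notes`, `state`, and the underlying `ga_result`.
#' @export
recommend_meals <- function(profile, ledger, db, config = ga_config()) {
  state <- build_state(profile, ledger)
  result <- evolve(db, state, config)
  notes <- character()
  if (!is.null(state$gi_limit)) {
    notes <- c(notes, sprintf("low glycemic index enforced (per-item GI <= %g)",
                              state$gi_limit))
  }
  if (!is.null(state$cholesterol_limit_mg)) {
    notes <- c(notes, sprintf("meal cholesterol < %g mg enforced",
                              state$cholesterol_limit_mg))
  }
  meals <- lapply(result$solutions, `[[`, "meal")
  tables <- lapply(meals, recommendation_rows)
  totals <- lapply(tables, function(tb) {
    c(kcal = sum(tb$kcal), carbohydrate_g = sum(tb$carbohydrate_g),
      protein_g = sum(tb$protein_g), fat_g = sum(tb$fat_g))
  })
  consumed <- if (length(totals)) totals[[1L]] else
    c(kcal = 0, carbohydrate_g = 0, protein_g = 0, fat_g = 0)
  residual <- c(
    kcal = state$available_kcal - consumed[["kcal"]],
    carbohydrate_g = state$carb_deficit_g - consumed[["carbohydrate_g"]],
    protein_g = state$protein_deficit_g - consumed[["protein_g"]],
    fat_g = state$fat_deficit_g - consumed[["fat_g"]]
  )
  if (!length(meals)) {
    notes <- c(notes, if (state$available_kcal <= 0)
      "no remaining calorie budget for today" else
      "no feasible meal found under the current deficits and constraints")
  }
  structure(
    list(meals = meals, tables = tables, totals = totals,
         residual_deficits = residual, notes = notes, state = state,
         ga_result = result),
    class = "meal_recommendation"
  )
}

#' Flatten a recommendation to a single data.frame
#'
#' One row per recommended item plus a Total row per meal group, mirroring the
#' columns of the text rendering (entry, serving size, number of servings,
#' kcal, carbohydrate/protein/fat grams).
#'
#' @param x A `meal_recommendation`.
#' @param ... Unused.
#' @return A data.frame (zero rows when the recommendation is empty).
#' @export
as.data.frame.meal_recommendation <- function(x, ...) {
  if (!length(x$tables)) {
    return(data.frame(group = integer(), entry = character(),
                      serving = character(), n_servings = integer(),
                      kcal = numeric(), carbohydrate_g = numeric(),
                      protein_g = numeric(), fat_g = numeric()))
  }
  out <- lapply(seq_along(x$tables), function(g) {
    tb <- x$tables[[g]]
    tot <- x$totals[[g]]
    rbind(cbind(group = g, tb),
          data.frame(group = g, entry = "Total", serving = "", n_servings = NA,
                     kcal = tot[["kcal"]], carbohydrate_g = tot[["carbohydrate_g"]],
                     protein_g = tot[["protein_g"]], fat_g = tot[["fat_g"]]))
  })
  do.call(rbind, out)
}

#' @export
print.meal_recommendation <- function(x, ...) {
  cat("<meal_recommendation>\n")
  for (note in x$notes) cat("  note:", note, "\n")
  if (!length(x$tables)) {
    cat("  (no meals to recommend)\n")
    return(invisible(x))
  }
  for (g in seq_along(x$tables)) {
    tb <- x$tables[[g]]
    tot <- x$totals[[g]]
    cat(sprintf("  -- meal option %d --\n", g))
    header <- sprintf("  %-22s %-12s %2s %9s %8s %8s %8s",
                      "Meal entry", "Serving", "N", "kcal", "carb g",
                      "prot g", "fat g")
    cat(header, "\n")
    for (i in seq_len(nrow(tb))) {
      cat(sprintf("  %-22s %-12s %2d %9.2f %8.2f %8.2f %8.2f\n",
                  tb$entry[i], tb$serving[i], tb$n_servings[i], tb$kcal[i],
                  tb$carbohydrate_g[i], tb$protein_g[i], tb$fat_g[i]))
    }
    cat(sprintf("  %-22s %-12s %2s %9.2f %8.2f %8.2f %8.2f\n", "Total", "", "",
                tot[["kcal"]], tot[["carbohydrate_g"]], tot[["protein_g"]],
                tot[["fat_g"]]))
  }
  rd <- x$residual_deficits
  cat(sprintf("  residual after option 1: %.2f kcal | carb %.2f g | protein %.2f g | fat %.2f g\n",
              rd[["kcal"]], rd[["carbohydrate_g"]], rd[["protein_g"]],
              rd[["fat_g"]]))
  invisible(x)
}
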