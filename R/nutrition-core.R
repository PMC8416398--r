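# Atwater general factors (kcal per gram)
KCAL_PER_G <- c(carbohydrate = 4, protein = 4, fat = 9)

#' Serving-weight scale factor
#'
#' Converts a household serving weight in grams into the dimensionless factor
#' applied to per-100 g nutrient data: `f = q / 100`, where `q` is the gram
#' weight of the named serving measure (ladle, teaspoon, slice, ...).
#'
#' @param serving_weight_g Serving weight in grams (non-negative).
#' @return The ratio `serving_weight_g / 100`.
#' @examples
#' scale_factor(100)    # 1
#' scale_factor(285.94) # 2.8594
#' @export
scale_factor <- function(serving_weight_g) {
  if (!is.numeric(serving_weight_g) || anyNA(serving_weight_g)) {
    stop("`serving_weight_g` must be numeric and non-missing", call. = FALSE)
  }
  if (any(serving_weight_g < 0)) {
    stop("`serving_weight_g` must be non-negative", call. = FALSE)
  }
  serving_weight_g / 100
}

#' Construct a food item
#'
#' A food item carries per-100 g nutrient content plus one or more named
#' household serving measures with gram weights. A measure may optionally carry
#' a direct energy value (`kcal`) per serving; when present it is used instead
#' of the Atwater computation, which supports foods recorded at the serving
#' level rather than decomposed per 100 g.
#'
#' @param id Unique identifier within a database.
#' @param name Display name.
#' @param category Food group (e.g. "staple", "fish", "vegetable").
#' @param carb_g_100g,protein_g_100g,fat_g_100g Macronutrients, grams per 100 g.
#' @param glycemic_index Glycemic index on the 0-110 scale.
#' @param cholesterol_mg_100g Cholesterol, mg per 100 g.
#' @param measures A data.frame with columns `label` and `weight_g` (and
#'   optionally `kcal`, a direct per-serving energy), one row per serving
#'   measure. Must be non-empty with positive weights.
#' @return A list of class `food_item`.
#' @export
food_item <- function(id, name, category = "other",
                      carb_g_100g = 0, protein_g_100g = 0, fat_g_100g = 0,
                      glycemic_index = 0, cholesterol_mg_100g = 0,
                      measures = data.frame(label = "100 g", weight_g = 100)) {
  measures <- as.data.frame(measures, stringsAsFactors = FALSE)
  if (is.null(measures$kcal)) measures$kcal <- NA_real_
  stopifnot(is.character(measures$label), is.numeric(measures$weight_g))
  if (nrow(measures) < 1) stop("a food item needs at least one serving measure", call. = FALSE)
  if (any(measures$weight_g <= 0)) stop("serving weights must be positive", call. = FALSE)
  vals <- c(carb_g_100g, protein_g_100g, fat_g_100g, glycemic_index, cholesterol_mg_100g)
  if (anyNA(vals) || any(vals < 0)) {
    stop(sprintf("food '%s': nutrient fields must be non-negative", id), call. = FALSE)
  }
  if (glycemic_index > 110) {
    stop(sprintf("food '%s': glycemic index above 110", id), call. = FALSE)
  }
  structure(
    list(id = as.character(id), name = as.character(name),
         category = as.character(category),
         carb_g_100g = as.numeric(carb_g_100g),
         protein_g_100g = as.numeric(protein_g_100g),
         fat_g_100g = as.numeric(fat_g_100g),
         glycemic_index = as.numeric(glycemic_index),
         cholesterol_mg_100g = as.numeric(cholesterol_mg_100g),
         measures = measures[, c("label", "weight_g", "kcal")]),
    class = "food_item"
  )
}

#' @export
print.food_item <- function(x, ...) {
  cat(sprintf("<food_item> %s (%s, %s)\n", x$id, x$name, x$category))
  cat(sprintf("  per 100 g: carb %.2f g, protein %.2f g, fat %.2f g, GI %g, chol %.1f mg\n",
              x$carb_g_100g, x$protein_g_100g, x$fat_g_100g,
              x$glycemic_index, x$cholesterol_mg_100g))
  for (i in seq_len(nrow(x$measures))) {
    m <- x$measures[i, ]
    cat(sprintf("  measure: %s = %.2f g%s\n", m$label, m$weight_g,
                if (!is.na(m$kcal)) sprintf(" (direct %.2f kcal/serving)", m$kcal) else ""))
  }
  invisible(x)
}

#' Construct a meal component
#'
#' One entry of a meal: a food, a chosen serving measure (the gram weight `q`),
#' and an integer number of servings `N`.
#'
#' @param food A `food_item` (or one row of a food database coerced via
#'   [db_food()]).
#' @param measure Serving measure: a label matching one of the food's measures,
#'   or an integer index into them. Defaults to the first measure.
#' @param n_servings Positive integer number of servings.
#' @return A list of class `meal_component` holding a snapshot of the food's
#'   nutrients, the serving weight and any direct per-serving energy.
#' @export
meal_component <- function(food, measure = 1L, n_servings = 1L) {
  stopifnot(inherits(food, "food_item"))
  n_servings <- as.integer(n_servings)
  if (is.na(n_servings) || n_servings < 1L) {
    stop("`n_servings` must be a positive integer", call. = FALSE)
  }
  if (is.character(measure)) {
    idx <- match(measure, food$measures$label)
    if (is.na(idx)) {
      stop(sprintf("food '%s' has no serving measure '%s'", food$id, measure),
           call. = FALSE)
    }
  } else {
    idx <- as.integer(measure)
    if (is.na(idx) || idx < 1L || idx > nrow(food$measures)) {
      stop(sprintf("measure index out of range for food '%s'", food$id), call. = FALSE)
    }
  }
  m <- food$measures[idx, ]
  structure(
    list(food_id = food$id, food_name = food$name, category = food$category,
         carb_g_100g = food$carb_g_100g, protein_g_100g = food$protein_g_100g,
         fat_g_100g = food$fat_g_100g, glycemic_index = food$glycemic_index,
         cholesterol_mg_100g = food$cholesterol_mg_100g,
         measure_label = m$label, serving_weight_g = m$weight_g,
         kcal_per_serving = m$kcal, n_servings = n_servings),
    class = "meal_component"
  )
}

#' Construct a meal
#'
#' An ordered list of meal components. The first component is the base of the
#' meal; the remainder are additional components (the tail exchanged by the
#' genetic algorithm's crossover). An empty meal is permitted at this layer so
#' that reporting code can represent "nothing consumed".
#'
#' @param ... `meal_component` objects (or a single list of them).
#' @return A list of class `meal`.
#' @export
meal <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && !inherits(comps[[1]], "meal_component") && is.list(comps[[1]])) {
    comps <- comps[[1]]
  }
  ok <- vapply(comps, inherits, logical(1), what = "meal_component")
  if (length(comps) && !all(ok)) stop("all meal elements must be meal_components", call. = FALSE)
  structure(comps, class = "meal")
}

#' @export
c.meal <- function(...) {
  parts <- list(...)
  meal(do.call(c, lapply(parts, unclass)))
}

#' @export
print.meal <- function(x, ...) {
  cat(sprintf("<meal> %d component(s), %.2f kcal\n", length(x), meal_energy(x)))
  for (comp in x) {
    cat(sprintf("  %s: %s x%d (%.2f g) -> %.2f kcal\n",
                comp$food_name, comp$measure_label, comp$n_servings,
                comp$serving_weight_g, component_energy(comp)))
  }
  invisible(x)
}

#' Energy of a single meal component
#'
#' Atwater general-factor energy `N * (q/100) * (4p + 4c + 9h)` kcal, where
#' `p`, `c`, `h` are the per-100 g protein, carbohydrate and fat of the food,
#' `q` the serving weight and `N` the number of servings. When the chosen
#' serving measure carries a direct per-serving energy record, that value times
#' `N` is returned instead.
#'
#' @param component A `meal_component`.
#' @return Energy in kilocalories (non-negative, unrounded).
#' @export
component_energy <- function(component) {
  stopifnot(inherits(component, "meal_component"))
  if (!is.na(component$kcal_per_serving)) {
    return(component$n_servings * component$kcal_per_serving)
  }
  atwater <- KCAL_PER_G[["protein"]] * component$protein_g_100g +
    KCAL_PER_G[["carbohydrate"]] * component$carb_g_100g +
    KCAL_PER_G[["fat"]] * component$fat_g_100g
  component$n_servings * scale_factor(component$serving_weight_g) * atwater
}

#' Total energy of a meal
#'
#' Sum of [component_energy()] over all components; additive over
#' concatenation of meals.
#'
#' @param meal A `meal`.
#' @return Energy in kilocalories.
#' @export
meal_energy <- function(meal) {
  stopifnot(inherits(meal, "meal"))
  if (!length(meal)) return(0)
  sum(vapply(meal, component_energy, numeric(1)))
}

#' Macronutrients actually consumed in a meal
#'
#' Each per-100 g macro is scaled by `N * q/100` so the result is in grams
#' consumed, commensurable with gram-denominated daily requirements.
#'
#' @param meal A `meal`.
#' @return Named numeric vector `c(carbohydrate, protein, fat)` in grams.
#' @export
meal_macros <- function(meal) {
  stopifnot(inherits(meal, "meal"))
  out <- c(carbohydrate = 0, protein = 0, fat = 0)
  for (comp in meal) {
    sc <- comp$n_servings * scale_factor(comp$serving_weight_g)
    out <- out + sc * c(comp$carb_g_100g, comp$protein_g_100g, comp$fat_g_100g)
  }
  out
}

#' Cholesterol content of a meal
#'
#' @param meal A `meal`.
#' @return Total cholesterol in milligrams: `sum(N * q/100 * mg_per_100g)`.
#' @export
meal_cholesterol <- function(meal) {
  stopifnot(inherits(meal, "meal"))
  if (!length(meal)) return(0)
  sum(vapply(meal, function(comp) {
    comp$n_servings * scale_factor(comp$serving_weight_g) * comp$cholesterol_mg_100g
  }, numeric(1)))
}

#' Per-item glycemic-index bound
#'
#' TRUE iff every component's glycemic index lies in `[0, limit]`. The bound is
#' per item: a single high-GI food makes the whole meal fail, matching the
#' low-GI rule applied for diabetic users (conventionally `limit = 55`).
#'
#' @param meal A `meal`.
#' @param limit Non-negative upper bound on the glycemic index.
#' @return Logical scalar.
#' @export
gi_within_limit <- function(meal, limit) {
  stopifnot(inherits(meal, "meal"), is.numeric(limit), limit >= 0)
  if (!length(meal)) return(TRUE)
  all(vapply(meal, function(comp) {
    comp$glycemic_index >= 0 && comp$glycemic_index <= limit
  }, logical(1)))
}
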