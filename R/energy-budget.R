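ACTIVITY_LEVELS <- c("extremely_inactive", "sedentary", "moderately_active",
                     "vigorously_active", "extremely_active")
HEALTH_LEVELS <- c("none", "low", "medium", "high")

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Construct a user profile
#'
#' Anthropometrics, WHO activity level and ordered health-status flags. The
#' hypertension and sugar-level fields are recorded for completeness but drive
#' no constraint.
#'
#' @param age_years Age in years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param height_cm Height in centimeters (> 0).
#' @param weight_kg Weight in kilograms (> 0).
#' @param activity_level One of `"extremely_inactive"` (little to no
#'   exercise), `"sedentary"`, `"moderately_active"`, `"vigorously_active"`,
#'   `"extremely_active"`.
#' @param diabetes,cholesterol,hypertension,sugar Ordered levels among
#'   `"none"`, `"low"`, `"medium"`, `"high"`.
#' @return A list of class `user_profile`.
#' @export
user_profile <- function(age_years, sex, height_cm, weight_kg,
                         activity_level = "extremely_inactive",
                         diabetes = "none", cholesterol = "none",
                         hypertension = "none", sugar = "none") {
  sex <- match.arg(sex, c("male", "female"))
  activity_level <- match.arg(activity_level, ACTIVITY_LEVELS)
  for (lv in c(diabetes, cholesterol, hypertension, sugar)) {
    if (!lv %in% HEALTH_LEVELS) {
      stop("health levels must be one of: ", paste(HEALTH_LEVELS, collapse = ", "),
           call. = FALSE)
    }
  }
  stopifnot(age_years > 0, height_cm > 0, weight_kg > 0)
  structure(
    list(age_years = age_years, sex = sex, height_cm = height_cm,
         weight_kg = weight_kg, activity_level = activity_level,
         diabetes = diabetes, cholesterol = cholesterol,
         hypertension = hypertension, sugar = sugar),
    class = "user_profile"
  )
}

#' @export
print.user_profile <- function(x, ...) {
  cat(sprintf("<user_profile> %s, %g y, %.1f cm, %.1f kg, %s\n",
              x$sex, x$age_years, x$height_cm, x$weight_kg, x$activity_level))
  cat(sprintf("  diabetes: %s | cholesterol: %s | hypertension: %s\n",
              x$diabetes, x$cholesterol, x$hypertension))
  invisible(x)
}

#' Basal metabolic rate (Mifflin-St Jeor)
#'
#' `BMR = 10 W + 6.25 H - 5 a + s` kcal/day, with weight `W` in kg, height `H`
#' in cm, age `a` in years and the sex constant `s = +5` for males, `-161` for
#' females.
#'
#' @param profile A [user_profile()].
#' @return Kilocalories per day.
#' @export
bmr <- function(profile) {
  stopifnot(inherits(profile, "user_profile"))
  s <- if (profile$sex == "male") 5 else -161
  10 * profile$weight_kg + 6.25 * profile$height_cm - 5 * profile$age_years + s
}

#' Physical activity level multipliers
#'
#' The multiplier applied to BMR per WHO activity category. These are the
#' conventional PAL values; they can be overridden in [daily_requirement()].
#'
#' @return Named numeric vector keyed by activity level.
#' @export
pal_multipliers <- function() {
  c(extremely_inactive = 1.2, sedentary = 1.375, moderately_active = 1.55,
    vigorously_active = 1.725, extremely_active = 1.9)
}

#' Daily calorie and macronutrient requirement
#'
#' `Q = round(PAL * BMR)` kcal (half-up to the nearest kcal), split into gram
#' targets: carbohydrate `0.50 Q / 4`, protein `0.20 Q / 4`, fat `0.30 Q / 9`
#' (each rounded to 2 decimals). The split satisfies the Atwater closure
#' `4C + 4P + 9F = Q` within rounding.
#'
#' @param profile A [user_profile()].
#' @param pal Named PAL multipliers; defaults to [pal_multipliers()].
#' @param macro_split Fractions of energy from carbohydrate/protein/fat;
#'   must sum to 1.
#' @return A list of class `daily_requirement` with elements `calories_kcal`,
#'   `carbohydrate_g`, `protein_g`, `fat_g`.
#' @export
daily_requirement <- function(profile, pal = pal_multipliers(),
                              macro_split = c(carbohydrate = 0.50,
                                              protein = 0.20, fat = 0.30)) {
  stopifnot(inherits(profile, "user_profile"))
  if (!profile$activity_level %in% names(pal)) {
    stop("no PAL multiplier configured for activity level '",
         profile$activity_level, "'", call. = FALSE)
  }
  if (abs(sum(macro_split) - 1) > 1e-9) {
    stop("macro_split fractions must sum to 1", call. = FALSE)
  }
  q <- round_half_up(pal[[profile$activity_level]] * bmr(profile))
  structure(
    list(calories_kcal = q,
         carbohydrate_g = round_half_up(macro_split[["carbohydrate"]] * q / 4, 2),
         protein_g = round_half_up(macro_split[["protein"]] * q / 4, 2),
         fat_g = round_half_up(macro_split[["fat"]] * q / 9, 2)),
    class = "daily_requirement"
  )
}

#' @export
print.daily_requirement <- function(x, ...) {
  cat(sprintf("<daily_requirement> %g kcal | carb %.2f g | protein %.2f g | fat %.2f g\n",
              x$calories_kcal, x$carbohydrate_g, x$protein_g, x$fat_g))
  invisible(x)
}

#' Exercise energy expenditure
#'
#' `E = coefficient * MET * weight_kg * duration_min` kcal. The default
#' coefficient is 0.175; the conventional MET formula uses 0.0175
#' kcal kg^-1 min^-1, a factor of ten smaller, so the coefficient is exposed
#' as a parameter for users who prefer the conventional scale.
#'
#' @param met Metabolic equivalent of the exercise (dimensionless, > 0).
#' @param weight_kg Body weight in kilograms.
#' @param duration_min Duration in minutes.
#' @param coefficient Scale coefficient, default 0.175.
#' @return Kilocalories expended.
#' @export
exercise_energy <- function(met, weight_kg, duration_min, coefficient = 0.175) {
  stopifnot(met >= 0, weight_kg >= 0, duration_min >= 0, coefficient >= 0)
  coefficient * met * weight_kg * duration_min
}

#' Open a day ledger
#'
#' One ledger per calendar date. It records meals and exercises with
#' timestamps and exposes the running calorie deficit
#' `d = Q + sum(E) - sum(Z)` and macro deficits (requirement minus consumed).
#' Deficits may go negative (overconsumption is recorded, not rejected); they
#' are never carried across dates - see [end_of_day_reset()].
#'
#' @param profile A [user_profile()].
#' @param date A `Date` (or string coercible to one).
#' @param requirement A [daily_requirement()]; recomputed from the profile by
#'   default.
#' @return A list of class `day_ledger`.
#' @export
day_ledger <- function(profile, date = Sys.Date(),
                       requirement = daily_requirement(profile)) {
  stopifnot(inherits(profile, "user_profile"),
            inherits(requirement, "daily_requirement"))
  structure(
    list(date = as.Date(date), profile = profile, requirement = requirement,
         meal_entries = list(), exercise_entries = list()),
    class = "day_ledger"
  )
}

ledger_check_timestamp <- function(ledger, timestamp) {
  ts <- as.POSIXct(timestamp, tz = "UTC")
  if (as.Date(ts, tz = "UTC") != ledger$date) {
    stop(sprintf("timestamp %s falls outside ledger date %s",
                 format(ts), format(ledger$date)), call. = FALSE)
  }
  ts
}

#' Log a meal into a day ledger
#'
#' Appends the meal with its energy and consumed macros; the calorie deficit
#' decreases by the meal energy and the macro deficits by the consumed grams.
#'
#' @param ledger A [day_ledger()].
#' @param meal A [meal()].
#' @param timestamp Time of consumption; must fall on the ledger's date.
#' @return The updated ledger.
#' @export
log_meal <- function(ledger, meal, timestamp = paste(ledger$date, "12:00:00")) {
  stopifnot(inherits(ledger, "day_ledger"), inherits(meal, "meal"))
  ts <- ledger_check_timestamp(ledger, timestamp)
  entry <- list(timestamp = ts, meal = meal,
                energy_kcal = meal_energy(meal), macros = meal_macros(meal))
  ledger$meal_entries <- c(ledger$meal_entries, list(entry))
  ledger
}

#' Log an exercise into a day ledger
#'
#' The expended energy `E = coefficient * MET * W * t` (with the profile's
#' weight) is added to the day's calorie deficit.
#'
#' @param ledger A [day_ledger()].
#' @param met Metabolic equivalent of the activity.
#' @param duration_min Duration in minutes.
#' @param timestamp Time of the activity; must fall on the ledger's date.
#' @param coefficient Passed to [exercise_energy()].
#' @return The updated ledger.
#' @export
log_exercise <- function(ledger, met, duration_min,
                         timestamp = paste(ledger$date, "12:00:00"),
                         coefficient = 0.175) {
  stopifnot(inherits(ledger, "day_ledger"), met > 0, duration_min >= 0)
  ts <- ledger_check_timestamp(ledger, timestamp)
  entry <- list(timestamp = ts, met = met, duration_min = duration_min,
                energy_kcal = exercise_energy(met, ledger$profile$weight_kg,
                                              duration_min, coefficient))
  ledger$exercise_entries <- c(ledger$exercise_entries, list(entry))
  ledger
}

#' Total energy consumed on the ledger's date
#' @param ledger A [day_ledger()].
#' @return Kilocalories.
#' @export
intake_kcal <- function(ledger) {
  if (!length(ledger$meal_entries)) return(0)
  sum(vapply(ledger$meal_entries, `[[`, numeric(1), "energy_kcal"))
}

#' Total exercise energy expended on the ledger's date
#' @param ledger A [day_ledger()].
#' @return Kilocalories.
#' @export
expended_kcal <- function(ledger) {
  if (!length(ledger$exercise_entries)) return(0)
  sum(vapply(ledger$exercise_entries, `[[`, numeric(1), "energy_kcal"))
}

#' Running calorie deficit
#'
#' Telescoped deficit recurrence: `d = Q + sum(E) - sum(Z)`. Negative values
#' indicate overconsumption.
#'
#' @param ledger A [day_ledger()].
#' @return Kilocalories still available for the day.
#' @export
calorie_deficit <- function(ledger) {
  ledger$requirement$calories_kcal + expended_kcal(ledger) - intake_kcal(ledger)
}

#' Running macronutrient deficits
#'
#' Requirement gram targets minus grams consumed so far.
#'
#' @param ledger A [day_ledger()].
#' @return Named numeric vector `c(carbohydrate, protein, fat)` in grams.
#' @export
macro_deficits <- function(ledger) {
  consumed <- c(carbohydrate = 0, protein = 0, fat = 0)
  for (e in ledger$meal_entries) consumed <- consumed + e$macros
  c(carbohydrate = ledger$requirement$carbohydrate_g,
    protein = ledger$requirement$protein_g,
    fat = ledger$requirement$fat_g) - consumed
}

#' @export
print.day_ledger <- function(x, ...) {
  md <- macro_deficits(x)
  cat(sprintf("<day_ledger> %s: %d meal(s), %d exercise(s)\n", format(x$date),
              length(x$meal_entries), length(x$exercise_entries)))
  cat(sprintf("  consumed %.2f kcal of %g; expended %.2f kcal\n",
              intake_kcal(x), x$requirement$calories_kcal, expended_kcal(x)))
  cat(sprintf("  deficits: %.2f kcal | carb %.2f g | protein %.2f g | fat %.2f g\n",
              calorie_deficit(x), md[["carbohydrate"]], md[["protein"]], md[["fat"]]))
  invisible(x)
}

#' End-of-day reset
#'
#' Any excess or residual energy at the end of the day is nullified: the new
#' day starts a fresh ledger whose deficits equal the (re-computed) daily
#' requirement, with no carryover. Pass an updated profile (e.g. new weight)
#' to have the requirement reflect it.
#'
#' @param ledger The ledger being closed.
#' @param next_date The new date; must be strictly after the ledger's date.
#' @param profile Profile for the new day; defaults to the ledger's.
#' @return A fresh [day_ledger()] for `next_date`.
#' @export
end_of_day_reset <- function(ledger, next_date, profile = ledger$profile) {
  stopifnot(inherits(ledger, "day_ledger"))
  next_date <- as.Date(next_date)
  if (next_date <= ledger$date) {
    stop("next_date must be strictly after the ledger date", call. = FALSE)
  }
  day_ledger(profile, next_date, daily_requirement(profile))
}

# --- serialization: JSON-lines ledger, YAML/JSON profile -------------------

component_to_list <- function(comp) unclass(comp)

component_from_list <- function(x) {
  x$n_servings <- as.integer(x$n_servings)
  if (is.null(x$kcal_per_serving) || length(x$kcal_per_serving) == 0) {
    x$kcal_per_serving <- NA_real_
  }
  structure(x, class = "meal_component")
}

#' Write a day ledger as JSON lines
#'
#' One JSON object per line: a header carrying date, profile and requirement,
#' then one line per meal or exercise entry in timestamp order of logging.
#'
#' @param ledger A [day_ledger()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "day_ledger"))
  jline <- function(x) as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                     na = "null", digits = NA))
  lines <- jline(list(kind = "ledger", date = format(ledger$date),
                      profile = unclass(ledger$profile),
                      requirement = unclass(ledger$requirement)))
  for (e in ledger$meal_entries) {
    lines <- c(lines, jline(list(
      kind = "meal", timestamp = format(e$timestamp, "%Y-%m-%d %H:%M:%S"),
      components = lapply(unclass(e$meal), component_to_list))))
  }
  for (e in ledger$exercise_entries) {
    lines <- c(lines, jline(list(
      kind = "exercise", timestamp = format(e$timestamp, "%Y-%m-%d %H:%M:%S"),
      met = e$met, duration_min = e$duration_min)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a day ledger from JSON lines
#'
#' @param path File written by [write_ledger()].
#' @return A [day_ledger()] with all entries replayed (energies recomputed).
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) stop("no such ledger file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("empty ledger file: ", path, call. = FALSE)
  head_rec <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  if (!identical(head_rec$kind, "ledger")) {
    stop("malformed ledger file: first line must be the ledger header", call. = FALSE)
  }
  prof <- do.call(user_profile, head_rec$profile)
  req <- structure(head_rec$requirement, class = "daily_requirement")
  ledger <- day_ledger(prof, head_rec$date, req)
  for (line in lines[-1]) {
    rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    if (identical(rec$kind, "meal")) {
      m <- meal(lapply(rec$components, component_from_list))
      ledger <- log_meal(ledger, m, rec$timestamp)
    } else if (identical(rec$kind, "exercise")) {
      ledger <- log_exercise(ledger, rec$met, rec$duration_min, rec$timestamp)
    } else {
      stop("malformed ledger entry of kind '", rec$kind, "'", call. = FALSE)
    }
  }
  ledger
}

#' Write a user profile to YAML (or JSON)
#' @param profile A [user_profile()].
#' @param path Destination `.yaml`/`.yml` or `.json` file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "user_profile"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(unclass(profile), path)
  } else if (ext == "json") {
    jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported profile format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a user profile from YAML or JSON
#' @param path File written by [write_profile()] (or hand-edited).
#' @return A validated [user_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such profile file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  fields <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported profile format: .", ext, call. = FALSE)
  }
  do.call(user_profile, fields)
}
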