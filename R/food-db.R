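DB_COLUMNS <- c("id", "name", "category", "carb_g_100g", "protein_g_100g",
                "fat_g_100g", "glycemic_index", "cholesterol_mg_100g")

#' Assemble a food database from food items
#'
#' @param items A list of [food_item()] objects.
#' @return A data.frame of class `food_db` with one row per food and a
#'   `measures` list-column (each element a data.frame `label`, `weight_g`,
#'   `kcal`).
#' @export
food_db <- function(items) {
  stopifnot(length(items) >= 1, all(vapply(items, inherits, logical(1), "food_item")))
  df <- data.frame(
    id = vapply(items, `[[`, character(1), "id"),
    name = vapply(items, `[[`, character(1), "name"),
    category = vapply(items, `[[`, character(1), "category"),
    carb_g_100g = vapply(items, `[[`, numeric(1), "carb_g_100g"),
    protein_g_100g = vapply(items, `[[`, numeric(1), "protein_g_100g"),
    fat_g_100g = vapply(items, `[[`, numeric(1), "fat_g_100g"),
    glycemic_index = vapply(items, `[[`, numeric(1), "glycemic_index"),
    cholesterol_mg_100g = vapply(items, `[[`, numeric(1), "cholesterol_mg_100g"),
    stringsAsFactors = FALSE
  )
  df$measures <- lapply(items, `[[`, "measures")
  class(df) <- c("food_db", "data.frame")
  validate_food_db(df)
}

#' Validate a food database
#'
#' Enforces the schema invariants: unique ids, non-negative nutrient values,
#' glycemic index at most 110, and at least one serving measure with positive
#' weight per food. Errors name the offending row.
#'
#' @param db A `food_db`.
#' @return The database, invisibly unchanged, for chaining.
#' @export
validate_food_db <- function(db) {
  stopifnot(inherits(db, "data.frame"))
  missing_cols <- setdiff(c(DB_COLUMNS, "measures"), names(db))
  if (length(missing_cols)) {
    stop("food database is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dup <- db$id[duplicated(db$id)]
  if (length(dup)) {
    stop("duplicate food ids: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(DB_COLUMNS, c("id", "name", "category"))
  for (i in seq_len(nrow(db))) {
    vals <- unlist(db[i, num_cols])
    if (anyNA(vals) || any(vals < 0)) {
      stop(sprintf("row %d (food '%s'): nutrient fields must be non-negative and non-missing",
                   i, db$id[i]), call. = FALSE)
    }
    if (db$glycemic_index[i] > 110) {
      stop(sprintf("row %d (food '%s'): glycemic index above 110", i, db$id[i]),
           call. = FALSE)
    }
    m <- db$measures[[i]]
    if (!is.data.frame(m) || nrow(m) < 1 || any(m$weight_g <= 0)) {
      stop(sprintf("row %d (food '%s'): needs at least one serving measure with positive weight",
                   i, db$id[i]), call. = FALSE)
    }
  }
  if (!inherits(db, "food_db")) class(db) <- c("food_db", class(db))
  db
}

# Coerce a deserialized measures record (list or data.frame, possibly with a
# missing or all-null kcal column) into the canonical data.frame form.
normalize_measures <- function(m) {
  as_num <- function(x, len) {
    if (is.null(x)) return(rep(NA_real_, len))
    if (is.list(x)) {
      return(vapply(x, function(v) {
        if (is.null(v) || !length(v)) NA_real_ else as.numeric(v)
      }, numeric(1)))
    }
    suppressWarnings(as.numeric(x))
  }
  label <- as.character(unlist(m$label))
  data.frame(label = label,
             weight_g = as_num(m$weight_g, length(label)),
             kcal = as_num(m$kcal, length(label)),
             stringsAsFactors = FALSE)
}

#' Extract one food from a database as a food_item
#'
#' @param db A `food_db`.
#' @param id A food id (or, with `fuzzy = TRUE` on failure, an error listing
#'   nearest matches by name/id).
#' @param fuzzy Whether to suggest close matches in the error message.
#' @return A `food_item`.
#' @export
db_food <- function(db, id, fuzzy = TRUE) {
  i <- match(id, db$id)
  if (is.na(i)) {
    msg <- sprintf("no food with id '%s'", id)
    if (fuzzy) {
      near <- unique(c(agrep(id, db$id, max.distance = 0.3, value = TRUE),
                       db$id[agrep(id, db$name, max.distance = 0.3)]))
      if (length(near)) msg <- paste0(msg, "; nearest matches: ", paste(near, collapse = ", "))
    }
    stop(msg, call. = FALSE)
  }
  food_item(db$id[i], db$name[i], db$category[i],
            db$carb_g_100g[i], db$protein_g_100g[i], db$fat_g_100g[i],
            db$glycemic_index[i], db$cholesterol_mg_100g[i],
            db$measures[[i]])
}

#' @export
print.food_db <- function(x, ...) {
  cat(sprintf("<food_db> %d foods across %d categories\n",
              nrow(x), length(unique(x$category))))
  print.data.frame(utils::head(x[, DB_COLUMNS], 10))
  if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Read a food database from CSV or JSON
#'
#' CSV files carry serving measures in a JSON-encoded `measures_json` column;
#' JSON files nest them naturally. The loaded database is validated: duplicate
#' ids, missing columns or negative nutrient values are rejected with the row
#' named.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A validated `food_db`.
#' @export
read_food_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (is.null(raw$measures_json)) {
      stop("food database CSV is missing the measures_json column", call. = FALSE)
    }
    raw$measures <- lapply(raw$measures_json, function(x) {
      normalize_measures(jsonlite::fromJSON(x))
    })
    raw$measures_json <- NULL
  } else if (ext == "json") {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    chr <- function(field) vapply(recs, function(r) as.character(r[[field]]), character(1))
    num <- function(field) vapply(recs, function(r) as.numeric(r[[field]]), numeric(1))
    raw <- data.frame(id = chr("id"), name = chr("name"), category = chr("category"),
                      carb_g_100g = num("carb_g_100g"),
                      protein_g_100g = num("protein_g_100g"),
                      fat_g_100g = num("fat_g_100g"),
                      glycemic_index = num("glycemic_index"),
                      cholesterol_mg_100g = num("cholesterol_mg_100g"),
                      stringsAsFactors = FALSE)
    raw$measures <- lapply(recs, function(r) normalize_measures(r$measures))
  } else {
    stop("unsupported food database format: .", ext, call. = FALSE)
  }
  raw$id <- as.character(raw$id)
  validate_food_db(raw)
}

#' Write a food database to CSV or JSON
#'
#' @param db A `food_db`.
#' @param path Destination `.csv` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_food_db <- function(db, path) {
  db <- validate_food_db(db)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    flat <- as.data.frame(db[, DB_COLUMNS], stringsAsFactors = FALSE)
    flat$measures_json <- vapply(db$measures, function(m) {
      as.character(jsonlite::toJSON(m, dataframe = "columns", na = "null", digits = NA))
    }, character(1))
    utils::write.csv(flat, path, row.names = FALSE)
  } else if (ext == "json") {
    recs <- lapply(seq_len(nrow(db)), function(i) {
      rec <- as.list(db[i, DB_COLUMNS])
      rec$measures <- db$measures[[i]]
      rec
    })
    jsonlite::write_json(recs, path, dataframe = "columns", auto_unbox = TRUE,
                         na = "null", digits = NA, pretty = TRUE)
  } else {
    stop("unsupported food database format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Worked-example fixture database
#'
#' A small database of Ghanaian foods with per-100 g macronutrients, glycemic
#' indices and household serving measures. Foods recorded only at the serving
#' level (e.g. Waakye, Banku) carry a nominal 100 g measure whose per-100 g
#' macros are the per-serving grams, plus a direct per-serving kcal record
#' where the Atwater value would disagree with the recorded energy. Glycemic
#' index and cholesterol values not available for a food are stored as 0 and
#' should be treated as placeholders.
#'
#' @return A `food_db` with 21 foods.
#' @export
builtin_fixture_db <- function() {
  ms <- function(label, weight_g, kcal = NA_real_) {
    data.frame(label = label, weight_g = weight_g, kcal = kcal,
               stringsAsFactors = FALSE)
  }
  items <- list(
    # fully decomposed per-100 g records
    food_item("kenkey-ga", "Kenkey (Ga)", "staple", 25.00, 3.50, 0.60, 35,
              measures = ms("1 ball", 285.94)),
    food_item("okro-soup", "Okro soup", "soup", 4.20, 1.90, 2.80, 30,
              measures = ms("soup ladle", 100)),
    # fat 0.10 g/100 g: the only value under which the Atwater energy (48.10)
    # matches the recorded energy for this food
    food_item("hot-pepper", "Hot pepper", "condiment", 10.70, 1.10, 0.10, 0,
              measures = ms("portion", 100)),
    food_item("tilapia", "Tilapia", "fish", 0.00, 18.80, 2.70, 0,
              cholesterol_mg_100g = 50,
              measures = ms("100 g", 100)),
    food_item("palm-nut-soup", "Palm nut soup", "soup", 16.20, 1.80, 46.80, 20,
              measures = ms("soup ladle", 100)),
    # per-serving energies recorded directly: Atwater over the per-100 g macros
    # does not reproduce them for these three foods
    food_item("rice-ball", "Rice ball", "staple", 79.60, 7.20, 0.40, 70,
              measures = ms("1 ball", 222.39, kcal = 2340.43)),
    food_item("rabbit", "Rabbit", "meat", 0.00, 21.60, 21.10, 0,
              cholesterol_mg_100g = 82,
              measures = ms("100 g", 100, kcal = 129.60)),
    food_item("smoked-tuna", "Smoked tuna", "fish", 0.00, 31.80, 31.70, 90,
              cholesterol_mg_100g = 60,
              measures = ms("100 g", 100, kcal = 129.90)),
    # serving-level records (nominal 100 g measure, macros are per serving)
    food_item("waakye", "Waakye", "staple", 54.00, 8.00, 6.00, 0,
              measures = ms("Soup ladle", 100, kcal = 225.00)),
    food_item("salad", "Salad", "vegetable", 1.50, 0.50, 0.00, 0,
              measures = ms("Stew ladle", 100, kcal = 7.50)),
    food_item("spaghetti", "Spaghetti", "staple", 14.00, 3.00, 0.50, 0,
              measures = ms("Stew ladle", 100, kcal = 67.00)),
    # recorded per-entry energy 55.40 for two servings (see vignette note on
    # the total closing at 1017.50)
    food_item("gari", "Gari", "staple", 6.50, 0.00, 0.00, 0,
              measures = ms("Table spoon", 100, kcal = 27.70)),
    food_item("fried-fish", "Fried fish", "fish", 0.00, 15.00, 2.00, 0,
              cholesterol_mg_100g = 55,
              measures = ms("1 whole", 100, kcal = 78.00)),
    food_item("tomato-stew", "Tomato stew", "stew", 0.00, 13.00, 2.00, 0,
              measures = ms("Stew ladle", 100, kcal = 114.60)),
    food_item("egg", "Egg", "protein", 0.00, 6.00, 8.00, 0,
              cholesterol_mg_100g = 186,
              measures = ms("1 egg", 100, kcal = 87.00)),
    food_item("shito", "Shito", "condiment", 0.50, 1.50, 4.00, 0,
              measures = ms("Teaspoon", 100, kcal = 41.75)),
    food_item("banku", "Banku", "staple", 23.80, 2.40, 0.40, 40,
              measures = ms("Small ball", 100, kcal = 334.96)),
    food_item("okro-stew", "Okro stew", "stew", 5.00, 2.80, 11.60, 30,
              measures = ms("100 g", 100)),
    food_item("lamb-mutton", "Lamb/mutton", "meat", 0.00, 16.50, 21.20, 0,
              cholesterol_mg_100g = 97,
              measures = ms("100 g", 100)),
    food_item("apple-juice", "Apple juice", "beverage", 14.50, 0.00, 0.00, 41,
              measures = ms("240 ml", 100, kcal = 139.20)),
    food_item("wheat-bread", "Wheat bread", "staple", 12.90, 2.70, 1.20, 53,
              measures = ms("1 slice", 100, kcal = 50.51))
  )
  food_db(items)
}

SYNTH_CATEGORIES <- list(
  # per-100 g macro ranges (carb, protein, fat), GI range, cholesterol range
  staple    = list(carb = c(20, 85), protein = c(1, 10),  fat = c(0, 5),
                   gi = c(30, 95),  chol = c(0, 0)),
  vegetable = list(carb = c(1, 12),  protein = c(0.5, 4), fat = c(0, 2),
                   gi = c(0, 40),   chol = c(0, 0)),
  legume    = list(carb = c(10, 30), protein = c(5, 12),  fat = c(0.5, 5),
                   gi = c(10, 50),  chol = c(0, 0)),
  fruit     = list(carb = c(5, 25),  protein = c(0.2, 2), fat = c(0, 1),
                   gi = c(20, 75),  chol = c(0, 0)),
  fish      = list(carb = c(0, 1),   protein = c(15, 32), fat = c(1, 15),
                   gi = c(0, 0),    chol = c(30, 90)),
  meat      = list(carb = c(0, 1),   protein = c(14, 28), fat = c(5, 30),
                   gi = c(0, 0),    chol = c(50, 150)),
  dairy     = list(carb = c(3, 10),  protein = c(3, 26),  fat = c(1, 30),
                   gi = c(10, 45),  chol = c(10, 110)),
  beverage  = list(carb = c(2, 15),  protein = c(0, 2),   fat = c(0, 1),
                   gi = c(20, 70),  chol = c(0, 0)),
  condiment = list(carb = c(1, 15),  protein = c(0.5, 5), fat = c(0, 40),
                   gi = c(0, 35),   chol = c(0, 20))
)

MEASURE_LABELS <- c("soup ladle", "stew ladle", "teaspoon", "table spoon",
                    "portion", "slice", "small ball", "cup", "piece", "100 g")

#' Generate a seeded synthetic food database
#'
#' Emulates the shape of a food-composition table joined with household
#' serving measures: foods are drawn from nine categories with
#' category-conditioned macronutrient, glycemic-index and cholesterol ranges,
#' and each food gets 1-3 named serving measures with gram weights in
#' \[5, 400\]. Deterministic for a given seed.
#'
#' @param n Number of foods (at least 1).
#' @param seed Integer seed.
#' @return A validated `food_db` with `n` foods.
#' @export
generate_synthetic_db <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  cats <- sample(names(SYNTH_CATEGORIES), n, replace = TRUE)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    rng <- SYNTH_CATEGORIES[[cats[i]]]
    draw <- function(r) stats::runif(1, r[1], r[2])
    n_meas <- sample(1:3, 1)
    measures <- data.frame(
      label = sample(MEASURE_LABELS, n_meas),
      weight_g = round(stats::runif(n_meas, 5, 400), 2),
      kcal = NA_real_,
      stringsAsFactors = FALSE
    )
    items[[i]] <- food_item(
      id = sprintf("synth-%03d", i),
      name = sprintf("Synthetic %s %03d", cats[i], i),
      category = cats[i],
      carb_g_100g = round(draw(rng$carb), 2),
      protein_g_100g = round(draw(rng$protein), 2),
      fat_g_100g = round(draw(rng$fat), 2),
      glycemic_index = round(draw(rng$gi), 1),
      cholesterol_mg_100g = round(draw(rng$chol), 1),
      measures = measures
    )
  }
  food_db(items)
}
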