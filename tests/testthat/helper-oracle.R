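# Exhaustive-enumeration oracle over all meals expressible in a small food
# database with bounded serving counts and meal length. Independent of the
# package's GA path: per-serving values are derived here directly from the
# database columns and all multisets of (measure, count) genes up to size
# 1 + max_additional are enumerated.

oracle_best_slack <- function(db, state, max_servings = 2L, max_additional = 2L) {
  stopifnot(max_additional <= 2L) # enumeration below covers meals of size <= 3
  nm <- vapply(db$measures, nrow, integer(1))
  food <- rep.int(seq_len(nrow(db)), nm)
  mm <- do.call(rbind, db$measures)
  f <- mm$weight_g / 100
  atw <- 4 * db$protein_g_100g[food] + 4 * db$carb_g_100g[food] +
    9 * db$fat_g_100g[food]
  base <- data.frame(
    kcal = ifelse(is.na(mm$kcal), f * atw, mm$kcal),
    carb = f * db$carb_g_100g[food], prot = f * db$protein_g_100g[food],
    fat = f * db$fat_g_100g[food], chol = f * db$cholesterol_mg_100g[food],
    gi = db$glycemic_index[food]
  )
  genes <- do.call(rbind, lapply(seq_len(max_servings), function(n) {
    g <- base
    g[c("kcal", "carb", "prot", "fat", "chol")] <-
      n * g[c("kcal", "carb", "prot", "fat", "chol")]
    g
  }))
  G <- nrow(genes)
  gl <- if (is.null(state$gi_limit)) Inf else state$gi_limit
  cl <- if (is.null(state$cholesterol_limit_mg)) Inf else state$cholesterol_limit_mg
  gi_ok <- genes$gi <= gl
  best <- Inf
  consider <- function(kcal, carb, prot, fat, chol, ok) {
    feas <- ok & kcal <= state$available_kcal & carb <= state$carb_deficit_g &
      prot <= state$protein_deficit_g & fat <= state$fat_deficit_g & chol < cl
    if (any(feas)) best <<- min(best, min(state$available_kcal - kcal[feas]))
  }
  consider(genes$kcal, genes$carb, genes$prot, genes$fat, genes$chol, gi_ok)
  if (max_additional >= 1L) for (i in 1:G) {
    j <- i:G
    consider(genes$kcal[i] + genes$kcal[j], genes$carb[i] + genes$carb[j],
             genes$prot[i] + genes$prot[j], genes$fat[i] + genes$fat[j],
             genes$chol[i] + genes$chol[j], gi_ok[i] & gi_ok[j])
  }
  if (max_additional >= 2L) for (i in 1:G) for (j in i:G) {
    k <- j:G
    consider(genes$kcal[i] + genes$kcal[j] + genes$kcal[k],
             genes$carb[i] + genes$carb[j] + genes$carb[k],
             genes$prot[i] + genes$prot[j] + genes$prot[k],
             genes$fat[i] + genes$fat[j] + genes$fat[k],
             genes$chol[i] + genes$chol[j] + genes$chol[k],
             gi_ok[i] & gi_ok[j] & gi_ok[k])
  }
  best # Inf when no feasible meal exists
}

# random deficit states for property tests, drawn from the active RNG stream
random_state <- function(with_limits = FALSE) {
  gi <- NULL
  chol <- NULL
  if (with_limits) {
    if (stats::runif(1) < 0.5) gi <- 55
    if (stats::runif(1) < 0.5) chol <- 300
  }
  deficit_state(
    available_kcal = stats::runif(1, 0, 2200),
    carb_deficit_g = stats::runif(1, 0, 280),
    protein_deficit_g = stats::runif(1, 0, 120),
    fat_deficit_g = stats::runif(1, 0, 80),
    gi_limit = gi, cholesterol_limit_mg = chol
  )
}
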