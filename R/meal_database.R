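#' Construct a dish record
#'
#' A dish is the atomic unit of the database: a standard adult portion with
#' its energy and macronutrient content and its food-group memberships over
#' the fixed 16-label vocabulary (see [food_groups()]).
#'
#' @param id Unique dish identifier (character).
#' @param name Display name.
#' @param kcal Energy per portion, kcal.
#' @param protein,fat,carbs Macronutrients per portion, grams.
#' @param groups Character vector of food-group labels.
#' @return A one-row data frame with a `groups` list-column.
#' @export
#' @examples
#' dish("d1", "Yoghurt with blueberries and oatmeal", 195.5, 11.53, 2.32,
#'      27.14, c("dairy", "cereals", "fruit"))
dish <- function(id, name, kcal, protein, fat, carbs, groups = character()) {
  bad <- setdiff(groups, food_groups())
  if (length(bad))
    stop_input("dish '%s': unknown food group(s): %s", id,
               paste(bad, collapse = ", "))
  if (any(c(kcal, protein, fat, carbs) < 0))
    stop_input("dish '%s': nutrient values must be non-negative", id)
  data.frame(id = as.character(id), name = as.character(name),
             kcal = kcal, protein = protein, fat = fat, carbs = carbs,
             groups = I(list(as.character(groups))),
             stringsAsFactors = FALSE)
}

#' Construct a meal record
#'
#' A meal is a typed, season- and cuisine-tagged bundle of 1-10 dish
#' references. Nutrient totals are always derived from the member dishes,
#' never stored.
#'
#' @param id Unique meal identifier (character).
#' @param type Meal slot, one of [meal_types()].
#' @param country Cuisine code, `"ES"` or `"TR"`.
#' @param dish_ids Character vector of 1-10 dish ids.
#' @param seasons Character vector of seasons in which the meal is offered
#'   (at least one).
#' @return A one-row data frame with logical season columns and a `dish_ids`
#'   list-column.
#' @export
meal <- function(id, type, country, dish_ids, seasons) {
  type <- match_one(type, meal_types(), sprintf("meal '%s' type", id))
  country <- match_one(country, countries(), sprintf("meal '%s' country", id))
  bad <- setdiff(seasons, nutriplanr::seasons())
  if (length(bad))
    stop_input("meal '%s': unknown season(s): %s", id, paste(bad, collapse = ", "))
  if (length(seasons) < 1L)
    stop_input("meal '%s': at least one season flag must be set", id)
  if (length(dish_ids) < 1L || length(dish_ids) > 10L)
    stop_input("meal '%s': must reference 1-10 dishes, got %d", id,
               length(dish_ids))
  out <- data.frame(id = as.character(id), type = type, country = country,
                    stringsAsFactors = FALSE)
  for (s in nutriplanr::seasons()) out[[s]] <- s %in% seasons
  out$dish_ids <- I(list(as.character(dish_ids)))
  out
}

#' Assemble a meal database
#'
#' @param dishes Data frame of dishes (rows as produced by [dish()]).
#' @param meals Data frame of meals (rows as produced by [meal()]).
#' @param check Validate invariants and fail on violations (default `TRUE`).
#' @return An object of class `meal_db`.
#' @export
meal_database <- function(dishes, meals, check = TRUE) {
  db <- structure(list(dishes = dishes, meals = meals), class = "meal_db")
  if (nrow(meals) == 0L)
    warning("meal database contains no meals", call. = FALSE)
  if (check) {
    v <- validate_database(db)
    if (nrow(v))
      stop_input("invalid meal database: %s",
                 paste(sprintf("[%s] %s: %s", v$record, v$rule, v$message),
                       collapse = "; "))
  }
  db
}

#' @export
print.meal_db <- function(x, ...) {
  cat(sprintf("<meal_db> %d dishes, %d meals\n", nrow(x$dishes), nrow(x$meals)))
  if (nrow(x$meals)) {
    tab <- table(factor(x$meals$type, levels = meal_types()), x$meals$country)
    print(tab)
  }
  invisible(x)
}

#' Validate a meal database
#'
#' Checks referential integrity, id uniqueness, group vocabulary, meal
#' cardinality (1-10 dishes), season flags, non-negative nutrients, and the
#' macro-energy consistency rule 4*protein + 9*fat <= 1.05*kcal (5%
#' tolerance for rounding in food-composition sources).
#'
#' @param db A `meal_db`.
#' @return A data frame of violations (`record`, `rule`, `message`); empty
#'   when the database is valid.
#' @export
validate_database <- function(db) {
  v <- list()
  add <- function(record, rule, message)
    v[[length(v) + 1L]] <<- data.frame(record = record, rule = rule,
                                       message = message)
  d <- db$dishes; m <- db$meals
  if (anyDuplicated(d$id))
    add(paste(d$id[duplicated(d$id)], collapse = ","), "unique_dish_id",
        "duplicated dish id")
  if (nrow(m) && anyDuplicated(m$id))
    add(paste(m$id[duplicated(m$id)], collapse = ","), "unique_meal_id",
        "duplicated meal id")
  for (i in seq_len(nrow(d))) {
    bad <- setdiff(d$groups[[i]], food_groups())
    if (length(bad))
      add(d$id[i], "group_vocabulary", paste("unknown group:", paste(bad, collapse = ",")))
    if (any(c(d$kcal[i], d$protein[i], d$fat[i], d$carbs[i]) < 0))
      add(d$id[i], "nonnegative_nutrients", "negative nutrient value")
    macro <- 4 * d$protein[i] + 9 * d$fat[i]
    if (macro > 1.05 * d$kcal[i] + 1e-9)
      add(d$id[i], "macro_energy",
          sprintf("protein+fat energy %.1f kcal exceeds 1.05 * %.1f kcal",
                  macro, d$kcal[i]))
  }
  for (i in seq_len(nrow(m))) {
    ids <- m$dish_ids[[i]]
    if (length(ids) < 1L || length(ids) > 10L)
      add(m$id[i], "meal_cardinality",
          sprintf("meal references %d dishes (allowed 1-10)", length(ids)))
    missing <- setdiff(ids, d$id)
    if (length(missing))
      add(m$id[i], "dangling_dish_ref",
          paste("unresolved dish id:", paste(missing, collapse = ",")))
    if (!any(unlist(m[i, seasons()])))
      add(m$id[i], "season_flags", "no season flag set")
    if (!m$type[i] %in% meal_types())
      add(m$id[i], "meal_type", paste("unknown type:", m$type[i]))
    if (!m$country[i] %in% countries())
      add(m$id[i], "country", paste("unknown country:", m$country[i]))
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(record = character(), rule = character(),
                  message = character())
}

#' Nutrient totals and food-group set of a meal
#'
#' Totals are sums over member dishes; the group set is the union of the
#' member dishes' groups.
#'
#' @param meal_id A meal id present in `db`.
#' @param db A `meal_db`.
#' @return A list with `kcal`, `protein`, `fat`, `carbs` and `groups`.
#' @export
meal_totals <- function(meal_id, db) {
  i <- match(meal_id, db$meals$id)
  if (is.na(i)) stop_input("meal '%s' not found in database", meal_id)
  ids <- db$meals$dish_ids[[i]]
  j <- match(ids, db$dishes$id)
  if (anyNA(j))
    stop_input("meal '%s': unresolved dish id(s): %s", meal_id,
               paste(ids[is.na(j)], collapse = ", "))
  list(kcal = sum(db$dishes$kcal[j]),
       protein = sum(db$dishes$protein[j]),
       fat = sum(db$dishes$fat[j]),
       carbs = sum(db$dishes$carbs[j]),
       groups = sort(unique(unlist(db$dishes$groups[j]))))
}

#' Allergen flags carried by a dish
#'
#' Allergens are not stored separately: they are a pure function of the
#' dish's food groups. `dairy` triggers the milk flag; `eggs`, `fish` and
#' `nuts` trigger their own; `pork` is flagged for the halal preference.
#'
#' @param groups Character vector of food-group labels (or a one-row dish
#'   data frame).
#' @return Named logical vector over `milk`, `eggs`, `fish`, `nuts`, `pork`.
#' @export
#' @examples
#' derive_allergen_flags(c("dairy", "cereals", "fruit"))
derive_allergen_flags <- function(groups) {
  if (is.data.frame(groups)) groups <- groups$groups[[1L]]
  map <- allergen_group_map()
  stats::setNames(map %in% groups, names(map))
}

# ---- internal resolved view ------------------------------------------------

# Per-meal derived table used by filtering/scoring: nutrient totals, allergen
# presence, and the count of member dishes carrying fruit or vegetables.
resolve_meals <- function(db) {
  m <- db$meals
  d <- db$dishes
  j_of <- lapply(m$dish_ids, function(ids) {
    j <- match(ids, d$id)
    if (anyNA(j)) stop_input("unresolved dish id(s): %s",
                             paste(ids[is.na(j)], collapse = ", "))
    j
  })
  agg <- function(col) vapply(j_of, function(j) sum(d[[col]][j]), numeric(1))
  out <- data.frame(id = m$id, type = m$type, country = m$country,
                    stringsAsFactors = FALSE)
  for (s in seasons()) out[[s]] <- m[[s]]
  out$kcal <- agg("kcal"); out$protein <- agg("protein")
  out$fat <- agg("fat"); out$carbs <- agg("carbs")
  map <- allergen_group_map()
  for (a in names(map))
    out[[paste0("has_", a)]] <- vapply(j_of, function(j)
      any(vapply(d$groups[j], function(g) map[[a]] %in% g, logical(1))),
      logical(1))
  out$n_fv_dishes <- vapply(j_of, function(j)
    sum(vapply(d$groups[j], function(g) any(g %in% fv_groups()), logical(1))),
    integer(1))
  out$n_dishes <- lengths(j_of)
  out
}

# ---- JSON / CSV I/O --------------------------------------------------------

#' Read a meal database from JSON
#'
#' The canonical on-disk format is a single JSON document
#' `{"dishes": [...], "meals": [...]}`. Each dish carries `id`, `name`,
#' `kcal`, `protein`, `fat`, `carbs` and a `groups` array; each meal carries
#' `id`, `type`, `country`, a `seasons` object of four booleans and a
#' `dish_ids` array. All invariants are checked on load.
#'
#' @param path Path to a JSON database file.
#' @return A validated `meal_db`.
#' @export
load_database <- function(path) {
  if (!file.exists(path)) stop_input("database file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  dishes <- do.call(rbind, lapply(doc$dishes, function(x)
    dish(x$id, x$name %||% x$id, x$kcal, x$protein, x$fat, x$carbs,
         as.character(unlist(x$groups)))))
  if (is.null(dishes))
    dishes <- dish("placeholder", "x", 0, 0, 0, 0)[0, ]
  meals <- do.call(rbind, lapply(doc$meals, function(x)
    meal(x$id, x$type, x$country, as.character(unlist(x$dish_ids)),
         names(Filter(isTRUE, x$seasons)))))
  if (is.null(meals))
    meals <- meal("placeholder", "lunch", "ES", "d", "winter")[0, ]
  meal_database(dishes, meals)
}

#' Write a meal database to JSON
#'
#' @param db A `meal_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_database <- function(db, path) {
  dishes <- lapply(seq_len(nrow(db$dishes)), function(i)
    list(id = db$dishes$id[i], name = db$dishes$name[i],
         kcal = db$dishes$kcal[i], protein = db$dishes$protein[i],
         fat = db$dishes$fat[i], carbs = db$dishes$carbs[i],
         groups = as.list(db$dishes$groups[[i]])))
  meals <- lapply(seq_len(nrow(db$meals)), function(i) {
    s <- as.list(stats::setNames(
      lapply(seasons(), function(x) isTRUE(db$meals[[x]][i])), seasons()))
    list(id = db$meals$id[i], type = db$meals$type[i],
         country = db$meals$country[i], seasons = s,
         dish_ids = as.list(db$meals$dish_ids[[i]]))
  })
  jsonlite::write_json(list(dishes = dishes, meals = meals), path,
                       auto_unbox = TRUE, pretty = FALSE, digits = NA)
  invisible(path)
}

#' Read or write the two-file CSV dialect
#'
#' For interchange the database can be stored as `dishes.csv` (one boolean
#' column per food group) and `meals.csv` (one boolean column per season;
#' `dish_ids` as a `;`-separated list).
#'
#' @param dir Directory containing (or to receive) `dishes.csv` and
#'   `meals.csv`.
#' @param db A `meal_db` (for writing).
#' @return `read_database_csv()` returns a validated `meal_db`;
#'   `write_database_csv()` returns `dir` invisibly.
#' @export
read_database_csv <- function(dir) {
  dpath <- file.path(dir, "dishes.csv"); mpath <- file.path(dir, "meals.csv")
  if (!file.exists(dpath) || !file.exists(mpath))
    stop_input("expected dishes.csv and meals.csv under %s", dir)
  dcsv <- utils::read.csv(dpath, stringsAsFactors = FALSE)
  mcsv <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  dishes <- do.call(rbind, lapply(seq_len(nrow(dcsv)), function(i) {
    grp <- food_groups()[vapply(food_groups(), function(g)
      isTRUE(as.logical(dcsv[[g]][i])), logical(1))]
    dish(dcsv$id[i], dcsv$name[i], dcsv$kcal[i], dcsv$protein[i],
         dcsv$fat[i], dcsv$carbs[i], grp)
  }))
  meals <- do.call(rbind, lapply(seq_len(nrow(mcsv)), function(i) {
    sn <- seasons()[vapply(seasons(), function(s)
      isTRUE(as.logical(mcsv[[s]][i])), logical(1))]
    meal(mcsv$id[i], mcsv$type[i], mcsv$country[i],
         strsplit(mcsv$dish_ids[i], ";", fixed = TRUE)[[1L]], sn)
  }))
  meal_database(dishes, meals)
}

#' @rdname read_database_csv
#' @export
write_database_csv <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- db$dishes[c("id", "name", "kcal", "protein", "fat", "carbs")]
  for (g in food_groups())
    d[[g]] <- vapply(db$dishes$groups, function(x) g %in% x, logical(1))
  m <- db$meals[c("id", "type", "country", seasons())]
  m$dish_ids <- vapply(db$meals$dish_ids, paste, character(1), collapse = ";")
  utils::write.csv(d, file.path(dir, "dishes.csv"), row.names = FALSE)
  utils::write.csv(m, file.path(dir, "meals.csv"), row.names = FALSE)
  invisible(dir)
}
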