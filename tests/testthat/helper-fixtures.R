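# Shared fixtures, built in code at load time.

# A hand-written micro database modelled on a published Spanish daily meal
# plan (yoghurt breakfast, sandwich snack, lentil lunch with orange, couscous
# + tuna + apple dinner), plus enough extra meals to exercise the filters
# and weekly rules.
micro_db <- local({
  dishes <- rbind(
    dish("yoghurt_oat", "Yoghurt with blueberries and oatmeal",
         195.50, 11.53, 2.32, 27.14, c("dairy", "cereals", "fruit")),
    dish("turkey_sandwich", "Turkey, apple and rocket sandwich",
         301.17, 13.64, 11.89, 31.90,
         c("white_meat", "cereals", "fruit", "raw_vegetables",
           "cooked_vegetables")),
    dish("lentil_stew", "Stewed lentils with vegetables and rice",
         362.12, 8.39, 16.11, 42.64,
         c("pulses", "rice", "soups", "cereals", "cooked_vegetables")),
    dish("orange", "Orange", 65.52, 1.08, 0.72, 11.56, "fruit"),
    dish("couscous_salad", "Couscous and pomegranate salad",
         419.20, 10.75, 11.63, 68.18, c("pasta", "fruit", "raw_vegetables")),
    dish("tuna_puree", "Grilled tuna with sweet potato puree",
         591.35, 37.86, 35.14, 28.92, c("fish", "dairy", "tubers")),
    dish("apple", "Apple", 89.14, 0.41, 0.41, 19.21, "fruit"),
    dish("omelette", "Plain omelette", 220, 14, 16, 2, "eggs"),
    dish("rice_bowl", "Rice bowl", 310, 6, 4, 62, c("rice", "cereals")),
    dish("pork_loin", "Pork loin", 280, 30, 17, 0, "pork"),
    dish("walnut_mix", "Walnut mix", 190, 4, 18, 4, "nuts"),
    dish("veg_soup", "Vegetable soup", 120, 4, 4, 16,
         c("soups", "cooked_vegetables")),
    dish("zero_dish", "Water", 0, 0, 0, 0, character()))
  meals <- rbind(
    meal("b_yoghurt", "breakfast", "ES", "yoghurt_oat", seasons()),
    meal("b_omelette", "breakfast", "ES", "omelette", c("winter", "spring")),
    meal("ms_sandwich", "morning_snack", "ES", "turkey_sandwich", seasons()),
    meal("ms_nuts", "morning_snack", "ES", "walnut_mix", c("autumn", "winter")),
    meal("l_lentils", "lunch", "ES", c("lentil_stew", "orange"), seasons()),
    meal("l_pork", "lunch", "ES", c("pork_loin", "rice_bowl"),
         c("winter", "summer")),
    meal("as_apple", "afternoon_snack", "ES", "apple", seasons()),
    meal("as_soup", "afternoon_snack", "ES", "veg_soup", c("winter")),
    meal("d_tuna", "dinner", "ES",
         c("couscous_salad", "tuna_puree", "apple"), seasons()),
    meal("d_rice", "dinner", "ES", c("rice_bowl", "veg_soup"), seasons()),
    meal("tr_b", "breakfast", "TR", "omelette", seasons()))
  meal_database(dishes, meals)
})

# Season/allergy-calibrated fixtures are relatively costly (~0.5 s each);
# build once and share across test files.
es_fixture <- generate_fixture_db(fixture_spec("ES"), seed = 101)
tr_fixture <- generate_fixture_db(fixture_spec("TR"), seed = 101)

# quick profile factory
test_profile <- function(der = 2400, country = "ES",
                         allergies = character(), halal = FALSE) {
  list(country = country, allergies = allergies, halal = halal, der = der)
}

# exhaustive lexicographic-first oracle for weekly assembly on small pools:
# the first 7-subset (in index-lexicographic order) of the sorted candidate
# list whose week passes the full independent verifier.
lex_first_feasible_week <- function(sorted_plans, db,
                                    config = weekly_rule_config()) {
  n <- nrow(sorted_plans)
  if (n < 7L) return(NULL)
  combos <- utils::combn(n, 7L)
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    if (nrow(verify_week(sorted_plans[idx, ], db, config)) == 0L)
      return(idx)
  }
  NULL
}

# deterministic candidate pool with known rule conflicts: days 1-3 each put
# two fish dishes at lunch (only day 1 fits under the weekly fish cap of 3);
# the remaining days are benign and pairwise disjoint. Greedy must keep day
# 1, skip days 2-3, and fill the week from the decoys.
make_conflict_pool <- function(n_days = 10L) {
  dishes <- list(); meals <- list(); days <- list()
  for (k in seq_len(n_days)) {
    ids <- sprintf("p%d_%s", k, c("b", "ms", "l", "as", "d"))
    for (j in seq_along(ids)) {
      grp <- if (j == 3L && k <= 3L) "fish" else c("fruit", "cereals")
      nd <- if (j == 3L && k <= 3L) 2L else 1L
      for (dji in seq_len(nd))
        dishes[[length(dishes) + 1L]] <-
          dish(sprintf("%s_dish%d", ids[j], dji), ids[j], 300, 10, 8, 40, grp)
      meals[[length(meals) + 1L]] <-
        meal(ids[j], meal_types()[j], "ES",
             sprintf("%s_dish%d", ids[j], seq_len(nd)), "winter")
    }
    days[[k]] <- data.frame(breakfast = ids[1], morning_snack = ids[2],
                            lunch = ids[3], afternoon_snack = ids[4],
                            dinner = ids[5], tk = 2000, protein_g = 90,
                            fat_g = 70, tfv = 6L, dnps = k,
                            stringsAsFactors = FALSE)
  }
  list(db = meal_database(do.call(rbind, dishes), do.call(rbind, meals)),
       pool = do.call(rbind, days))
}

# small random database used by property tests: n meals per slot, dishes
# with random groups drawn from a weighted palette (benign groups dominate
# so that complete weeks stay feasible while the capped/clash groups still
# occur regularly)
random_small_db <- function(n_per_slot = 6L, seed = 1L, country = "ES") {
  set.seed(seed)
  palette <- c("fruit", "raw_vegetables", "cooked_vegetables", "cereals",
               "soups", "dairy", "white_meat", "pulses",
               "rice", "pasta", "tubers", "fish", "eggs")
  weights <- c(0.16, 0.13, 0.13, 0.16, 0.08, 0.10, 0.05, 0.05,
               0.028, 0.028, 0.028, 0.028, 0.028)
  dishes <- list(); meals <- list()
  for (tp in meal_types()) {
    for (i in seq_len(n_per_slot)) {
      nd <- sample(1:3, 1)
      ids <- sprintf("%s_%s_%d_d%d", country, tp, i, seq_len(nd))
      for (j in seq_len(nd)) {
        kcal <- round(runif(1, 60, 500), 1)
        prot <- round(runif(1, 0.05, 0.2) * kcal / 4, 1)
        fat <- round(runif(1, 0.1, 0.35) * kcal / 9, 1)
        dishes[[length(dishes) + 1L]] <-
          dish(ids[j], ids[j], kcal, prot, fat,
               round(max(kcal - 4 * prot - 9 * fat, 0) / 4, 1),
               unique(sample(palette, sample(0:3, 1), replace = TRUE,
                             prob = weights)))
      }
      meals[[length(meals) + 1L]] <-
        meal(sprintf("%s_%s_%d", country, tp, i), tp, country, ids,
             sample(seasons(), sample(2:4, 1)))
    }
  }
  meal_database(do.call(rbind, dishes), do.call(rbind, meals))
}
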