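#' Reference availability matrix for a cuisine
#'
#' Per-slot counts of eligible meals for every season and single
#' allergy/preference attribute, used as calibration targets by the fixture
#' generator. These mirror the characterization of the project's curated
#' Spanish and Turkish databases (90 meals each). One cell of the Spanish
#' matrix (winter nut-free lunches) is carried as 18 rather than the
#' published 8, the unique value consistent with the schema's fixed per-meal
#' composition across seasons; see the methods vignette for the derivation.
#'
#' @param country `"ES"` or `"TR"`.
#' @return Data frame with columns `season`, `attribute`, and one count per
#'   meal slot.
#' @export
reference_availability <- function(country) {
  country <- match_one(country, countries(), "country")
  mk <- function(season, tab) {
    out <- data.frame(season = season,
                      attribute = c("none", "milk", "eggs", "fish", "nuts",
                                    "halal"))
    m <- matrix(tab, ncol = 5, byrow = TRUE)
    colnames(m) <- meal_types()
    cbind(out, as.data.frame(m))
  }
  if (country == "ES") {
    rbind(
      mk("winter", c(14, 7, 21, 6, 15,   0, 3, 11, 2, 9,   12, 7, 16, 6, 8,
                     14, 7, 15, 6, 9,   11, 4, 18, 2, 13,  13, 7, 20, 6, 13)),
      mk("spring", c(15, 9, 25, 10, 19,  0, 5, 12, 3, 13,  13, 9, 17, 10, 11,
                     15, 9, 14, 10, 10, 12, 4, 22, 5, 17,  14, 9, 24, 10, 17)),
      mk("summer", c(18, 7, 23, 10, 19,  0, 4, 11, 3, 13,  15, 7, 18, 10, 11,
                     18, 7, 12, 10, 10, 15, 3, 21, 5, 17,  17, 7, 23, 10, 17)),
      mk("autumn", c(16, 8, 21, 6, 17,   0, 4, 9, 2, 11,   13, 8, 18, 6, 10,
                     16, 8, 15, 6, 10,  13, 4, 19, 2, 15,  15, 8, 21, 6, 15)))
  } else {
    rbind(
      mk("winter", c(16, 6, 14, 9, 13,   4, 1, 8, 6, 5,    6, 6, 8, 9, 10,
                     16, 6, 14, 9, 11,  16, 4, 14, 4, 13,  16, 6, 14, 9, 13)),
      mk("spring", c(15, 5, 16, 6, 14,   6, 0, 4, 2, 5,    5, 5, 11, 6, 10,
                     15, 5, 16, 6, 12,  15, 4, 16, 4, 13,  15, 5, 16, 6, 14)),
      mk("summer", c(16, 8, 22, 8, 14,   5, 1, 8, 4, 6,    5, 8, 16, 8, 10,
                     16, 8, 22, 8, 12,  15, 7, 21, 5, 13,  16, 8, 22, 8, 14)),
      mk("autumn", c(16, 6, 13, 10, 12,  4, 1, 7, 7, 4,    6, 6, 10, 10, 10,
                     16, 6, 13, 10, 10, 16, 4, 12, 4, 12,  16, 6, 13, 10, 12)))
  }
}

#' Reference daily-plan nutrient statistics for a cuisine
#'
#' Per-season mean and standard deviation of the full-day energy of the
#' unrestricted daily-plan pool, and of the fat and protein energy
#' percentages, used to calibrate the fixture generator's nutrient draws.
#'
#' @param country `"ES"` or `"TR"`.
#' @return Data frame with one row per season.
#' @export
reference_np_stats <- function(country) {
  country <- match_one(country, countries(), "country")
  if (country == "ES") {
    data.frame(season = c("winter", "spring", "summer", "autumn"),
               kcal_mean = c(2340, 2318, 2326, 2367),
               kcal_sd = c(258, 263, 263, 266),
               fat_pct_mean = c(38, 37, 37, 37), fat_pct_sd = c(5, 5, 5, 4),
               protein_pct_mean = c(18, 18, 18, 18),
               protein_pct_sd = c(4, 4, 4, 4))
  } else {
    data.frame(season = c("winter", "spring", "summer", "autumn"),
               kcal_mean = c(1821, 1685, 1742, 1808),
               kcal_sd = c(233, 225, 252, 133),
               fat_pct_mean = c(40, 40, 38, 40), fat_pct_sd = c(8, 8, 9, 8),
               protein_pct_mean = c(16, 16, 15, 16),
               protein_pct_sd = c(3, 3, 3, 3))
  }
}

#' Fixture database specification
#'
#' Bundles everything the fixture generator needs: per-slot meal counts, the
#' target availability matrix (eligible meals per season and
#' allergy/preference attribute), and the target full-day nutrient
#' distributions. Defaults reproduce the characterization of the curated
#' databases: Spanish 20/10/30/10/20 meals per slot, Turkish 20/10/28/12/20.
#'
#' @param country `"ES"` or `"TR"`.
#' @param type_counts Named integer vector of meals per slot.
#' @param availability Availability targets, as from
#'   [reference_availability()].
#' @param np_stats Nutrient targets, as from [reference_np_stats()].
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(country,
                         type_counts = NULL,
                         availability = reference_availability(country),
                         np_stats = reference_np_stats(country)) {
  country <- match_one(country, countries(), "country")
  if (is.null(type_counts))
    type_counts <- if (country == "ES")
      c(breakfast = 20L, morning_snack = 10L, lunch = 30L,
        afternoon_snack = 10L, dinner = 20L)
    else
      c(breakfast = 20L, morning_snack = 10L, lunch = 28L,
        afternoon_snack = 12L, dinner = 20L)
  for (tp in meal_types()) {
    if (any(availability[[tp]] > type_counts[[tp]]))
      stop_input("availability target for %s exceeds its total count", tp)
    for (s in unique(availability$season)) {
      rows <- availability[availability$season == s, ]
      n_none <- rows[[tp]][rows$attribute == "none"]
      if (any(rows[[tp]] > n_none))
        stop_input("%s/%s: attribute availability exceeds unrestricted count",
                   s, tp)
    }
  }
  structure(list(country = country, type_counts = type_counts,
                 availability = availability, np_stats = np_stats),
            class = "fixture_spec")
}

# ---- season-pattern construction ------------------------------------------

# Assign season flags to n meals so that exactly t_no[s] meals carry season s.
# Start from all-season meals and strip flags; the first attempt strips from
# the meals currently holding the most seasons (balanced patterns), later
# attempts strip at random, which produces the richer pattern mixtures some
# allergen demands require.
assign_seasons <- function(n, t_no, randomize = FALSE) {
  flags <- matrix(TRUE, n, 4, dimnames = list(NULL, seasons()))
  season_order <- if (randomize) sample.int(4L) else order(n - t_no,
                                                           decreasing = TRUE)
  for (s in season_order) {
    excess <- n - t_no[s]
    if (excess == 0L) next
    cand <- which(flags[, s] & rowSums(flags) > 1L)
    if (length(cand) < excess) return(NULL)
    pick <- if (randomize) sample(cand, excess)
            else {
              o <- order(rowSums(flags)[cand], cand,
                         decreasing = c(TRUE, FALSE), method = "radix")
              cand[o][seq_len(excess)]
            }
    flags[pick, s] <- FALSE
  }
  if (!all(colSums(flags) == t_no)) return(NULL)
  flags
}

# Analytic pre-check of the availability targets for one meal type: an
# allergen whose demand in one season exceeds the combined demand of the
# other seasons needs that many single-season meals, which the unrestricted
# counts may not leave room for. Returns NULL or a message naming the cell.
availability_infeasibility <- function(n, t_no, demands) {
  for (a in rownames(demands)) for (s in seasons()) {
    others <- setdiff(seasons(), s)
    need_single <- demands[a, s] - sum(demands[a, others])
    cap_single <- min(n - t_no[others])
    if (need_single > cap_single)
      return(sprintf(
        "attribute '%s', season '%s': %d meals must carry the group in that season only, but the other seasons' counts leave room for at most %d single-season meals",
        a, s, need_single, cap_single))
  }
  NULL
}

# Find a 0/1 allergen assignment over meals with season-flag matrix `flags`
# such that, per season s, exactly demand[s] flagged meals carry the
# allergen. Solved exactly over season-pattern classes by depth-first search
# with interval pruning.
solve_allergen <- function(flags, demand) {
  pat <- apply(flags, 1L, function(r) paste(as.integer(r), collapse = ""))
  classes <- sort(unique(pat))
  n_p <- vapply(classes, function(p) sum(pat == p), integer(1))
  inc <- t(vapply(classes, function(p)
    as.logical(as.integer(strsplit(p, "")[[1L]])), logical(4)))
  if (k_is_one <- length(classes) == 1L) inc <- matrix(inc, 1L, 4L)
  k <- length(classes)
  best <- NULL
  rec <- function(i, rem, x) {
    if (!is.null(best)) return()
    if (i > k) {
      if (all(rem == 0L)) best <<- x
      return()
    }
    # max still contributable to each season by classes i..k
    tail_max <- colSums(inc[seq(i, k), , drop = FALSE] * n_p[seq(i, k)])
    if (any(rem < 0L) || any(rem > tail_max)) return()
    lo <- 0L; hi <- n_p[i]
    if (any(inc[i, ])) {
      hi <- min(hi, min(rem[inc[i, ]]))
      later <- colSums(inc[seq.int(i + 1L, length.out = k - i), , drop = FALSE] *
                         n_p[seq.int(i + 1L, length.out = k - i)])
      lo <- max(lo, max(rem[inc[i, ]] - later[inc[i, ]]))
    }
    if (lo > hi) return()
    for (v in lo:hi) {
      rec(i + 1L, rem - v * inc[i, ], c(x, v))
      if (!is.null(best)) return()
    }
  }
  rec(1L, as.integer(demand), integer(0))
  if (is.null(best)) return(NULL)
  # expand class counts into a per-meal logical vector (first meals in class)
  out <- logical(length(pat))
  for (j in seq_len(k)) {
    idx <- which(pat == classes[j])
    out[idx[seq_len(best[j])]] <- TRUE
  }
  out
}

#' Generate a fixture meal database matching an availability matrix
#'
#' Constructively builds a synthetic dish/meal database whose
#' [filter_meals()] output reproduces the spec's availability matrix
#' cell-for-cell: season flags are assigned so the unrestricted per-season
#' counts match, and allergen-carrying food groups (dairy, eggs, fish, nuts,
#' pork) are placed by exact combinatorial search so each allergy/preference
#' row matches. Meal nutrient values are drawn from normal distributions and
#' then adjusted by a minimum-norm linear correction so that the mean
#' full-day energy of each season's unrestricted plan pool equals the target
#' mean. Deterministic under `seed`.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @return A validated `meal_db`.
#' @export
#' @examples
#' db <- generate_fixture_db(fixture_spec("ES"), seed = 1)
#' attr(filter_meals(db, filter_context("ES", "winter")), "n")
generate_fixture_db <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  av <- spec$availability
  attr_map <- allergen_group_map()  # milk/eggs/fish/nuts/pork
  attr_of <- c(milk = "milk", eggs = "eggs", fish = "fish", nuts = "nuts",
               pork = "halal")
  with_seed(seed, {
    meals_all <- list(); dishes_all <- list()
    slot_short <- c(breakfast = "b", morning_snack = "ms", lunch = "l",
                    afternoon_snack = "as", dinner = "d")
    for (tp in meal_types()) {
      n <- spec$type_counts[[tp]]
      t_no <- vapply(seasons(), function(s)
        av[[tp]][av$season == s & av$attribute == "none"], numeric(1))
      demands <- t(vapply(names(attr_map), function(a)
        t_no - vapply(seasons(), function(s)
          av[[tp]][av$season == s & av$attribute == attr_of[[a]]], numeric(1)),
        numeric(4)))
      msg <- availability_infeasibility(n, t_no, demands)
      if (!is.null(msg))
        stop_input("infeasible fixture spec, slot '%s' (%s): %s",
                   tp, spec$country, msg)
      solved <- NULL
      for (attempt in seq_len(400L)) {
        flags <- assign_seasons(n, t_no, randomize = attempt > 1L)
        if (is.null(flags)) next
        carries <- list(); ok <- TRUE
        for (a in names(attr_map)) {
          t_attr <- vapply(seasons(), function(s)
            av[[tp]][av$season == s & av$attribute == attr_of[[a]]],
            numeric(1))
          sol <- solve_allergen(flags, t_no - t_attr)
          if (is.null(sol)) { ok <- FALSE; failed <- a; break }
          carries[[a]] <- sol
        }
        if (ok) { solved <- list(flags = flags, carries = carries); break }
      }
      if (is.null(solved))
        stop_input("infeasible fixture spec: no assignment for slot '%s' (%s)",
                   tp, spec$country)
      meals_all[[tp]] <- solved
    }
    build_fixture_records(spec, meals_all, slot_short)
  })
}

# slot weights: share of the daily energy assigned to each meal slot
slot_weights <- function() {
  c(breakfast = 0.20, morning_snack = 0.10, lunch = 0.35,
    afternoon_snack = 0.10, dinner = 0.25)
}

# number of dishes composing a meal of each slot
slot_dish_counts <- function() {
  c(breakfast = 2L, morning_snack = 1L, lunch = 3L, afternoon_snack = 1L,
    dinner = 3L)
}

build_fixture_records <- function(spec, meals_all, slot_short) {
  stats_tab <- spec$np_stats
  w <- slot_weights()
  kcal_mean_bar <- mean(stats_tab$kcal_mean)
  kcal_sd_bar <- mean(stats_tab$kcal_sd)
  dish_rows <- list(); meal_rows <- list()
  for (tp in meal_types()) {
    n <- spec$type_counts[[tp]]
    flags <- meals_all[[tp]]$flags
    carries <- meals_all[[tp]]$carries
    # initial energy draws, then minimum-norm correction so that the mean
    # energy of the season-eligible meals equals the slot share of each
    # season's target day mean
    x0 <- stats::rnorm(n, w[[tp]] * kcal_mean_bar, kcal_sd_bar * sqrt(w[[tp]]))
    A <- t(apply(flags, 2L, function(f) f / sum(f)))
    b <- w[[tp]] * stats_tab$kcal_mean[match(seasons(), stats_tab$season)]
    x <- x0 + t(A) %*% MASS::ginv(A %*% t(A)) %*% (b - A %*% x0)
    kcal <- pmax(as.numeric(x), 40)
    fat_frac <- pmin(pmax(stats::rnorm(
      n, mean(stats_tab$fat_pct_mean) / 100,
      2 * mean(stats_tab$fat_pct_sd) / 100), 0.10), 0.62)
    prot_frac <- pmin(pmax(stats::rnorm(
      n, mean(stats_tab$protein_pct_mean) / 100,
      2 * mean(stats_tab$protein_pct_sd) / 100), 0.06), 0.32)
    tot <- fat_frac + prot_frac
    over <- tot > 0.92
    fat_frac[over] <- fat_frac[over] * 0.92 / tot[over]
    prot_frac[over] <- prot_frac[over] * 0.92 / tot[over]
    nd <- slot_dish_counts()[[tp]]
    for (i in seq_len(n)) {
      mid <- sprintf("%s_%s%02d", spec$country, slot_short[[tp]], i)
      groups_per_dish <- rep(list(character(0)), nd)
      # allergen-driven groups, cycled over dishes
      a_groups <- allergen_group_map()[names(carries)[vapply(
        carries, function(v) v[i], logical(1))]]
      for (k in seq_along(a_groups)) {
        slot_j <- ((k - 1L) %% nd) + 1L
        groups_per_dish[[slot_j]] <- c(groups_per_dish[[slot_j]],
                                       unname(a_groups[k]))
      }
      # fruit/vegetable dishes
      n_fv <- if (tp %in% c("lunch", "dinner")) 2L
              else stats::rbinom(1L, 1L, 0.8)
      fv_pick <- sample(fv_groups(), max(n_fv, 1L), replace = TRUE)
      if (n_fv > 0L)
        for (k in seq_len(n_fv)) {
          slot_j <- nd - k + 1L
          groups_per_dish[[slot_j]] <- c(groups_per_dish[[slot_j]], fv_pick[k])
        }
      # a protein main and a carb staple for the two big meals
      if (tp %in% c("lunch", "dinner")) {
        if (!any(c("fish", "pork") %in% unlist(groups_per_dish)))
          groups_per_dish[[1L]] <- c(groups_per_dish[[1L]],
                                     sample(c("white_meat", "red_meat",
                                              "pulses"), 1L))
        staple <- sample(c("cereals", "rice", "pasta", "tubers"), 1L,
                         prob = c(0.7, 0.1, 0.1, 0.1))
        groups_per_dish[[min(2L, nd)]] <-
          c(groups_per_dish[[min(2L, nd)]], staple)
      } else if (tp == "breakfast") {
        groups_per_dish[[1L]] <- c(groups_per_dish[[1L]], "cereals")
      }
      # split meal nutrients over dishes
      share <- as.numeric(stats::rmultinom(1L, 100L, rep(1, nd))) / 100
      share <- (share + 0.05) / sum(share + 0.05)
      d_kcal <- kcal[i] * share
      d_prot <- prot_frac[i] * kcal[i] / 4 * share
      d_fat <- fat_frac[i] * kcal[i] / 9 * share
      d_carb <- pmax((d_kcal - 4 * d_prot - 9 * d_fat) / 4, 0)
      ids <- sprintf("%s_d%d", mid, seq_len(nd))
      for (j in seq_len(nd))
        dish_rows[[length(dish_rows) + 1L]] <-
          dish(ids[j], sprintf("synthetic %s dish %d", tp, j),
               round(d_kcal[j], 2), round(d_prot[j], 2), round(d_fat[j], 2),
               round(d_carb[j], 2), unique(groups_per_dish[[j]]))
      meal_rows[[length(meal_rows) + 1L]] <-
        meal(mid, tp, spec$country, ids, seasons()[flags[i, ]])
    }
  }
  meal_database(do.call(rbind, dish_rows), do.call(rbind, meal_rows))
}

# ---- cohort generation -----------------------------------------------------

#' Evaluation cohort specification
#'
#' One stratum per country-by-sex combination, 1,000 profiles each by
#' default (4,000 in total). Within each stratum the allergy/preference
#' allocation is deterministic (exact counts, at most one attribute per
#' profile): per 1,000 users, 60 milk, 25 eggs, 20 fish, 25 nuts, plus 30
#' halal in Spain or 500 halal in Turkiye, the remainder unrestricted. The
#' daily energy requirement is drawn from a sex-specific normal
#' distribution: mean 2,500 kcal and sd 1000/3 kcal for men, mean 2,000 kcal
#' and sd 4000/15 kcal for women, truncated to \[1000, 4000\] kcal by
#' redraw.
#'
#' @param per_stratum Profiles per country-by-sex stratum.
#' @param countries_used Countries to include.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(per_stratum = 1000L, countries_used = countries()) {
  alloc <- function(halal_n, n) {
    base <- c(milk = 60, eggs = 25, fish = 20, nuts = 25, halal = halal_n)
    base <- round(base * n / 1000)
    c(none = n - sum(base), base)
  }
  structure(list(
    per_stratum = per_stratum,
    countries_used = countries_used,
    allocation = list(ES = alloc(30, per_stratum),
                      TR = alloc(500, per_stratum)),
    der = list(male = c(mean = 2500, sd = 1000 / 3),
               female = c(mean = 2000, sd = 4000 / 15)),
    der_range = c(1000, 4000)),
    class = "cohort_spec")
}

#' Sample daily energy requirements
#'
#' Sex-specific truncated normal draws: Normal(2500, 1000/3) for men,
#' Normal(2000, 4000/15) for women, redrawing any value outside
#' \[1000, 4000\] kcal. Uses the current RNG state.
#'
#' @param n Number of draws.
#' @param sex `"male"` or `"female"`.
#' @param spec A [cohort_spec()] providing the distribution parameters.
#' @return Numeric vector of DER values, kcal/day.
#' @export
sample_der <- function(n, sex, spec = cohort_spec()) {
  sex <- match_one(sex, c("male", "female"), "sex")
  p <- spec$der[[sex]]
  lo <- spec$der_range[1]; hi <- spec$der_range[2]
  out <- stats::rnorm(n, p[["mean"]], p[["sd"]])
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), p[["mean"]], p[["sd"]])
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Generate the evaluation cohort
#'
#' Produces `per_stratum` profiles for each country-by-sex stratum with the
#' exact deterministic allergy/preference allocation of the spec and DER
#' values drawn from the sex-specific truncated normal distribution.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Data frame with columns `profile_id`, `country`, `sex`,
#'   `attribute` (`"none"`, an allergy, or `"halal"`) and `der`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(per_stratum = 100), seed = 1)
#' table(cohort$country, cohort$attribute)
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  with_seed(seed, {
    rows <- list()
    for (cty in spec$countries_used) for (sx in c("male", "female")) {
      alloc <- spec$allocation[[cty]]
      attribute <- rep(names(alloc), times = alloc)
      der <- sample_der(length(attribute), sx, spec)
      rows[[length(rows) + 1L]] <- data.frame(
        profile_id = sprintf("%s_%s_%04d", cty, sx, seq_along(attribute)),
        country = cty, sex = sx, attribute = attribute, der = der,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
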