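#' Recommend a weekly plan for one user
#'
#' End-to-end pipeline for a single profile and season: filter the meal pool,
#' enumerate or sample candidate daily plans, score them against the user's
#' daily energy requirement, sort, and greedily assemble seven days under
#' the weekly rules.
#'
#' @param profile A [user_profile()], or a list with at least `country`,
#'   `allergies`, `halal` and `der`.
#' @param db A `meal_db`.
#' @param season One of [seasons()].
#' @param sconfig A [scoring_config()].
#' @param wconfig A [weekly_rule_config()].
#' @param seed Integer seed for candidate sampling.
#' @return A `weekly_np` (see [assemble_week()]).
#' @export
recommend_week <- function(profile, db, season, sconfig = scoring_config(),
                           wconfig = weekly_rule_config(), seed = 1L) {
  ctx <- filter_context(profile$country, season,
                        allergies = profile$allergies %||% character(),
                        halal = isTRUE(profile$halal))
  r <- resolve_meals(db)
  buckets <- filter_meals(db, ctx, resolved = r)
  plans <- enumerate_daily_nps(db, buckets, sconfig, seed = seed, resolved = r)
  if (nrow(plans) == 0L)
    return(structure(list(days = plans, provenance = integer(0),
                          complete = FALSE, n_selected = 0L,
                          rejections = integer(0)),
                     class = "weekly_np"))
  scored <- sort_daily_nps(score_daily_nps(plans, profile$der, sconfig))
  assemble_week(scored, db, wconfig)
}

#' Mean caloric agreement of accepted daily plans
#'
#' Defined as the mean over daily plans of
#' `100 * max(0, 1 - |TK - DER| / DER)`: 100 when the plan's energy matches
#' the requirement exactly, decreasing linearly with the relative caloric
#' error and floored at 0.
#'
#' @param tk Total kcal per daily plan.
#' @param der Matching daily energy requirement per plan.
#' @return Percentage in \[0, 100\], or `NA` for an empty set.
#' @export
#' @examples
#' mean_caloric_agreement(c(2000, 1800), c(2000, 2000))
mean_caloric_agreement <- function(tk, der) {
  if (length(tk) == 0L) return(NA_real_)
  mean(100 * pmax(0, 1 - abs(tk - der) / der))
}

#' Share of accepted daily plans inside each nutritional band
#'
#' @param daily Data frame of accepted daily plans with columns `tfp`,
#'   `tpp`, `tfv`.
#' @param config A [scoring_config()] supplying the bands.
#' @return Named numeric vector (`fat`, `protein`, `fruit_veg`) of
#'   percentages, `NA` for an empty set.
#' @export
within_range_rates <- function(daily, config = scoring_config()) {
  if (nrow(daily) == 0L)
    return(c(fat = NA_real_, protein = NA_real_, fruit_veg = NA_real_))
  c(fat = 100 * mean(daily$tfp >= config$fat_bounds[1] &
                       daily$tfp <= config$fat_bounds[2]),
    protein = 100 * mean(daily$tpp >= config$protein_bounds[1] &
                           daily$tpp <= config$protein_bounds[2]),
    fruit_veg = 100 * mean(daily$tfv >= config$fv_bounds[1] &
                             daily$tfv <= config$fv_bounds[2]))
}

# context for a cohort attribute label
attribute_context <- function(country, season, attribute) {
  filter_context(country, season,
                 allergies = if (attribute %in% allergens()) attribute
                             else character(),
                 halal = attribute == "halal")
}

#' Run the full pipeline over a cohort
#'
#' For every profile and season: filter, enumerate/sample, score, sort and
#' assemble a weekly plan. A weekly plan is *acceptable* iff assembly
#' returned exactly 7 days. Failures are counted, never raised. Each
#' profile-season run uses an independent sub-seed derived from the master
#' seed, so any stratum can be reproduced in isolation.
#'
#' @param db A `meal_db`.
#' @param cohort Data frame from [generate_cohort()].
#' @param seasons_used Seasons to evaluate (default all four).
#' @param sconfig A [scoring_config()].
#' @param wconfig A [weekly_rule_config()].
#' @param seed Master seed.
#' @return An object of class `evaluation_report`: list with `runs` (one row
#'   per profile-season attempt), `daily` (one row per accepted daily plan,
#'   including its five meal ids and nutrient summary) and `strata` (the
#'   per-stratum accuracy table).
#' @export
run_experiment <- function(db, cohort, seasons_used = seasons(),
                           sconfig = scoring_config(),
                           wconfig = weekly_rule_config(), seed = 1L) {
  r <- resolve_meals(db)
  bucket_cache <- new.env(parent = emptyenv())
  enum_cache <- new.env(parent = emptyenv())
  runs <- list(); daily <- list()
  for (si in seq_along(seasons_used)) {
    season <- seasons_used[si]
    for (pi in seq_len(nrow(cohort))) {
      prof <- cohort[pi, ]
      key <- paste(prof$country, prof$attribute, season, sep = "|")
      buckets <- bucket_cache[[key]] %||% {
        b <- filter_meals(db, attribute_context(prof$country, season,
                                                prof$attribute),
                          resolved = r)
        bucket_cache[[key]] <- b
        b
      }
      counts <- attr(buckets, "n")
      total <- count_daily_nps(counts)
      sub_seed <- (seed * 100003L + pi * 7L + si) %% .Machine$integer.max
      if (total <= sconfig$sample_cap) {
        # full enumeration is profile-independent: cache it
        plans <- enum_cache[[key]] %||% {
          p <- enumerate_daily_nps(db, buckets, sconfig, resolved = r)
          enum_cache[[key]] <- p
          p
        }
      } else {
        plans <- enumerate_daily_nps(db, buckets, sconfig, seed = sub_seed,
                                     resolved = r)
      }
      if (nrow(plans) == 0L) {
        week <- NULL; complete <- FALSE; n_sel <- 0L
      } else {
        scored <- sort_daily_nps(score_daily_nps(plans, prof$der, sconfig))
        week <- assemble_week(scored, db, wconfig)
        complete <- week$complete; n_sel <- week$n_selected
      }
      runs[[length(runs) + 1L]] <- data.frame(
        profile_id = prof$profile_id, country = prof$country, sex = prof$sex,
        attribute = prof$attribute, season = season, der = prof$der,
        pool_size = total, complete = complete, n_selected = n_sel,
        stringsAsFactors = FALSE)
      if (complete) {
        d <- week$days
        d$profile_id <- prof$profile_id; d$country <- prof$country
        d$sex <- prof$sex; d$attribute <- prof$attribute
        d$season <- season; d$der <- prof$der
        daily[[length(daily) + 1L]] <- d
      }
    }
  }
  runs <- do.call(rbind, runs)
  daily <- if (length(daily)) do.call(rbind, daily) else NULL
  structure(list(runs = runs, daily = daily,
                 strata = summarize_strata(runs, daily, sconfig),
                 sconfig = sconfig),
            class = "evaluation_report")
}

# per-stratum accuracy table (country x sex x attribute)
summarize_strata <- function(runs, daily, sconfig) {
  keys <- unique(runs[c("country", "sex", "attribute")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- runs$country == k$country & runs$sex == k$sex &
      runs$attribute == k$attribute
    rr <- runs[sel, ]
    dd <- if (is.null(daily)) NULL
          else daily[daily$country == k$country & daily$sex == k$sex &
                       daily$attribute == k$attribute, ]
    n_daily <- if (is.null(dd)) 0L else nrow(dd)
    wr <- if (n_daily) within_range_rates(dd, sconfig)
          else c(fat = NA_real_, protein = NA_real_, fruit_veg = NA_real_)
    data.frame(
      country = k$country, sex = k$sex, attribute = k$attribute,
      users = length(unique(rr$profile_id)),
      corresponding_weekly = nrow(rr),
      acceptable_weekly = sum(rr$complete),
      pct_acceptable = 100 * mean(rr$complete),
      corresponding_daily = n_daily,
      mean_caloric_agreement = if (n_daily)
        mean_caloric_agreement(dd$tk, dd$der) else NA_real_,
      fat_within = wr[["fat"]], protein_within = wr[["protein"]],
      fv_within = wr[["fruit_veg"]],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d profile-season runs, %d acceptable\n",
              nrow(x$runs), sum(x$runs$complete)))
  cat("(caloric agreement = mean of 100 * max(0, 1 - |TK - DER| / DER))\n")
  print(x$strata, digits = 4)
  invisible(x)
}

#' Exhaustive post-hoc audit of filtering soundness
#'
#' Re-checks every meal of every accepted daily plan against the four hard
#' criteria: cuisine country, season flag, allergy exclusion and halal/pork
#' exclusion. Reports per-criterion check counts, violations and accuracy.
#' A correct pipeline scores 100 on every criterion; the audit exists to
#' catch regressions and deliberately corrupted plans.
#'
#' @param daily Accepted daily plans (the `daily` element of an
#'   [run_experiment()] report), with the five meal-id columns plus
#'   `country`, `attribute`, `season`.
#' @param db The `meal_db` the plans were drawn from.
#' @return Data frame with one row per criterion (`country`, `season`,
#'   `allergy`, `preference`): `checks`, `violations`, `accuracy` (percent;
#'   `NA` when no checks applied).
#' @export
filtering_accuracy_audit <- function(daily, db) {
  r <- resolve_meals(db)
  crit <- c("country", "season", "allergy", "preference")
  checks <- stats::setNames(numeric(4), crit)
  viols <- stats::setNames(numeric(4), crit)
  if (!is.null(daily) && nrow(daily)) {
    for (i in seq_len(nrow(daily))) {
      row <- daily[i, ]
      mi <- match(unlist(row[meal_types()], use.names = FALSE), r$id)
      if (anyNA(mi)) {
        # unresolvable meal counts as a violation of every criterion
        checks <- checks + 5; viols <- viols + sum(is.na(mi))
        mi <- mi[!is.na(mi)]
        if (!length(mi)) next
      }
      checks[["country"]] <- checks[["country"]] + length(mi)
      viols[["country"]] <- viols[["country"]] +
        sum(r$country[mi] != row$country)
      checks[["season"]] <- checks[["season"]] + length(mi)
      viols[["season"]] <- viols[["season"]] + sum(!r[[row$season]][mi])
      if (row$attribute %in% allergens()) {
        checks[["allergy"]] <- checks[["allergy"]] + length(mi)
        viols[["allergy"]] <- viols[["allergy"]] +
          sum(r[[paste0("has_", row$attribute)]][mi])
      }
      if (row$attribute == "halal") {
        checks[["preference"]] <- checks[["preference"]] + length(mi)
        viols[["preference"]] <- viols[["preference"]] + sum(r$has_pork[mi])
      }
    }
  }
  data.frame(criterion = crit, checks = unname(checks),
             violations = unname(viols),
             accuracy = ifelse(checks > 0, 100 * (1 - viols / checks),
                               NA_real_))
}
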