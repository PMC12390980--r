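#' Weekly food-group and diversity rules
#'
#' Configuration of the constraints a seven-day plan must satisfy:
#' \itemize{
#'   \item at most one egg-containing dish per day;
#'   \item no clash group (white meat, red meat, pork, fish, pulses, pasta,
#'     rice) present at both lunch and dinner of the same day;
#'   \item tubers, rice, pasta and fish each at most 3 dish occurrences per
#'     week;
#'   \item the same dish at most once per day and at most 3 times per week;
#'   \item the same meal at most twice per week;
#'   \item the same whole-day meal sequence (ordered 5-tuple of meal ids) at
#'     most twice per week.
#' }
#'
#' @param egg_daily_max Maximum egg-containing dishes per day.
#' @param clash_groups Food groups barred from appearing at both lunch and
#'   dinner of one day.
#' @param weekly_capped_groups Named integer vector: food group -> maximum
#'   dish occurrences per week.
#' @param dish_daily_max,dish_weekly_max Per-dish repetition caps.
#' @param meal_weekly_max Per-meal repetition cap per week.
#' @param sequence_weekly_max Whole-day sequence repetition cap per week.
#' @return An object of class `weekly_rule_config`.
#' @export
weekly_rule_config <- function(egg_daily_max = 1L,
                               clash_groups = c("white_meat", "red_meat",
                                                "pork", "fish", "pulses",
                                                "pasta", "rice"),
                               weekly_capped_groups = c(tubers = 3L, rice = 3L,
                                                        pasta = 3L, fish = 3L),
                               dish_daily_max = 1L,
                               dish_weekly_max = 3L,
                               meal_weekly_max = 2L,
                               sequence_weekly_max = 2L) {
  if (is.list(weekly_capped_groups))    # e.g. parsed from YAML/JSON config
    weekly_capped_groups <- unlist(weekly_capped_groups)
  caps <- c(egg_daily_max, weekly_capped_groups, dish_daily_max,
            dish_weekly_max, meal_weekly_max, sequence_weekly_max)
  if (any(caps < 0)) stop_input("all rule caps must be non-negative")
  if (!all(clash_groups %in% food_groups()) ||
      !all(names(weekly_capped_groups) %in% food_groups()))
    stop_input("rule groups must come from the food-group vocabulary")
  structure(list(egg_daily_max = egg_daily_max, clash_groups = clash_groups,
                 weekly_capped_groups = weekly_capped_groups,
                 dish_daily_max = dish_daily_max,
                 dish_weekly_max = dish_weekly_max,
                 meal_weekly_max = meal_weekly_max,
                 sequence_weekly_max = sequence_weekly_max),
            class = "weekly_rule_config")
}

# fast lookup tables: meal id -> dish ids; dish id -> groups
rule_tables <- function(db) {
  dish_groups <- stats::setNames(db$dishes$groups, db$dishes$id)
  meal_dishes <- stats::setNames(db$meals$dish_ids, db$meals$id)
  list(dish_groups = dish_groups, meal_dishes = meal_dishes)
}

day_meal_ids <- function(day) {
  if (is.data.frame(day)) unlist(day[1, meal_types()], use.names = FALSE)
  else as.character(day)[seq_len(5L)]
}

# dish ids of a day, with multiplicity, plus lunch/dinner group sets
day_dish_info <- function(day, rt) {
  ids <- day_meal_ids(day)
  dishes_by_slot <- rt$meal_dishes[ids]
  all_dishes <- unlist(dishes_by_slot, use.names = FALSE)
  groups_of <- function(dd) unlist(rt$dish_groups[dd], use.names = FALSE)
  list(meal_ids = ids,
       dishes = all_dishes,
       dish_groups = lapply(all_dishes, function(d) rt$dish_groups[[d]]),
       lunch_groups = unique(groups_of(dishes_by_slot[[3L]])),
       dinner_groups = unique(groups_of(dishes_by_slot[[5L]])))
}

#' Check the within-day rules for one daily plan
#'
#' Fails when the day contains more than the permitted number of
#' egg-containing dishes, when a clash group appears at both lunch and
#' dinner, or when any dish is repeated within the day.
#'
#' @param day A one-row scored plan (or character vector of 5 meal ids).
#' @param db A `meal_db`.
#' @param config A [weekly_rule_config()].
#' @param rt Internal precomputed lookup tables.
#' @return List with `pass` (logical) and `violations` (character labels).
#' @export
check_daily_rules <- function(day, db, config = weekly_rule_config(),
                              rt = rule_tables(db)) {
  info <- day_dish_info(day, rt)
  viol <- character(0)
  n_egg <- sum(vapply(info$dish_groups, function(g) "eggs" %in% g, logical(1)))
  if (n_egg > config$egg_daily_max)
    viol <- c(viol, sprintf("egg_daily:%d", n_egg))
  clash <- intersect(intersect(info$lunch_groups, info$dinner_groups),
                     config$clash_groups)
  if (length(clash))
    viol <- c(viol, paste0("lunch_dinner_clash:", clash))
  dup <- unique(info$dishes[duplicated(info$dishes)])
  over <- dup[vapply(dup, function(d) sum(info$dishes == d), integer(1)) >
                config$dish_daily_max]
  if (length(over))
    viol <- c(viol, paste0("dish_repeated_in_day:", over))
  list(pass = length(viol) == 0L, violations = viol)
}

#' Check whether a candidate day can join a partial week
#'
#' All weekly rules are "at most" caps, so the check asks whether adding the
#' candidate would push any count over its cap: capped food groups (dish
#' occurrences), per-dish, per-meal, and whole-day sequence repetitions.
#'
#' @param partial_week List of already-kept days (each a one-row plan).
#' @param candidate The candidate day.
#' @param db A `meal_db`.
#' @param config A [weekly_rule_config()].
#' @param rt Internal precomputed lookup tables.
#' @return List with `pass` and `violations`.
#' @export
check_weekly_rules <- function(partial_week, candidate, db,
                               config = weekly_rule_config(),
                               rt = rule_tables(db)) {
  days <- c(partial_week, list(candidate))
  infos <- lapply(days, day_dish_info, rt = rt)
  viol <- character(0)
  all_dishes <- unlist(lapply(infos, `[[`, "dishes"))
  grp_count <- function(g)
    sum(vapply(all_dishes, function(d) g %in% rt$dish_groups[[d]], logical(1)))
  for (g in names(config$weekly_capped_groups)) {
    n <- grp_count(g)
    if (n > config$weekly_capped_groups[[g]])
      viol <- c(viol, sprintf("weekly_group_cap:%s:%d", g, n))
  }
  dtab <- table(all_dishes)
  over <- names(dtab)[dtab > config$dish_weekly_max]
  if (length(over)) viol <- c(viol, paste0("dish_weekly_cap:", over))
  mtab <- table(unlist(lapply(infos, `[[`, "meal_ids")))
  over <- names(mtab)[mtab > config$meal_weekly_max]
  if (length(over)) viol <- c(viol, paste0("meal_weekly_cap:", over))
  seqs <- vapply(infos, function(x) paste(x$meal_ids, collapse = "|"),
                 character(1))
  stab <- table(seqs)
  if (any(stab > config$sequence_weekly_max))
    viol <- c(viol, paste0("sequence_weekly_cap:",
                           names(stab)[stab > config$sequence_weekly_max]))
  list(pass = length(viol) == 0L, violations = viol)
}

#' Assemble a seven-day plan from sorted candidates
#'
#' Single greedy first-fit pass: candidates are examined in score order and
#' kept when they pass the within-day rules and, incrementally, all weekly
#' caps against the days already kept. The pass stops as soon as seven days
#' are kept. If the list is exhausted first, a failure report is returned
#' with the number of days selected and a tally of the first rule each
#' rejected candidate violated. No backtracking is attempted.
#'
#' @param sorted_plans A scored, sorted `daily_np_set` (see
#'   [sort_daily_nps()]).
#' @param db A `meal_db`.
#' @param config A [weekly_rule_config()].
#' @return An object of class `weekly_np`: list with `days` (the kept rows),
#'   `provenance` (their indices in the sorted list), `complete` (exactly 7
#'   days found), `n_selected`, and `rejections` (named counts of first
#'   violated rules).
#' @export
assemble_week <- function(sorted_plans, db, config = weekly_rule_config()) {
  rt <- rule_tables(db)
  cnt <- function(vec, key) {          # named-counter read; absent key -> 0
    x <- vec[key]
    if (length(x) != 1L || is.na(x)) 0L else as.integer(x)
  }
  kept <- list(); kept_idx <- integer(0)
  # incremental counters
  grp_counts <- stats::setNames(integer(length(config$weekly_capped_groups)),
                                names(config$weekly_capped_groups))
  dish_counts <- integer(0); meal_counts <- integer(0); seq_counts <- integer(0)
  rejections <- integer(0)
  n <- if (is.null(sorted_plans)) 0L else nrow(sorted_plans)
  i <- 0L
  while (i < n && length(kept) < 7L) {
    i <- i + 1L
    day <- sorted_plans[i, , drop = FALSE]
    dc <- check_daily_rules(day, db, config, rt)
    if (!dc$pass) {
      first <- sub(":.*$", "", dc$violations[1L])
      rejections[first] <- cnt(rejections, first) + 1L
      next
    }
    info <- day_dish_info(day, rt)
    viol <- NULL
    for (g in names(grp_counts)) {
      add <- sum(vapply(info$dish_groups, function(x) g %in% x, logical(1)))
      if (grp_counts[[g]] + add > config$weekly_capped_groups[[g]]) {
        viol <- "weekly_group_cap"; break
      }
    }
    if (is.null(viol)) {
      dtab <- table(info$dishes)
      for (d in names(dtab)) {
        if (cnt(dish_counts, d) + dtab[[d]] > config$dish_weekly_max) {
          viol <- "dish_weekly_cap"; break
        }
      }
    }
    if (is.null(viol)) {
      for (mid in info$meal_ids) {
        if (cnt(meal_counts, mid) + sum(info$meal_ids == mid) >
            config$meal_weekly_max) {
          viol <- "meal_weekly_cap"; break
        }
      }
    }
    sq <- paste(info$meal_ids, collapse = "|")
    if (is.null(viol) &&
        cnt(seq_counts, sq) + 1L > config$sequence_weekly_max)
      viol <- "sequence_weekly_cap"
    if (!is.null(viol)) {
      rejections[viol] <- cnt(rejections, viol) + 1L
      next
    }
    # accept: update counters
    for (g in names(grp_counts))
      grp_counts[[g]] <- grp_counts[[g]] +
        sum(vapply(info$dish_groups, function(x) g %in% x, logical(1)))
    dtab <- table(info$dishes)
    for (d in names(dtab)) dish_counts[d] <- cnt(dish_counts, d) + dtab[[d]]
    for (mid in unique(info$meal_ids))
      meal_counts[mid] <- cnt(meal_counts, mid) + sum(info$meal_ids == mid)
    seq_counts[sq] <- cnt(seq_counts, sq) + 1L
    kept[[length(kept) + 1L]] <- day
    kept_idx <- c(kept_idx, i)
  }
  days <- if (length(kept)) do.call(rbind, kept) else sorted_plans[0, ]
  rownames(days) <- NULL
  structure(list(days = days, provenance = kept_idx,
                 complete = length(kept) == 7L, n_selected = length(kept),
                 rejections = rejections),
            class = "weekly_np")
}

#' @export
print.weekly_np <- function(x, ...) {
  status <- if (x$complete) "complete (7 days)"
            else sprintf("INCOMPLETE (%d day%s)", x$n_selected,
                         if (x$n_selected == 1L) "" else "s")
  cat(sprintf("<weekly_np> %s\n", status))
  if (nrow(x$days)) {
    show <- x$days[, c(meal_types(), intersect(c("tk", "dnps"), names(x$days)))]
    print(show)
  }
  if (length(x$rejections)) {
    cat("candidates rejected by first violated rule:\n")
    print(x$rejections)
  }
  invisible(x)
}

#' Independently verify a weekly plan
#'
#' Recomputes every daily and weekly rule from scratch with plain
#' set-and-counter logic, independent of the assembler's incremental
#' bookkeeping, and reports all violations found. An empty report means the
#' week satisfies every rule.
#'
#' @param week A `weekly_np`, or a data frame of days (one row per day).
#' @param db A `meal_db`.
#' @param config A [weekly_rule_config()].
#' @return Data frame of violations with columns `rule` and `detail`.
#' @export
verify_week <- function(week, db, config = weekly_rule_config()) {
  days <- if (inherits(week, "weekly_np")) week$days else week
  if (is.null(days) || nrow(days) == 0L)
    return(data.frame(rule = character(), detail = character()))
  rt <- rule_tables(db)
  viol <- list()
  note <- function(rule, detail)
    viol[[length(viol) + 1L]] <<- data.frame(rule = rule, detail = detail)
  # expand each day into its dish occurrences
  day_rows <- lapply(seq_len(nrow(days)), function(i) {
    mids <- unlist(days[i, meal_types()], use.names = FALSE)
    slots <- rep(meal_types(), times = lengths(rt$meal_dishes[mids]))
    data.frame(day = i, slot = slots,
               dish = unlist(rt$meal_dishes[mids], use.names = FALSE))
  })
  occ <- do.call(rbind, day_rows)
  occ$has_egg <- vapply(occ$dish, function(d) "eggs" %in% rt$dish_groups[[d]],
                        logical(1))
  for (i in seq_len(nrow(days))) {
    di <- occ[occ$day == i, ]
    if (sum(di$has_egg) > config$egg_daily_max)
      note("egg_daily", sprintf("day %d has %d egg dishes", i, sum(di$has_egg)))
    lunch_g <- unique(unlist(rt$dish_groups[di$dish[di$slot == "lunch"]]))
    dinner_g <- unique(unlist(rt$dish_groups[di$dish[di$slot == "dinner"]]))
    for (g in intersect(intersect(lunch_g, dinner_g), config$clash_groups))
      note("lunch_dinner_clash", sprintf("day %d: %s at lunch and dinner", i, g))
    dd <- table(di$dish)
    for (d in names(dd)[dd > config$dish_daily_max])
      note("dish_repeated_in_day", sprintf("day %d: dish %s x%d", i, d, dd[[d]]))
  }
  for (g in names(config$weekly_capped_groups)) {
    n <- sum(vapply(occ$dish, function(d) g %in% rt$dish_groups[[d]],
                    logical(1)))
    if (n > config$weekly_capped_groups[[g]])
      note("weekly_group_cap", sprintf("%s appears in %d dishes", g, n))
  }
  wd <- table(occ$dish)
  for (d in names(wd)[wd > config$dish_weekly_max])
    note("dish_weekly_cap", sprintf("dish %s x%d in week", d, wd[[d]]))
  mids_all <- unlist(days[, meal_types()], use.names = FALSE)
  wm <- table(mids_all)
  for (m in names(wm)[wm > config$meal_weekly_max])
    note("meal_weekly_cap", sprintf("meal %s x%d in week", m, wm[[m]]))
  seqs <- apply(days[, meal_types(), drop = FALSE], 1L, paste, collapse = "|")
  ws <- table(seqs)
  for (s in names(ws)[ws > config$sequence_weekly_max])
    note("sequence_weekly_cap", sprintf("day sequence repeated x%d", ws[[s]]))
  if (length(viol)) do.call(rbind, viol)
  else data.frame(rule = character(), detail = character())
}
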