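#' Filtering context
#'
#' Captures the hard filters applied before any scoring: cuisine, season,
#' allergies and the halal preference. Country and season are hard
#' restrictions; a meal is excluded for an allergy if ANY of its member
#' dishes carries the corresponding food group (strictest safe reading), and
#' under halal if any member dish carries pork.
#'
#' @param country Cuisine code, `"ES"` or `"TR"`.
#' @param season Exactly one of [seasons()].
#' @param allergies Subset of [allergens()]; multiple allergies are allowed.
#' @param halal Logical.
#' @return An object of class `filter_context`.
#' @export
filter_context <- function(country, season, allergies = character(),
                           halal = FALSE) {
  country <- match_one(country, countries(), "country")
  season <- match_one(season, seasons(), "season")
  if (!all(allergies %in% allergens()))
    stop_input("unknown allergy label(s): %s",
               paste(setdiff(allergies, allergens()), collapse = ", "))
  structure(list(country = country, season = season,
                 allergies = unique(allergies), halal = isTRUE(halal)),
            class = "filter_context")
}

#' Filter context from a user profile
#'
#' @param profile A [user_profile()].
#' @param season The season to plan for.
#' @return A `filter_context` mirroring the profile's country, allergies and
#'   halal preference.
#' @export
profile_context <- function(profile, season) {
  filter_context(profile$country, season, profile$allergies, profile$halal)
}

#' Restrict the meal pool by cuisine, season, allergies and preference
#'
#' A meal is eligible iff (i) its country equals the context country, (ii)
#' its flag for the context season is set, (iii) no member dish carries a
#' food group matching one of the context allergies, and (iv) under halal no
#' member dish carries pork. Eligible meals are bucketed by the five meal
#' slots. Empty buckets are legal output: they simply mean no daily plan can
#' be formed.
#'
#' @param db A `meal_db`.
#' @param ctx A [filter_context()].
#' @param resolved Optional pre-resolved meal table (internal reuse).
#' @return Named list of character vectors of eligible meal ids, one per
#'   slot in [meal_types()] order, with an `n` attribute of per-slot counts.
#' @export
#' @examples
#' db <- generate_fixture_db(fixture_spec("ES"), seed = 1)
#' av <- filter_meals(db, filter_context("ES", "winter"))
#' attr(av, "n")
filter_meals <- function(db, ctx, resolved = NULL) {
  stopifnot(inherits(ctx, "filter_context"))
  r <- resolved %||% resolve_meals(db)
  keep <- r$country == ctx$country & r[[ctx$season]]
  for (a in ctx$allergies) keep <- keep & !r[[paste0("has_", a)]]
  if (ctx$halal) keep <- keep & !r$has_pork
  out <- lapply(meal_types(), function(tp) r$id[keep & r$type == tp])
  names(out) <- meal_types()
  attr(out, "n") <- vapply(out, length, integer(1))
  attr(out, "context") <- ctx
  out
}

#' Per-slot availability counts for every season/attribute combination
#'
#' Convenience wrapper reproducing the availability-matrix view of a
#' database: for each season and each single attribute (no restriction, one
#' allergy, or halal) the number of eligible meals per slot.
#'
#' @param db A `meal_db`.
#' @param country Cuisine code.
#' @return Data frame with columns `season`, `attribute` and one count
#'   column per meal slot.
#' @export
availability_counts <- function(db, country) {
  r <- resolve_meals(db)
  attrs <- c("none", allergens(), "halal")
  rows <- list()
  for (s in seasons()) for (a in attrs) {
    ctx <- filter_context(country, s,
                          allergies = if (a %in% allergens()) a else character(),
                          halal = a == "halal")
    n <- attr(filter_meals(db, ctx, resolved = r), "n")
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(season = s, attribute = a), as.data.frame(as.list(n)))
  }
  do.call(rbind, rows)
}
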