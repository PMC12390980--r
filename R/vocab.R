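#' Controlled vocabularies
#'
#' The package uses fixed vocabularies for dish food groups, meal slots,
#' seasons, cuisines and allergens. All labels are lower-case snake_case in
#' code and on disk.
#'
#' @format `food_groups()` returns the 16 dish-level food-group labels;
#'   `meal_types()` the five daily meal slots in chronological order;
#'   `seasons()` the four seasons; `countries()` the supported cuisines;
#'   `allergens()` the four allergy labels recognised in user profiles.
#' @return A character vector.
#' @examples
#' food_groups()
#' meal_types()
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
food_groups <- function() {
  c("white_meat", "red_meat", "pork", "fish", "pulses", "dairy", "eggs",
    "pasta", "rice", "tubers", "soups", "cereals", "fruit", "nuts",
    "raw_vegetables", "cooked_vegetables")
}

#' @rdname vocabularies
#' @export
meal_types <- function() {
  c("breakfast", "morning_snack", "lunch", "afternoon_snack", "dinner")
}

#' @rdname vocabularies
#' @export
seasons <- function() {
  c("winter", "spring", "summer", "autumn")
}

#' @rdname vocabularies
#' @export
countries <- function() {
  c("ES", "TR")
}

#' @rdname vocabularies
#' @export
allergens <- function() {
  c("milk", "eggs", "fish", "nuts")
}

# groups that mark a dish as carrying fruit or vegetables
fv_groups <- function() c("fruit", "raw_vegetables", "cooked_vegetables")

# allergen label -> food group that triggers it (pork covers the halal rule)
allergen_group_map <- function() {
  c(milk = "dairy", eggs = "eggs", fish = "fish", nuts = "nuts", pork = "pork")
}

pal_levels <- function() c(1.2, 1.375, 1.55, 1.725, 1.9)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

match_one <- function(x, choices, what) {
  if (length(x) != 1L || is.na(x) || !x %in% choices)
    stop_input("%s must be one of: %s", what, paste(choices, collapse = ", "))
  x
}
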