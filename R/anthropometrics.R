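#' Age from calendar years
#'
#' Age is derived by calendar-year subtraction; no birth date beyond the year
#' is collected, so a user born in December counts the same as one born in
#' January. The reference year is injectable for reproducibility.
#'
#' @param yob Year of birth (calendar year).
#' @param current_year Reference calendar year (default: current system year).
#' @return Age in whole years.
#' @export
#' @examples
#' compute_age(1994, 2024)
compute_age <- function(yob, current_year = as.integer(format(Sys.Date(), "%Y"))) {
  if (!is.numeric(yob) || !is.numeric(current_year))
    stop_input("yob and current_year must be numeric")
  if (any(current_year < yob))
    stop_input("year of birth (%s) lies in the future of %s", yob, current_year)
  current_year - yob
}

#' Body mass index
#'
#' @param weight Body weight in kilograms.
#' @param height Height in metres.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' compute_bmi(70, 1.75)
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop_input("weight must be a positive number of kilograms")
  if (any(!is.finite(height)) || any(height <= 0))
    stop_input("height must be a positive number of metres")
  weight / height^2
}

#' Basal metabolic rate (Harris-Benedict)
#'
#' Sex-specific Harris-Benedict equations. The profile stores height in
#' metres; the Harris-Benedict coefficients expect centimetres, so the
#' conversion happens here and only here.
#'
#' @param sex `"male"` or `"female"` (vectorised).
#' @param weight Body weight, kg.
#' @param height Height, metres.
#' @param age Age, years.
#' @return BMR in kcal/day.
#' @export
#' @examples
#' compute_bmr("male", 70, 1.75, 30)
compute_bmr <- function(sex, weight, height, age) {
  if (!all(sex %in% c("male", "female")))
    stop_input("sex must be 'male' or 'female'")
  h_cm <- height * 100
  bmr <- ifelse(sex == "male",
    88.362 + 13.397 * weight + 4.799 * h_cm - 5.677 * age,
    447.593 + 9.247 * weight + 3.098 * h_cm - 4.330 * age)
  if (any(weight > 0 & height > 0 & bmr <= 0))
    stop_input("implausible profile: Harris-Benedict BMR is non-positive")
  bmr
}

#' Daily energy requirement
#'
#' DER is the activity-scaled BMR with a flat +/-500 kcal adjustment by BMI
#' band: underweight users (BMI < 18.5) get +500 kcal to support weight gain,
#' users with BMI > 24.99 get -500 kcal to promote weight loss, and the
#' healthy band 18.5 <= BMI <= 24.99 (both bounds inclusive) is unadjusted.
#'
#' @param bmr Basal metabolic rate, kcal/day.
#' @param pal Physical activity level multiplier, one of 1.2, 1.375, 1.55,
#'   1.725, 1.9.
#' @param bmi Body mass index, kg/m^2.
#' @return DER in kcal/day.
#' @export
#' @examples
#' compute_der(2000, 1.2, 22)   # healthy band: BMR * PAL
#' compute_der(2000, 1.2, 17)   # underweight: +500 kcal
compute_der <- function(bmr, pal, bmi) {
  if (any(!is.finite(bmr)) || any(bmr <= 0))
    stop_input("bmr must be positive")
  if (!all(pal %in% pal_levels()))
    stop_input("pal must be one of %s", paste(pal_levels(), collapse = ", "))
  base <- bmr * pal
  adj <- ifelse(bmi < 18.5, 500, ifelse(bmi > 24.99, -500, 0))
  base + adj
}

#' Build a user profile with derived energy quantities
#'
#' Validates raw inputs and attaches the derived age, BMI, BMR and DER.
#'
#' @param sex `"male"` or `"female"`.
#' @param yob Year of birth.
#' @param height Height in metres (plausible range 0.5-2.5 m).
#' @param weight Weight in kilograms (plausible range 20-300 kg).
#' @param pal Physical activity level multiplier.
#' @param allergies Character vector, subset of [allergens()].
#' @param halal Logical; exclude pork-containing dishes when `TRUE`.
#' @param country Cuisine, `"ES"` or `"TR"`.
#' @param current_year Reference year for the age computation.
#' @return A list of class `user_profile` with the inputs plus `age`, `bmi`,
#'   `bmr` and `der`.
#' @export
#' @examples
#' user_profile("male", 1994, 1.75, 70, 1.55, country = "ES",
#'              current_year = 2024)
user_profile <- function(sex, yob, height, weight, pal,
                         allergies = character(), halal = FALSE,
                         country = "ES",
                         current_year = as.integer(format(Sys.Date(), "%Y"))) {
  sex <- match_one(sex, c("male", "female"), "sex")
  country <- match_one(country, countries(), "country")
  if (height <= 0.5 || height >= 2.5)
    stop_input("height %.2f m outside plausible range (0.5, 2.5)", height)
  if (weight <= 20 || weight >= 300)
    stop_input("weight %.1f kg outside plausible range (20, 300)", weight)
  if (!all(allergies %in% allergens()))
    stop_input("unknown allergy label(s): %s",
               paste(setdiff(allergies, allergens()), collapse = ", "))
  age <- compute_age(yob, current_year)
  bmi <- compute_bmi(weight, height)
  bmr <- compute_bmr(sex, weight, height, age)
  der <- compute_der(bmr, pal, bmi)
  structure(list(sex = sex, yob = yob, height = height, weight = weight,
                 pal = pal, allergies = allergies, halal = isTRUE(halal),
                 country = country, age = age, bmi = bmi, bmr = bmr,
                 der = der),
            class = "user_profile")
}

#' @export
print.user_profile <- function(x, ...) {
  cat(sprintf("<user_profile> %s, %s, age %d\n", x$sex, x$country, x$age))
  cat(sprintf("  BMI %.1f kg/m2 | BMR %.0f kcal/d | PAL %.3f | DER %.0f kcal/d\n",
              x$bmi, x$bmr, x$pal, x$der))
  if (length(x$allergies))
    cat("  allergies:", paste(x$allergies, collapse = ", "), "\n")
  if (x$halal) cat("  preference: halal\n")
  invisible(x)
}

#' Read a user profile from JSON
#'
#' Expected keys: `sex`, `yob`, `height_m`, `weight_kg`, `pal`, `allergies`,
#' `halal`, `country`. Derived fields in the file are ignored and recomputed.
#'
#' @param path Path to a JSON file.
#' @param current_year Reference year for age.
#' @return A `user_profile`.
#' @export
read_profile <- function(path, current_year = as.integer(format(Sys.Date(), "%Y"))) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  user_profile(sex = p$sex, yob = p$yob, height = p$height_m,
               weight = p$weight_kg, pal = p$pal,
               allergies = as.character(p$allergies %||% character()),
               halal = isTRUE(p$halal), country = p$country %||% "ES",
               current_year = current_year)
}
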