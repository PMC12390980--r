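#' Scoring configuration for daily nutrition plans
#'
#' Holds the expert-validated bounds and penalties used to score a daily
#' plan: protein 15-20% and fat 25-40% of the daily energy requirement
#' (Atwater conversion 4 kcal/g protein, 9 kcal/g fat), 5-10 dishes with
#' fruit or vegetables, penalties of 50 score points for each macronutrient
#' band missed and 100 for the fruit-and-vegetable band, and the cap on the
#' number of candidate daily plans drawn from large pools.
#'
#' @param protein_bounds Inclusive protein energy-fraction interval.
#' @param fat_bounds Inclusive fat energy-fraction interval.
#' @param fv_bounds Inclusive bounds on the count of fruit/vegetable dishes.
#' @param macro_penalty Score points added when protein or fat is out of band.
#' @param fv_penalty Score points added when the fruit/vegetable count is
#'   out of band.
#' @param sample_cap Maximum number of daily plans considered; larger pools
#'   are sampled uniformly without replacement.
#' @param atwater_protein,atwater_fat Energy conversion factors, kcal/g.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(protein_bounds = c(0.15, 0.20),
                           fat_bounds = c(0.25, 0.40),
                           fv_bounds = c(5, 10),
                           macro_penalty = 50,
                           fv_penalty = 100,
                           sample_cap = 100000,
                           atwater_protein = 4,
                           atwater_fat = 9) {
  stopifnot(length(protein_bounds) == 2L, protein_bounds[1] <= protein_bounds[2],
            length(fat_bounds) == 2L, fat_bounds[1] <= fat_bounds[2],
            length(fv_bounds) == 2L, fv_bounds[1] <= fv_bounds[2])
  if (macro_penalty < 0 || fv_penalty < 0)
    stop_input("penalties must be non-negative")
  if (sample_cap < 1) stop_input("sample_cap must be >= 1")
  structure(list(protein_bounds = protein_bounds, fat_bounds = fat_bounds,
                 fv_bounds = fv_bounds, macro_penalty = macro_penalty,
                 fv_penalty = fv_penalty, sample_cap = sample_cap,
                 atwater_protein = atwater_protein, atwater_fat = atwater_fat),
            class = "scoring_config")
}

#' Number of possible daily plans
#'
#' A daily plan takes one meal per slot, so the pool size is the product of
#' the five per-slot availability counts.
#'
#' @param counts Numeric vector of five non-negative per-slot counts.
#' @return The product, as a double (pools can exceed integer range).
#' @export
#' @examples
#' count_daily_nps(c(14, 7, 21, 6, 15))
count_daily_nps <- function(counts) {
  if (length(counts) != 5L || any(counts < 0))
    stop_input("counts must be five non-negative numbers")
  prod(as.numeric(counts))
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' Enumerate or sample candidate daily plans
#'
#' When the full Cartesian product of the availability buckets fits under
#' `config$sample_cap` the whole pool is enumerated; otherwise `sample_cap`
#' distinct combinations are drawn uniformly without replacement. Each plan
#' carries its nutrient totals (`tk` kcal, protein and fat grams) and the
#' count of member dishes containing fruit or vegetables (`tfv`).
#'
#' @param db A `meal_db`.
#' @param buckets Availability buckets from [filter_meals()].
#' @param config A [scoring_config()].
#' @param seed Optional integer seed controlling the sampling draw.
#' @param resolved Optional pre-resolved meal table (internal reuse).
#' @return A data frame of class `daily_np_set` with one row per plan and
#'   columns for the five slot meal ids plus `tk`, `protein_g`, `fat_g`,
#'   `tfv`. Zero rows (with attribute `no_candidates = TRUE`) when any
#'   bucket is empty.
#' @export
enumerate_daily_nps <- function(db, buckets, config = scoring_config(),
                                seed = NULL, resolved = NULL) {
  counts <- vapply(buckets, length, integer(1))
  r <- resolved %||% resolve_meals(db)
  empty <- data.frame(matrix(character(), 0, 5,
                             dimnames = list(NULL, meal_types())),
                      stringsAsFactors = FALSE)
  empty$tk <- numeric(0); empty$protein_g <- numeric(0)
  empty$fat_g <- numeric(0); empty$tfv <- integer(0)
  class(empty) <- c("daily_np_set", "data.frame")
  if (any(counts == 0L)) {
    attr(empty, "no_candidates") <- TRUE
    return(empty)
  }
  total <- count_daily_nps(counts)
  if (total <= config$sample_cap) {
    idx <- as.matrix(expand.grid(lapply(counts, seq_len),
                                 KEEP.OUT.ATTRS = FALSE))
  } else {
    k <- config$sample_cap
    idx <- with_seed(seed, {
      if (total <= .Machine$integer.max) {
        lin <- sample.int(total, k) - 1
        decode_mixed_radix(lin, counts)
      } else {
        # pools beyond integer range: rejection-sample distinct tuples
        seen <- character(0); rows <- NULL
        while (is.null(rows) || nrow(rows) < k) {
          m <- ceiling((k - length(seen)) * 1.2) + 16L
          draw <- vapply(counts, function(n) sample.int(n, m, replace = TRUE),
                         integer(m))
          key <- apply(draw, 1L, paste, collapse = "/")
          new <- !duplicated(key) & !key %in% seen
          seen <- c(seen, key[new])
          rows <- rbind(rows, draw[new, , drop = FALSE])
        }
        rows[seq_len(k), , drop = FALSE]
      }
    })
  }
  plans <- data.frame(matrix("", nrow(idx), 5,
                             dimnames = list(NULL, meal_types())),
                      stringsAsFactors = FALSE)
  tk <- 0; pg <- 0; fg <- 0; fv <- 0L
  for (s in seq_along(meal_types())) {
    ids <- buckets[[s]]
    ri <- match(ids, r$id)[idx[, s]]
    plans[[s]] <- r$id[ri]
    tk <- tk + r$kcal[ri]; pg <- pg + r$protein[ri]; fg <- fg + r$fat[ri]
    fv <- fv + r$n_fv_dishes[ri]
  }
  plans$tk <- tk; plans$protein_g <- pg; plans$fat_g <- fg; plans$tfv <- fv
  class(plans) <- c("daily_np_set", "data.frame")
  plans
}

# decode 0-based linear indices into 1-based mixed-radix tuples
decode_mixed_radix <- function(lin, counts) {
  out <- matrix(0L, length(lin), length(counts))
  for (s in seq_along(counts)) {
    out[, s] <- as.integer(lin %% counts[s]) + 1L
    lin <- lin %/% counts[s]
  }
  out
}

#' Caloric score
#'
#' Absolute deviation, in kcal, of the plan's total energy from the user's
#' daily energy requirement. The raw difference is used (no normalisation),
#' so caloric mismatch dominates the fixed band penalties for large
#' deviations.
#'
#' @param der Daily energy requirement, kcal.
#' @param tk Total kcal of the daily plan.
#' @return `abs(der - tk)`.
#' @export
score_caloric <- function(der, tk) {
  if (any(der <= 0)) stop_input("der must be positive")
  abs(der - tk)
}

#' Protein score
#'
#' @param tpp Protein energy as a fraction of DER.
#' @param config A [scoring_config()].
#' @return 0 inside the inclusive protein band, otherwise the macronutrient
#'   penalty (default 50).
#' @export
score_protein <- function(tpp, config = scoring_config()) {
  b <- config$protein_bounds
  ifelse(tpp >= b[1] & tpp <= b[2], 0, config$macro_penalty)
}

#' Fat score
#'
#' @param tfp Fat energy as a fraction of DER.
#' @param config A [scoring_config()].
#' @return 0 inside the inclusive fat band, otherwise the macronutrient
#'   penalty (default 50).
#' @export
score_fat <- function(tfp, config = scoring_config()) {
  b <- config$fat_bounds
  ifelse(tfp >= b[1] & tfp <= b[2], 0, config$macro_penalty)
}

#' Fruits-and-vegetables score
#'
#' @param tfv Count of dishes in the daily plan containing fruit or
#'   vegetables.
#' @param config A [scoring_config()].
#' @return 0 inside the inclusive band (default 5-10 dishes), otherwise the
#'   fruit-and-vegetable penalty (default 100).
#' @export
score_fv <- function(tfv, config = scoring_config()) {
  b <- config$fv_bounds
  ifelse(tfv >= b[1] & tfv <= b[2], 0, config$fv_penalty)
}

#' Score a set of daily plans against a user's energy requirement
#'
#' Computes the protein and fat energy fractions of DER (`tpp`, `tfp`), the
#' four sub-scores and the total daily-plan score
#' `dnps = cs + ps + fs + fvs`. Lower is better; 0 means the plan meets the
#' caloric target exactly and every band constraint.
#'
#' @param plans A `daily_np_set` from [enumerate_daily_nps()].
#' @param der Daily energy requirement, kcal.
#' @param config A [scoring_config()].
#' @return The input with columns `tpp`, `tfp`, `cs`, `ps`, `fs`, `fvs`,
#'   `dnps` appended.
#' @export
score_daily_nps <- function(plans, der, config = scoring_config()) {
  if (length(der) != 1L || !is.finite(der) || der <= 0)
    stop_input("der must be a single positive number")
  plans$tpp <- config$atwater_protein * plans$protein_g / der
  plans$tfp <- config$atwater_fat * plans$fat_g / der
  plans$cs <- score_caloric(der, plans$tk)
  plans$ps <- score_protein(plans$tpp, config)
  plans$fs <- score_fat(plans$tfp, config)
  plans$fvs <- score_fv(plans$tfv, config)
  plans$dnps <- plans$cs + plans$ps + plans$fs + plans$fvs
  attr(plans, "der") <- der
  plans
}

#' Score a single daily plan
#'
#' @param np A one-row `daily_np_set` (totals populated).
#' @param der Daily energy requirement, kcal.
#' @param config A [scoring_config()].
#' @return The plan's total score (DNPS).
#' @export
score_daily_np <- function(np, der, config = scoring_config()) {
  score_daily_nps(np, der, config)$dnps
}

#' Sort daily plans from most to least suitable
#'
#' Ascending by total score; ties are broken lexicographically on the
#' 5-tuple of meal ids so the order is deterministic and independent of
#' enumeration order.
#'
#' @param plans A scored `daily_np_set`.
#' @return The same rows, reordered.
#' @export
sort_daily_nps <- function(plans) {
  if (!"dnps" %in% names(plans))
    stop_input("plans must be scored before sorting (missing 'dnps')")
  o <- do.call(order, c(list(plans$dnps),
                        unname(as.list(plans[meal_types()])),
                        list(method = "radix")))
  out <- plans[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
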