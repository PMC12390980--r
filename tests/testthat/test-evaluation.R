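# A shared scaled-down cohort run over the Spanish fixture: 6 profiles per
# stratum, two seasons, small sampling cap. Reused by several tests.
small_report <- local({
  cohort <- generate_cohort(cohort_spec(per_stratum = 50), seed = 5)
  cohort <- cohort[cohort$country == "ES", ]
  # keep a representative subset per attribute to stay fast
  keep <- unlist(lapply(split(seq_len(nrow(cohort)),
                              paste(cohort$sex, cohort$attribute)),
                        utils::head, 3))
  run_experiment(es_fixture, cohort[keep, ], c("winter", "summer"),
                 scoring_config(sample_cap = 2000), seed = 9)
})

test_that("report arithmetic is self-consistent", {
  st <- small_report$strata
  expect_true(all(st$acceptable_weekly <= st$corresponding_weekly))
  expect_equal(st$corresponding_daily, 7 * st$acceptable_weekly)
  expect_equal(st$pct_acceptable,
               100 * st$acceptable_weekly / st$corresponding_weekly)
  pcts <- c(st$pct_acceptable, st$mean_caloric_agreement, st$fat_within,
            st$protein_within, st$fv_within)
  expect_true(all(is.na(pcts) | (pcts >= 0 & pcts <= 100)))
  # every profile is attempted once per requested season
  expect_equal(nrow(small_report$runs),
               2 * length(unique(small_report$runs$profile_id)))
})

test_that("acceptable weeks all pass the independent verifier", {
  d <- small_report$daily
  skip_if(is.null(d), "no acceptable plans in the scaled-down run")
  for (pid in unique(d$profile_id)[1:5]) {
    for (s in unique(d$season[d$profile_id == pid])) {
      week <- d[d$profile_id == pid & d$season == s, ]
      expect_equal(nrow(week), 7)
      expect_equal(nrow(verify_week(week, es_fixture)), 0,
                   label = paste(pid, s))
    }
  }
})

test_that("strata with an empty filtered bucket yield exactly 0% acceptable", {
  st <- small_report$strata
  milk <- st[st$attribute == "milk", ]
  expect_true(all(milk$pct_acceptable == 0))   # 0 winter/summer ES breakfasts
  none <- st[st$attribute == "none", ]
  expect_true(all(none$pct_acceptable >= 50))
})

test_that("caloric agreement follows its defining formula", {
  expect_equal(mean_caloric_agreement(2000, 2000), 100)
  expect_equal(mean_caloric_agreement(1800, 2000), 90)
  expect_equal(mean_caloric_agreement(c(2000, 1800), c(2000, 2000)), 95)
  expect_true(is.na(mean_caloric_agreement(numeric(0), numeric(0))))
  # floored at zero for absurd deviations
  expect_equal(mean_caloric_agreement(10000, 2000), 0)
})

test_that("within-range rates count plans inside each band", {
  d <- data.frame(tfp = c(0.30, 0.45, 0.30, 0.30), tpp = rep(0.18, 4),
                  tfv = c(6, 6, 4, 6))
  wr <- within_range_rates(d)
  expect_equal(wr[["fat"]], 75)
  expect_equal(wr[["protein"]], 100)
  expect_equal(wr[["fruit_veg"]], 75)
  expect_true(all(is.na(within_range_rates(d[0, ]))))
  # plans with zero score are inside every band
  dd <- small_report$daily
  skip_if(is.null(dd), "no acceptable plans")
  zero <- dd[dd$dnps == 0, ]
  if (nrow(zero) > 0)
    expect_equal(unname(within_range_rates(zero)), c(100, 100, 100))
})

test_that("the filtering audit reports 100% on an uncorrupted run", {
  audit <- filtering_accuracy_audit(small_report$daily, es_fixture)
  applied <- audit[audit$checks > 0, ]
  expect_gt(nrow(applied), 0)
  expect_true(all(applied$accuracy == 100))
  expect_true(all(applied$violations == 0))
})

test_that("the audit detects deliberately injected violations", {
  d <- small_report$daily
  skip_if(is.null(d) || !any(d$attribute == "halal"), "no halal stratum")
  # inject a pork-carrying meal into a halal user's plan
  r <- nutriplanr:::resolve_meals(es_fixture)
  pork_meal <- r$id[r$has_pork & r$type == "lunch"][1]
  skip_if(is.na(pork_meal), "fixture has no pork lunch")
  i <- which(d$attribute == "halal")[1]
  d$lunch[i] <- pork_meal
  audit <- filtering_accuracy_audit(d, es_fixture)
  expect_lt(audit$accuracy[audit$criterion == "preference"], 100)
  expect_equal(audit$violations[audit$criterion == "preference"], 1)
  # and a wrong-country meal
  d2 <- small_report$daily
  tr_meal <- tr_fixture$meals$id[tr_fixture$meals$type == "dinner"][1]
  db_both <- meal_database(rbind(es_fixture$dishes, tr_fixture$dishes),
                           rbind(es_fixture$meals, tr_fixture$meals))
  d2$dinner[1] <- tr_meal
  audit2 <- filtering_accuracy_audit(d2, db_both)
  expect_lt(audit2$accuracy[audit2$criterion == "country"], 100)
})

test_that("an empty recommendation set gives a vacuous audit", {
  audit <- filtering_accuracy_audit(NULL, es_fixture)
  expect_true(all(audit$checks == 0))
  expect_true(all(is.na(audit$accuracy)))
})

test_that("recommend_week is deterministic and fails cleanly on empty pools", {
  prof <- test_profile(der = 2400)
  w1 <- recommend_week(prof, es_fixture, "winter",
                       scoring_config(sample_cap = 2000), seed = 4)
  w2 <- recommend_week(prof, es_fixture, "winter",
                       scoring_config(sample_cap = 2000), seed = 4)
  expect_true(w1$complete)
  expect_identical(w1$days, w2$days)
  milk <- recommend_week(test_profile(allergies = "milk"), es_fixture,
                         "winter", seed = 4)
  expect_false(milk$complete)
  expect_equal(milk$n_selected, 0)
})
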