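tab <- mdb_reference_tables()

test_that("frequency categories map deterministically and monotonically", {
  expect_identical(frequency_to_annual("more_than_two_per_week"), 144)
  expect_identical(frequency_to_annual("never"), 0)
  m <- default_frequency_map()
  expect_true(all(diff(m) > 0))
  expect_error(frequency_to_annual("sometimes"), "unknown")
})

test_that("activity weights honour degenerate and empty inputs", {
  sv <- data.frame(
    respondent_id = c("r1", "r2"), usable = TRUE, uses_ebird = TRUE,
    birdwatches_in_basin = TRUE, group_category = "alone",
    day_trip_frequency_category = "weekly",
    overnight_trip_frequency_category = "never",
    per_day_expenditure_day_trip = 50, per_day_expenditure_overnight = 0,
    annual_expenditure_day_trip = 2400, annual_expenditure_overnight = 0)
  w <- activity_weights(sv, "ebird")
  expect_equal(unname(w["alone.day"]), 1)
  expect_equal(sum(w), 1)
  expect_error(activity_weights(sv, "nonebird"), "no usable")
})

test_that("weights converge to the generating probabilities", {
  cfg <- small_cfg(seed = 55,
                   survey_params = list(n_respondents = 10000L,
                                        p_usable = 1))
  sv <- sim_survey(cfg)
  w <- activity_weights(sv, "ebird")
  sp <- cfg$survey_params
  # truth: group shares (excluding >5 groups) times the common day-trip
  # share implied by the frequency-category distributions
  g <- sp$group_probs_ebird[c("alone", "pair", "group2_5")]
  g <- g / sum(g)
  m <- default_frequency_map()
  day <- sum(sp$day_freq_probs * m)
  on <- sum(sp$overnight_freq_probs * m)
  share_day <- day / (day + on)
  truth <- as.vector(rbind(g * share_day, g * (1 - share_day)))
  names(truth) <- as.vector(rbind(paste0(names(g), ".day"),
                                  paste0(names(g), ".overnight")))
  expect_lt(max(abs(w[names(truth)] - truth)), 0.02)
})

test_that("published worked example reproduces to printed precision", {
  e_day_e <- per_visit_day_expenditure(tab$weights$ebird,
                                       tab$per_day_medians$ebird)
  e_day_n <- per_visit_day_expenditure(tab$weights$nonebird,
                                       tab$per_day_medians$nonebird)
  expect_lt(abs(e_day_e - 98.11), 0.05)
  expect_lt(abs(e_day_n - 99.27), 0.05)
  ann_e <- annual_expenditure(tab$weights$ebird, tab$annual_medians$ebird)
  ann_n <- annual_expenditure(tab$weights$nonebird,
                              tab$annual_medians$nonebird)
  expect_lt(abs(ann_e - 1554), 1)
  expect_lt(abs(ann_n - 1184), 1)
  expect_lt(abs(extrapolation_factor(26.5, 69.1) - 0.383), 1e-3)
})

test_that("weighted expenditures are convex combinations of cell costs", {
  w <- tab$weights$ebird
  med <- tab$per_day_medians$ebird
  out <- per_visit_day_expenditure(w, med)
  expect_gte(out, min(med))
  expect_lte(out, max(med))
  flat <- stats::setNames(rep(42, length(w)), names(w))
  expect_equal(per_visit_day_expenditure(w, flat), 42)
  one <- stats::setNames(c(1, rep(0, length(w) - 1)), names(w))
  expect_equal(annual_expenditure(one, med), unname(med[1]))
  expect_error(per_visit_day_expenditure(w, med[-1]), "alone.day")
})

test_that("cell medians use the lower middle order statistic", {
  sv <- data.frame(
    respondent_id = sprintf("r%d", 1:4), usable = TRUE, uses_ebird = TRUE,
    birdwatches_in_basin = TRUE, group_category = "alone",
    day_trip_frequency_category = "weekly",
    overnight_trip_frequency_category = "never",
    per_day_expenditure_day_trip = c(10, 20, 30, 40),
    per_day_expenditure_overnight = 5,
    annual_expenditure_day_trip = 100, annual_expenditure_overnight = 0)
  med <- cell_medians(sv, "ebird")
  expect_equal(unname(med["alone.day"]), 20)  # lower of the two middles
})

test_that("extrapolation and site totals follow the stated arithmetic", {
  expect_equal(extrapolation_factor(50, 50), 1)
  expect_equal(extrapolation_factor(20, 40), 2 * extrapolation_factor(10, 40))
  expect_error(extrapolation_factor(10, 0), "positive")

  expect_equal(site_annual_expenditure(0, 0.383, 98.11, 99.27), 0)
  expect_equal(site_annual_expenditure(1000, 0.383, 98.11, 99.27),
               98110 + 38020.41, tolerance = 1e-9)
  expect_equal(site_annual_expenditure(2000, 0.383, 98.11, 99.27),
               2 * site_annual_expenditure(1000, 0.383, 98.11, 99.27))
  expect_error(site_annual_expenditure(-1, 0.4, 1, 1), "non-negative")
})

test_that("scenario deltas scale the base and respect the ns sentinel", {
  sc <- structure(list(hotspot_id = "h01", chain = "direct",
                       median_pct_change = -10, p5_pct_change = -20,
                       p95_pct_change = 5, ns = FALSE),
                  class = "bud_scenario")
  d <- scenario_expenditure_delta(10000, sc)
  expect_equal(d$median, -1000)
  expect_equal(d$p5, -2000)
  expect_equal(d$p95, 500)
  expect_true(d$p5 <= d$median && d$median <= d$p95)

  zero <- sc; zero$median_pct_change <- 0
  expect_equal(scenario_expenditure_delta(10000, zero)$median, 0)

  nssc <- sc; nssc$ns <- TRUE
  dn <- scenario_expenditure_delta(10000, nssc)
  expect_true(dn$ns)
  expect_true(is.na(dn$median))
})
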