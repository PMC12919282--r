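make_weather <- function(hotspot, cells, dates, rain_fun, tmax_fun) {
  rows <- list()
  k <- 0
  for (cc in seq_len(cells)) for (i in seq_along(dates)) {
    k <- k + 1
    rows[[k]] <- data.frame(hotspot_id = hotspot,
                            cell_id = sprintf("c%02d", cc),
                            date = dates[i], rain_mm = rain_fun(cc, i),
                            tmax_c = tmax_fun(cc, i))
  }
  do.call(rbind, rows)
}

april <- seq(EPOCH, EPOCH + 29, by = "day")

test_that("monthly rainfall is the across-cell mean summed over days", {
  w1 <- make_weather("h1", 1, april, function(cc, i) 1, function(cc, i) 25)
  expect_equal(monthly_rain(w1, "h1", EPOCH, 1)$rain_mm, 30)
  # two cells at 0 and 2 mm: daily mean 1 mm, monthly total 30 mm
  w2 <- make_weather("h1", 2, april, function(cc, i) 2 * (cc - 1),
                     function(cc, i) 25)
  expect_equal(monthly_rain(w2, "h1", EPOCH, 1)$rain_mm, 30)
})

test_that("monthly temperature is the mean of daily cell means", {
  w <- make_weather("h1", 2, april, function(cc, i) 0,
                    function(cc, i) if (cc == 1) 20 else 30)
  expect_equal(monthly_tmax(w, "h1", EPOCH, 1)$tmax_c, 25)
})

test_that("a missing day raises a gap error naming the date", {
  w <- make_weather("h1", 1, april[-10], function(cc, i) 1,
                    function(cc, i) 25)
  expect_error(monthly_rain(w, "h1", EPOCH, 1), "2013-04-10")
})

test_that("monthly aggregation equals a naive double loop", {
  cfg <- small_cfg(seed = 44, n_months = 5, cells = 3)
  w <- sim_weather(cfg)
  rain <- monthly_rain(w, "h01", cfg$epoch, 5)
  tmax <- monthly_tmax(w, "h01", cfg$epoch, 5)
  for (m in 1:5) {
    days <- seq(budwatch:::month_start(m, cfg$epoch),
                by = "day",
                length.out = budwatch:::days_in_month(m, cfg$epoch))
    tot <- 0; avg <- 0
    for (d in seq_along(days)) {
      sub <- w[w$date == days[d], ]
      tot <- tot + mean(sub$rain_mm)
      avg <- avg + mean(sub$tmax_c)
    }
    expect_equal(rain$rain_mm[m], tot, tolerance = 1e-12)
    expect_equal(tmax$tmax_c[m], avg / length(days), tolerance = 1e-12)
  }
})

test_that("wet percentage scales by the maximum over valid months", {
  wa <- data.frame(hotspot_id = "h1", month_index = 1:3,
                   observed_wet_area = c(10, 20, 5),
                   visible_fraction = c(0.9, 0.8, 0.7))
  wp <- wet_percentage(wa, "h1")
  expect_equal(wp$wet_pct, c(50, 100, 25))
  expect_equal(max(wp$wet_pct), 100)
  # a low-visibility maximum month is excluded from the denominator
  wa$visible_fraction[2] <- 0.2
  wp2 <- wet_percentage(wa, "h1")
  expect_equal(wp2$wet_pct[1], 100)
  expect_false(wp2$valid[2])
})

test_that("ground-truth wet percentages are recovered when skies are clear", {
  cfg <- small_cfg(seed = 13, cloud_gap_rate = 0)
  wa <- sim_wet_area(cfg)
  wp <- wet_percentage(wa, "h01")
  truth <- 100 * wa$true_wet_area / max(wa$true_wet_area)
  expect_equal(wp$wet_pct, truth, tolerance = 1e-12)
})

test_that("gap interpolation fills flagged months linearly", {
  expect_equal(interpolate_gaps(c(40, 99, 60), c(TRUE, FALSE, TRUE)),
               c(40, 50, 60))
  x <- c(10, 20, 30)
  expect_identical(interpolate_gaps(x, rep(TRUE, 3)), x)
  expect_error(interpolate_gaps(x, rep(FALSE, 3)), "unusable")
  expect_warning(out <- interpolate_gaps(c(99, 20, 30),
                                         c(FALSE, TRUE, TRUE)), "edge")
  expect_equal(out, c(20, 20, 30))
})

test_that("interpolation matches an independent piecewise-linear oracle", {
  # hand-rolled oracle: scan to the nearest valid neighbours of each gap
  oracle <- function(x, valid) {
    out <- x
    idx <- which(!valid)
    vidx <- which(valid)
    for (i in idx) {
      lo <- max(vidx[vidx < i], -Inf)
      hi <- min(vidx[vidx > i], Inf)
      out[i] <- if (!is.finite(lo)) x[hi]
      else if (!is.finite(hi)) x[lo]
      else x[lo] + (x[hi] - x[lo]) * (i - lo) / (hi - lo)
    }
    out
  }
  set.seed(515)
  for (rep in 1:20) {
    n <- 40
    x <- runif(n, 0, 100)
    valid <- runif(n) > 0.3
    valid[sample(n, 2)] <- TRUE  # keep the series usable
    got <- suppressWarnings(interpolate_gaps(x, valid))
    expect_equal(got, oracle(x, valid), tolerance = 1e-12)
    # idempotence and bracketing bounds
    expect_equal(suppressWarnings(interpolate_gaps(got, valid)), got,
                 tolerance = 1e-12)
    interior <- !valid & seq_len(n) > min(which(valid)) &
      seq_len(n) < max(which(valid))
    for (i in which(interior)) {
      lo <- max(which(valid)[which(valid) < i])
      hi <- min(which(valid)[which(valid) > i])
      expect_gte(got[i], min(x[lo], x[hi]) - 1e-12)
      expect_lte(got[i], max(x[lo], x[hi]) + 1e-12)
    }
  }
})

test_that("add_covariates joins rain, temperature and gap-filled wet area", {
  cfg <- small_cfg(seed = 66, n_months = 15, n_birders = 40)
  st <- sim_study(cfg)
  pan <- build_panel(st$checklists, cfg$epoch, cfg$n_months,
                     hotspots = "h01")
  pan <- suppressWarnings(
    add_covariates(pan, st$weather, st$wet_area, cfg$epoch))
  expect_true(all(c("rain_mm", "tmax_c", "wet_pct", "wet_pct_lag1") %in%
                    names(pan)))
  expect_true(all(pan$wet_pct >= 0 & pan$wet_pct <= 100))
  expect_true(is.na(pan$wet_pct_lag1[1]))
  expect_equal(pan$wet_pct_lag1[-1], pan$wet_pct[-nrow(pan)])
})
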