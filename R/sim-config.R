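#' Configuration for the synthetic study generator
#'
#' Builds and validates the parameter set from which all four synthetic
#' inputs (checklists, daily weather, monthly wet-area observations, and the
#' birdwatcher survey) are generated.  The defaults emulate the study
#' conditions of a ten-hotspot, 72-month wetland panel (April 2013 to
#' March 2019): roughly ten Birder User Days (BuDs) per hotspot-month, a
#' thousand-odd birders, seasonal rainfall and temperature, wet surface area
#' expressed as a percentage of each site's maximum, and a 76-respondent
#' expenditure survey.  Every downstream stage can therefore be tested
#' against known generating parameters.
#'
#' @param n_hotspots number of wetland hotspot sites.
#' @param n_months length of the monthly study window (>= 3; lagged terms
#'   need history).
#' @param n_birders size of the birder population posting checklists.  Zero
#'   is allowed and yields an empty checklist table.
#' @param epoch first day of month 1 (a `Date` or ISO string).  Months are
#'   calendar months; month index runs 1..`n_months`.
#' @param cells_per_hotspot weather grid cells intersecting each hotspot
#'   (scalar, recycled).
#' @param true_beta named list of generating coefficients on the log-mean
#'   scale: `intercept`, `rain` (per mm monthly total), `temp` (per degree C),
#'   `wet` (per wet-percentage point), `spp_lag` (per species, previous
#'   month), `trend` (per month index).
#' @param wet_lag 0 or 1: whether the generating BuD model uses current-month
#'   or previous-month wet percentage.
#' @param month_effects length-12 vector of seasonal effects on the log-mean
#'   scale, indexed by month-of-year (January = 1).  Only differences matter;
#'   the intercept absorbs the level.
#' @param rain_mm_daily_mean,rain_daily_var mean and variance of daily cell
#'   rainfall (mm); variance 0 gives constant rainfall.
#' @param rain_season_amp relative seasonal amplitude of the rainfall mean.
#' @param tmax_mean,tmax_amp,tmax_daily_sd maximum-temperature climatology
#'   (degrees C): annual mean, seasonal amplitude (southern-hemisphere
#'   phase), and daily noise.
#' @param wet_area_max maximum combined waterbody wet surface area per
#'   hotspot (areal units, e.g. hectares).
#' @param wet_season_amp,wet_ar1,wet_noise_sd wet-fraction dynamics: seasonal
#'   amplitude, AR(1) coefficient and innovation standard deviation of the
#'   latent wet fraction.
#' @param cloud_gap_rate probability that a month's visible fraction falls
#'   below 0.5 (a cloud gap needing interpolation downstream).
#' @param n_species,water_frac species pool size and the fraction flagged as
#'   using freshwater or freshwater-edge habitat.
#' @param richness_base_logit,richness_wet_slope species inclusion model:
#'   logit of monthly occurrence at 50% wet area, and slope per 10
#'   wet-percentage points (water-flagged species get double the slope).
#' @param richness_month_sd standard deviation of a common month-level
#'   shock to the occupancy logit, representing reporting effort and
#'   detection variation shared across species within a month.
#' @param species_per_list_mean mean species count per posted checklist.
#' @param checklists_per_bud_mean mean checklist postings per birder visit
#'   day (shifted-geometric; the observed posting-to-visit-day ratio is
#'   about 1.5).
#' @param survey_params list of survey generating parameters; see
#'   [sim_survey()].  `NULL` keeps the defaults.
#' @param seed master integer seed; every generator stage derives its own
#'   stream from it, so a fixed seed gives byte-identical output.
#'
#' @return an object of class `"sim_config"` (a validated list).
#' @seealso [sim_study()], [sim_weather()], [sim_wet_area()],
#'   [sim_checklists()], [sim_survey()]
#' @export
sim_config <- function(n_hotspots = 10L,
                       n_months = 72L,
                       n_birders = 1060L,
                       epoch = as.Date("2013-04-01"),
                       cells_per_hotspot = 3L,
                       true_beta = list(intercept = 1.1, rain = -0.002,
                                        temp = -0.015, wet = 0.02,
                                        spp_lag = 0.01, trend = 0.002),
                       wet_lag = 1L,
                       month_effects = 0.25 * sin(2 * pi * (1:12) / 12),
                       rain_mm_daily_mean = 1.5,
                       rain_daily_var = 9,
                       rain_season_amp = 0.15,
                       tmax_mean = 22,
                       tmax_amp = 8,
                       tmax_daily_sd = 2.5,
                       wet_area_max = 500,
                       wet_season_amp = 0.2,
                       wet_ar1 = 0.6,
                       wet_noise_sd = 0.08,
                       cloud_gap_rate = 0.2,
                       n_species = 120L,
                       water_frac = 0.5,
                       richness_base_logit = -0.8,
                       richness_wet_slope = 0.1,
                       richness_month_sd = 0.4,
                       species_per_list_mean = 20,
                       checklists_per_bud_mean = 1.5,
                       survey_params = NULL,
                       seed = 1L) {
  cfg <- list(
    n_hotspots = as.integer(n_hotspots), n_months = as.integer(n_months),
    n_birders = as.integer(n_birders), epoch = as.Date(epoch),
    cells_per_hotspot = rep_len(as.integer(cells_per_hotspot), n_hotspots),
    true_beta = true_beta, wet_lag = as.integer(wet_lag),
    month_effects = month_effects,
    rain_mm_daily_mean = rain_mm_daily_mean, rain_daily_var = rain_daily_var,
    rain_season_amp = rain_season_amp,
    tmax_mean = tmax_mean, tmax_amp = tmax_amp, tmax_daily_sd = tmax_daily_sd,
    wet_area_max = wet_area_max, wet_season_amp = wet_season_amp,
    wet_ar1 = wet_ar1, wet_noise_sd = wet_noise_sd,
    cloud_gap_rate = cloud_gap_rate,
    n_species = as.integer(n_species), water_frac = water_frac,
    richness_base_logit = richness_base_logit,
    richness_wet_slope = richness_wet_slope,
    richness_month_sd = richness_month_sd,
    species_per_list_mean = species_per_list_mean,
    checklists_per_bud_mean = checklists_per_bud_mean,
    survey_params = default_survey_params(survey_params),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

# Fill survey generating parameters, overriding defaults with user entries.
default_survey_params <- function(override = NULL) {
  p <- list(
    n_respondents = 76L,
    p_usable = 59 / 76,
    # trinomial over respondents: Basin eBirder / Basin non-eBirder / non-Basin
    p_basin_ebirder = 0.691, p_basin_nonebirder = 0.265, p_nonbasin = 0.044,
    group_probs_ebird = c(alone = 0.635, pair = 0.139, group2_5 = 0.096,
                          group_gt5 = 0.13),
    group_probs_nonebird = c(alone = 0.55, pair = 0.35, group2_5 = 0.05,
                             group_gt5 = 0.05),
    # share of a category's trips that are day trips (rest overnight)
    day_trip_share = c(alone = 0.90, pair = 0.67, group2_5 = 0.25,
                       group_gt5 = 0.25),
    # per-visit-day expenditure medians (AUD) by cohort x group x trip type
    per_day_median = list(
      ebird = c(alone.day = 95, alone.overnight = 170, pair.day = 59,
                pair.overnight = 84, group2_5.day = 86.75,
                group2_5.overnight = 124.25),
      nonebird = c(alone.day = 95, alone.overnight = 132.5, pair.day = 75,
                   pair.overnight = 112.5, group2_5.day = 85,
                   group2_5.overnight = 120)
    ),
    expenditure_sdlog = 0.4,
    day_freq_probs = c(never = 0.05, once_a_year = 0.10,
                       few_times_a_year = 0.30, monthly = 0.25,
                       fortnightly = 0.12, weekly = 0.10,
                       more_than_two_per_week = 0.08),
    overnight_freq_probs = c(never = 0.25, once_a_year = 0.25,
                             few_times_a_year = 0.30, monthly = 0.12,
                             fortnightly = 0.05, weekly = 0.02,
                             more_than_two_per_week = 0.01)
  )
  if (!is.null(override)) p[names(override)] <- override
  p
}

validate_sim_config <- function(cfg) {
  if (cfg$n_months < 3L) stop_invalid("n_months must be >= 3 (lags need history)")
  if (cfg$n_hotspots < 1L) stop_invalid("n_hotspots must be positive")
  if (cfg$n_birders < 0L) stop_invalid("n_birders must be non-negative")
  if (any(cfg$cells_per_hotspot < 1L))
    stop_invalid("each hotspot needs at least one grid cell")
  need <- c("intercept", "rain", "temp", "wet", "spp_lag", "trend")
  if (!all(need %in% names(cfg$true_beta)))
    stop_invalid("true_beta must name: ", paste(need, collapse = ", "))
  if (length(cfg$month_effects) != 12L)
    stop_invalid("month_effects must have length 12")
  if (cfg$cloud_gap_rate < 0 || cfg$cloud_gap_rate > 1)
    stop_invalid("cloud_gap_rate must lie in [0, 1]")
  if (cfg$rain_daily_var < 0) stop_invalid("rain_daily_var must be >= 0")
  if (cfg$n_species < 1L) stop_invalid("species pool must be non-empty")
  sp <- cfg$survey_params
  tri <- sp$p_basin_ebirder + sp$p_basin_nonebirder + sp$p_nonbasin
  if (abs(tri - 1) > 1e-9)
    stop_invalid("survey cohort probabilities must sum to 1 (got ", tri, ")")
  for (nm in c("group_probs_ebird", "group_probs_nonebird")) {
    if (abs(sum(sp[[nm]]) - 1) > 1e-9)
      stop_invalid(nm, " must sum to 1 (tolerance 1e-9)")
    if (any(sp[[nm]] < 0 | sp[[nm]] > 1))
      stop_invalid(nm, " entries must lie in [0, 1]")
  }
  for (nm in c("day_freq_probs", "overnight_freq_probs"))
    if (abs(sum(sp[[nm]]) - 1) > 1e-9)
      stop_invalid(nm, " must sum to 1 (tolerance 1e-9)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d hotspots x %d months from %s; %d birders\n",
              x$n_hotspots, x$n_months, format(x$epoch), x$n_birders))
  b <- x$true_beta
  cat(sprintf("  true beta: intercept %.3f rain %.4f temp %.4f wet %.4f spp_lag %.4f trend %.4f (wet lag %d)\n",
              b$intercept, b$rain, b$temp, b$wet, b$spp_lag, b$trend, x$wet_lag))
  cat(sprintf("  cloud gap rate %.2f, species pool %d (%.0f%% water-related), seed %d\n",
              x$cloud_gap_rate, x$n_species, 100 * x$water_frac, x$seed))
  invisible(x)
}
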