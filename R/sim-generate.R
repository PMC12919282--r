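#' Generate daily gridded weather for every hotspot cell
#'
#' Simulates daily rainfall (mm) and maximum temperature (degrees C) for each
#' weather grid cell intersecting each hotspot, over the whole study window.
#' Rainfall is gamma-distributed around a seasonal sinusoid (variance 0 gives
#' exactly the mean); temperature is a southern-hemisphere seasonal sinusoid
#' plus Gaussian noise.
#'
#' @param config a [sim_config()] object.
#' @return data frame with columns `hotspot_id`, `cell_id`, `date`,
#'   `rain_mm`, `tmax_c`; one row per cell per day.
#' @export
sim_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  first <- config$epoch
  last <- seq(first, by = "month", length.out = config$n_months + 1L)[config$n_months + 1L] - 1L
  dates <- seq(first, last, by = "day")
  doy <- as.integer(format(dates, "%j"))
  # seasonal means shared by all cells; day 15 ~ austral midsummer peak heat,
  # rainfall peaks offset half a year (winter-dominated)
  rain_mean <- config$rain_mm_daily_mean *
    (1 + config$rain_season_amp * cos(2 * pi * (doy - 197) / 365.25))
  rain_mean <- pmax(rain_mean, 0)
  tmax_mean <- config$tmax_mean +
    config$tmax_amp * cos(2 * pi * (doy - 15) / 365.25)
  nd <- length(dates)

  with_seed(derive_seed(config$seed, "weather"), {
    out <- vector("list", config$n_hotspots)
    for (h in seq_len(config$n_hotspots)) {
      ncell <- config$cells_per_hotspot[h]
      cells <- vector("list", ncell)
      for (cc in seq_len(ncell)) {
        if (config$rain_daily_var > 0) {
          shape <- rain_mean^2 / config$rain_daily_var
          rain <- ifelse(rain_mean > 0,
                         stats::rgamma(nd, shape = shape,
                                       rate = shape / pmax(rain_mean, 1e-12)),
                         0)
        } else {
          rain <- rain_mean
        }
        tmax <- tmax_mean + stats::rnorm(nd, 0, config$tmax_daily_sd)
        cells[[cc]] <- data.frame(
          hotspot_id = hotspot_label(h), cell_id = sprintf("c%02d", cc),
          date = dates, rain_mm = rain, tmax_c = tmax)
      }
      out[[h]] <- do.call(rbind, cells)
    }
    do.call(rbind, out)
  })
}

hotspot_label <- function(i) sprintf("h%02d", i)

#' Generate monthly waterbody wet-area observations with cloud gaps
#'
#' Simulates each hotspot's combined waterbody wet surface area per month as
#' a seasonal AR(1) fraction of the site maximum, then masks a random subset
#' of months as cloud-obscured (visible fraction below 0.5).  Months with at
#' least half the surface visible are treated as fully observed; obscured
#' months undercount area in proportion to visibility.  The pre-masking
#' series is retained as ground truth in column `true_wet_area`.
#'
#' @param config a [sim_config()] object.
#' @return data frame with columns `hotspot_id`, `month_index`,
#'   `observed_wet_area`, `visible_fraction`, `true_wet_area`.
#' @export
sim_wet_area <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_months
  moy <- month_of_year(seq_len(n), as.integer(format(config$epoch, "%m")))
  with_seed(derive_seed(config$seed, "wetarea"), {
    out <- vector("list", config$n_hotspots)
    for (h in seq_len(config$n_hotspots)) {
      ar <- numeric(n)
      innov <- stats::rnorm(n, 0, config$wet_noise_sd)
      ar[1] <- innov[1] / sqrt(1 - config$wet_ar1^2)
      for (t in 2:n) ar[t] <- config$wet_ar1 * ar[t - 1] + innov[t]
      frac <- 0.55 + config$wet_season_amp * sin(2 * pi * moy / 12) + ar
      frac <- pmin(pmax(frac, 0.05), 1)
      true_wet <- config$wet_area_max * frac
      gap <- stats::runif(n) < config$cloud_gap_rate
      vis <- ifelse(gap, stats::runif(n, 0, 0.5), stats::runif(n, 0.5, 1))
      observed <- true_wet * ifelse(vis >= 0.5, 1, vis)
      out[[h]] <- data.frame(
        hotspot_id = hotspot_label(h), month_index = seq_len(n),
        observed_wet_area = observed, visible_fraction = vis,
        true_wet_area = true_wet)
    }
    do.call(rbind, out)
  })
}

#' Species pool with freshwater-habitat flags
#'
#' @param config a [sim_config()] object.
#' @return data frame with columns `species` and `water_related`.
#' @export
species_pool <- function(config) {
  n_water <- round(config$n_species * config$water_frac)
  data.frame(
    species = c(sprintf("Waterbird sp. %03d", seq_len(n_water)),
                sprintf("Woodland bird sp. %03d",
                        seq_len(config$n_species - n_water))),
    water_related = rep(c(TRUE, FALSE),
                        c(n_water, config$n_species - n_water)))
}

# Per-species occupancy intercepts on the logit scale, fixed by the seed so
# the pool has stable common/rare structure across stages.
species_logits <- function(config) {
  with_seed(derive_seed(config$seed, "species"),
            stats::rnorm(config$n_species, config$richness_base_logit, 0.6))
}

#' Generate the latent monthly panel: covariates, richness and BuD counts
#'
#' The monthly backbone of the generator.  Daily weather is aggregated to
#' monthly totals/means exactly as the analysis side does, wet percentage is
#' computed from the ground-truth (pre-cloud) wet series, monthly species
#' occupancy is drawn with inclusion probability logistic in wet percentage
#' (water-related species respond twice as strongly, and a common
#' month-level logit shock adds the reporting noise real checklist-derived
#' richness carries), and BuD counts are
#' drawn Poisson with log-mean
#' `intercept + rain*Rain + temp*MTemp + wet*Wet(lagged per config) +
#'  spp_lag*Richness(t-1) + month_effect + trend*t`.
#'
#' @param config a [sim_config()] object.
#' @param weather,wet_area optionally, pre-generated tables from
#'   [sim_weather()] / [sim_wet_area()]; regenerated from `config` if `NULL`.
#' @return list with `panel` (one row per hotspot-month: covariates, true
#'   richness, latent mean `mu`, `bud` count), `species_sets` (per
#'   hotspot-month character vectors of occurring species), and the input
#'   tables.
#' @export
sim_monthly_panel <- function(config, weather = NULL, wet_area = NULL) {
  stopifnot(inherits(config, "sim_config"))
  weather <- weather %||% sim_weather(config)
  wet_area <- wet_area %||% sim_wet_area(config)
  n <- config$n_months
  epoch_m <- as.integer(format(config$epoch, "%m"))
  moy <- month_of_year(seq_len(n), epoch_m)
  pool <- species_pool(config)
  logit0 <- species_logits(config)
  slope <- config$richness_wet_slope * (1 + pool$water_related)
  b <- config$true_beta

  with_seed(derive_seed(config$seed, "panel"), {
    rows <- vector("list", config$n_hotspots)
    sets <- vector("list", config$n_hotspots)
    for (h in seq_len(config$n_hotspots)) {
      hid <- hotspot_label(h)
      w <- weather[weather$hotspot_id == hid, , drop = FALSE]
      rain <- monthly_rain(w, hid, epoch = config$epoch, n_months = n)$rain_mm
      tmax <- monthly_tmax(w, hid, epoch = config$epoch, n_months = n)$tmax_c
      wa <- wet_area[wet_area$hotspot_id == hid, , drop = FALSE]
      wa <- wa[order(wa$month_index), ]
      wet_pct <- 100 * wa$true_wet_area / max(wa$true_wet_area)

      rich_all <- integer(n); rich_water <- integer(n)
      msets <- vector("list", n)
      for (t in seq_len(n)) {
        shock <- stats::rnorm(1, 0, config$richness_month_sd)
        p <- stats::plogis(logit0 + shock + slope * (wet_pct[t] - 50) / 10)
        occ <- stats::runif(config$n_species) < p
        msets[[t]] <- pool$species[occ]
        rich_all[t] <- sum(occ)
        rich_water[t] <- sum(occ & pool$water_related)
      }
      lag1 <- function(x) c(x[1], x[-length(x)])
      wet_used <- if (config$wet_lag >= 1L) lag1(wet_pct) else wet_pct
      eta <- b$intercept + b$rain * rain + b$temp * tmax +
        b$wet * wet_used + b$spp_lag * lag1(rich_all) +
        config$month_effects[moy] + b$trend * seq_len(n)
      mu <- exp(eta)
      bud <- stats::rpois(n, mu)
      rows[[h]] <- data.frame(
        hotspot_id = hid, month_index = seq_len(n), month_of_year = moy,
        rain_mm = rain, tmax_c = tmax, wet_pct_true = wet_pct,
        richness_all_true = rich_all, richness_water_true = rich_water,
        mu = mu, bud = bud)
      sets[[h]] <- msets
    }
    list(panel = do.call(rbind, rows), species_sets = stats::setNames(
      sets, hotspot_label(seq_len(config$n_hotspots))),
      weather = weather, wet_area = wet_area, config = config)
  })
}

#' Generate checklist records realizing the latent BuD counts
#'
#' Each Birder User Day (one distinct birder-date pair at a hotspot) is
#' realized as one or more same-day checklist rows: the number of postings
#' per visit day is shifted-geometric with the configured mean, and each
#' checklist samples species from that month's occurring set.  Within a
#' month every occurring species appears on at least one checklist, so
#' observed monthly richness matches the generating richness whenever the
#' month has any visits.  Visit days fall uniformly over the month's days.
#'
#' @param config a [sim_config()] object.
#' @param weather,wet_area optional pre-generated input tables.
#' @param monthly optionally a [sim_monthly_panel()] result (regenerated
#'   otherwise).
#' @return long-format data frame, one row per species entry on a checklist:
#'   columns `checklist_id`, `birder_id`, `hotspot_id`, `date`, `species`.
#'   Zero birders gives a zero-row table.  The latent panel is attached as
#'   attribute `"truth"`.
#' @export
sim_checklists <- function(config, weather = NULL, wet_area = NULL,
                           monthly = NULL) {
  stopifnot(inherits(config, "sim_config"))
  monthly <- monthly %||% sim_monthly_panel(config, weather, wet_area)
  empty <- data.frame(checklist_id = character(), birder_id = character(),
                      hotspot_id = character(), date = as.Date(character()),
                      species = character())
  if (config$n_birders == 0L) {
    attr(empty, "truth") <- monthly$panel
    return(empty)
  }
  pan <- monthly$panel
  p_geo <- 1 / config$checklists_per_bud_mean
  with_seed(derive_seed(config$seed, "checklists"), {
    acc <- list(); k <- 0L; cl_counter <- 0L
    for (i in seq_len(nrow(pan))) {
      B <- pan$bud[i]
      if (B == 0L) next
      hid <- pan$hotspot_id[i]
      t <- pan$month_index[i]
      nd <- days_in_month(t, config$epoch)
      start <- month_start(t, config$epoch)
      ncomb <- config$n_birders * nd
      if (B > ncomb) B <- ncomb  # cannot exceed distinct birder-day pairs
      idx <- sample.int(ncomb, B)
      birder <- (idx - 1L) %/% nd + 1L
      day <- (idx - 1L) %% nd + 1L
      S <- monthly$species_sets[[hid]][[t]]
      month_rows <- list(); m <- 0L
      for (j in seq_len(B)) {
        ncl <- 1L + stats::rgeom(1, p_geo)
        for (cl in seq_len(ncl)) {
          cl_counter <- cl_counter + 1L
          ns <- if (length(S) == 0L) 0L else
            min(length(S), 1L + stats::rpois(1, config$species_per_list_mean - 1))
          if (ns == 0L) next
          m <- m + 1L
          month_rows[[m]] <- data.frame(
            checklist_id = sprintf("cl%07d", cl_counter),
            birder_id = sprintf("b%05d", birder[j]),
            hotspot_id = hid, date = start + (day[j] - 1L),
            species = sample(S, ns))
        }
      }
      if (m > 0L) {
        mr <- do.call(rbind, month_rows)
        missing <- setdiff(S, unique(mr$species))
        if (length(missing)) {
          # pin unsampled species onto random existing checklists so the
          # month's observed richness equals the generating richness
          ids <- unique(mr$checklist_id)
          host <- sample(ids, length(missing), replace = TRUE)
          extra <- mr[match(host, mr$checklist_id), ]
          extra$species <- missing
          mr <- rbind(mr, extra)
        }
        k <- k + 1L
        acc[[k]] <- mr
      }
    }
    out <- if (k > 0L) do.call(rbind, acc) else empty
    rownames(out) <- NULL
    attr(out, "truth") <- pan
    out
  })
}

#' Generate birdwatcher survey responses
#'
#' Emulates an online expenditure survey of birdwatching-club members:
#' whether the respondent uses the eBird app and birdwatches in the basin,
#' usual travelling-group size, categorical day- and overnight-trip
#' frequencies, and per-visit-day expenditures (lognormal around the
#' configured cohort/cell medians, so cell medians are recoverable).  A
#' configurable fraction of responses is incomplete (`usable = FALSE`,
#' expenditure fields missing), mirroring real return rates.
#'
#' @param config a [sim_config()] object.
#' @return data frame, one row per respondent.
#' @export
sim_survey <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$survey_params
  n <- sp$n_respondents
  groups <- c("alone", "pair", "group2_5", "group_gt5")
  freq_levels <- names(sp$day_freq_probs)
  with_seed(derive_seed(config$seed, "survey"), {
    cohort <- sample(c("basin_ebird", "basin_nonebird", "nonbasin"), n,
                     replace = TRUE,
                     prob = c(sp$p_basin_ebirder, sp$p_basin_nonebirder,
                              sp$p_nonbasin))
    uses_ebird <- cohort == "basin_ebird" |
      (cohort == "nonbasin" & stats::runif(n) < 0.5)
    in_basin <- cohort != "nonbasin"
    grp <- character(n)
    for (i in seq_len(n)) {
      pr <- if (uses_ebird[i]) sp$group_probs_ebird else sp$group_probs_nonebird
      grp[i] <- sample(groups, 1, prob = pr)
    }
    day_cat <- sample(freq_levels, n, replace = TRUE, prob = sp$day_freq_probs)
    on_cat <- sample(freq_levels, n, replace = TRUE,
                     prob = sp$overnight_freq_probs)
    med_for <- function(i, type) {
      tab <- if (uses_ebird[i]) sp$per_day_median$ebird else
        sp$per_day_median$nonebird
      g <- if (grp[i] == "group_gt5") "group2_5" else grp[i]
      unname(tab[paste(g, type, sep = ".")])
    }
    ed <- vapply(seq_len(n), med_for, numeric(1), type = "day")
    eo <- vapply(seq_len(n), med_for, numeric(1), type = "overnight")
    per_day_day <- exp(stats::rnorm(n, log(ed), sp$expenditure_sdlog))
    per_day_on <- exp(stats::rnorm(n, log(eo), sp$expenditure_sdlog))
    usable <- stats::runif(n) < sp$p_usable
    ann_day <- per_day_day * vapply(day_cat, frequency_to_annual, numeric(1))
    ann_on <- per_day_on * vapply(on_cat, frequency_to_annual, numeric(1))
    per_day_day[!usable] <- NA_real_; per_day_on[!usable] <- NA_real_
    ann_day[!usable] <- NA_real_; ann_on[!usable] <- NA_real_
    data.frame(
      respondent_id = sprintf("r%03d", seq_len(n)), usable = usable,
      uses_ebird = uses_ebird, birdwatches_in_basin = in_basin,
      group_category = grp, day_trip_frequency_category = day_cat,
      overnight_trip_frequency_category = on_cat,
      per_day_expenditure_day_trip = per_day_day,
      per_day_expenditure_overnight = per_day_on,
      annual_expenditure_day_trip = ann_day,
      annual_expenditure_overnight = ann_on)
  })
}

#' Generate a complete synthetic study
#'
#' Runs every generator stage under the configuration's master seed and
#' returns all four input tables plus the ground truth.
#'
#' @param config a [sim_config()] object.
#' @return list with `weather`, `wet_area`, `checklists`, `survey`, `truth`
#'   (the latent monthly panel with `mu` and `bud`), and `config`.
#' @export
sim_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  monthly <- sim_monthly_panel(config)
  checklists <- sim_checklists(config, monthly = monthly)
  survey <- sim_survey(config)
  list(weather = monthly$weather, wet_area = monthly$wet_area,
       checklists = checklists, survey = survey,
       truth = monthly$panel, config = config)
}

#' Write a synthetic study to CSV files
#'
#' Writes `checklists.csv`, `weather.csv`, `wetarea.csv`, `survey.csv` and
#' `truth.csv` (the latent panel) into `dir`.
#'
#' @param study a [sim_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$checklists, file.path(dir, "checklists.csv"),
                   row.names = FALSE)
  utils::write.csv(study$weather, file.path(dir, "weather.csv"),
                   row.names = FALSE)
  utils::write.csv(study$wet_area, file.path(dir, "wetarea.csv"),
                   row.names = FALSE)
  utils::write.csv(study$survey, file.path(dir, "survey.csv"),
                   row.names = FALSE)
  utils::write.csv(study$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
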