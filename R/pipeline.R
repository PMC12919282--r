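#' Month indices of the last complete calendar year in a study window
#'
#' Expenditure totals are applied to the most recent complete calendar year
#' of BuD counts.
#'
#' @param epoch first day of month 1.
#' @param n_months window length.
#' @return integer vector of 12 month indices (January..December).
#' @export
last_complete_year_months <- function(epoch, n_months) {
  starts <- seq(as.Date(epoch), by = "month", length.out = n_months)
  yrs <- as.integer(format(starts, "%Y"))
  complete <- names(which(table(yrs) == 12L))
  if (length(complete) == 0L) stop("window contains no complete calendar year")
  yr <- max(as.integer(complete))
  which(yrs == yr)
}

#' Run the full visitation-to-valuation chain on a synthetic study
#'
#' Executes the pipeline end to end: simulate (or accept) a study, aggregate
#' checklists into the monthly BuD/richness panel, attach rainfall,
#' temperature and gap-filled wet-percentage covariates, fit the candidate
#' count models per hotspot and the fixed-effects panel model, project the
#' direct and mediated wet-area scenarios, and compute survey-based
#' activity-weighted expenditures and their scenario deltas.
#'
#' @param config a [sim_config()]; ignored when `study` is supplied.
#' @param study optionally a pre-generated [sim_study()] result.
#' @param delta_wet the wet-area scenario, a [wet_scenario()].
#' @param scenario_seed seed for scenario coefficient draws.
#' @param boot_reps hotspot-clustered bootstrap replications for the panel
#'   model (0 skips the bootstrap).
#' @param hac_lag Newey-West lag passed to the hotspot fits (`NULL` for the
#'   plug-in default).
#' @return object of class `"bud_study"`: list with `panel` (covariate-
#'   joined monthly records), `candidates` (per hotspot: BuD and richness
#'   candidate runs), `panel_fit`, `scenarios` (per hotspot: direct and
#'   mediated), `expenditure` (weights, per-day rates, extrapolation
#'   factor, per-site annual totals and scenario deltas), plus the inputs.
#' @export
run_study <- function(config = sim_config(), study = NULL,
                      delta_wet = wet_scenario(), scenario_seed = 1L,
                      boot_reps = 199L, hac_lag = NULL) {
  study <- study %||% sim_study(config)
  config <- study$config
  pool <- species_pool(config)
  hotspots <- hotspot_label(seq_len(config$n_hotspots))

  panel <- build_panel(study$checklists, config$epoch, config$n_months,
                       hotspots = hotspots,
                       longlist = pool$species[pool$water_related])
  panel <- add_covariates(panel, study$weather, study$wet_area, config$epoch)

  candidates <- list(); scenarios <- list()
  for (h in hotspots) {
    ph <- panel[panel$hotspot_id == h, , drop = FALSE]
    bud_run <- run_candidates(ph, "bud", hac_lag = hac_lag)
    rich_run <- run_candidates(ph, "richness_all", hac_lag = hac_lag)
    candidates[[h]] <- list(bud = bud_run, richness = rich_run)
    direct <- direct_change(bud_run$fits[["2"]], delta_wet,
                            seed = scenario_seed)
    mediated <- mediated_change(rich_run$fits[["2"]], bud_run$fits[["3"]],
                                delta_wet, seed = scenario_seed)
    scenarios[[h]] <- list(direct = direct, mediated = mediated)
  }

  panel_fit <- fe_poisson(panel, "bud", candidate = 2L)
  if (boot_reps >= 2L)
    panel_fit <- cluster_bootstrap(panel_fit, n_reps = boot_reps,
                                   seed = scenario_seed)

  expenditure <- study_expenditure(study$survey, panel, scenarios,
                                   config$epoch, config$n_months)

  out <- list(panel = panel, candidates = candidates,
              panel_fit = panel_fit, scenarios = scenarios,
              expenditure = expenditure, study = study, config = config,
              delta_wet = delta_wet)
  class(out) <- "bud_study"
  out
}

# Survey-side arithmetic for a whole study: cohort weights and rates, the
# extrapolation factor from observed eBird usage, per-site annual totals
# from the last complete calendar year, and scenario deltas.
study_expenditure <- function(survey, panel, scenarios, epoch, n_months) {
  w_e <- activity_weights(survey, "ebird")
  w_n <- activity_weights(survey, "nonebird")
  e_day_e <- per_visit_day_expenditure(w_e, cell_medians(survey, "ebird"))
  e_day_n <- per_visit_day_expenditure(w_n, cell_medians(survey, "nonebird"))
  ann_e <- annual_expenditure(w_e, cell_medians(survey, "ebird", "annual"))
  ann_n <- annual_expenditure(w_n, cell_medians(survey, "nonebird", "annual"))
  basin <- survey[survey$birdwatches_in_basin, , drop = FALSE]
  p_e <- 100 * mean(basin$uses_ebird)
  fac <- extrapolation_factor(100 - p_e, p_e)
  months <- last_complete_year_months(epoch, n_months)
  sites <- list()
  for (h in unique(panel$hotspot_id)) {
    buds <- annual_bud_total(panel, h, months)
    total <- site_annual_expenditure(buds, fac, e_day_e, e_day_n)
    delta <- if (!is.null(scenarios[[h]]))
      scenario_expenditure_delta(total, scenarios[[h]]$direct) else NULL
    sites[[h]] <- list(annual_buds = buds, annual_expenditure = total,
                       scenario_delta = delta)
  }
  list(weights = list(ebird = w_e, nonebird = w_n),
       per_visit_day = c(ebird = e_day_e, nonebird = e_day_n),
       annual_per_birder = c(ebird = ann_e, nonebird = ann_n),
       p_ebird_basin = p_e, extrapolation_factor = fac,
       year_months = months, sites = sites)
}

#' @export
print.bud_study <- function(x, ...) {
  cat("Birdwatching visitation study --",
      sprintf("%d hotspots, %d months\n", x$config$n_hotspots,
              x$config$n_months))
  best <- vapply(x$candidates, function(cc)
    cc$bud$best$spec$candidate_id, integer(1))
  cat("  best BuD candidate per hotspot:",
      paste(names(best), best, sep = ":", collapse = " "), "\n")
  med <- vapply(x$scenarios, function(s) s$direct$median_pct_change,
                numeric(1))
  cat(sprintf("  direct scenario median BuD change: %s\n",
              paste(sprintf("%+.1f%%", med), collapse = " ")))
  e <- x$expenditure
  cat(sprintf("  per-visit-day expenditure: eBirder %.2f, non-eBirder %.2f AUD (factor %.3f)\n",
              e$per_visit_day["ebird"], e$per_visit_day["nonebird"],
              e$extrapolation_factor))
  invisible(x)
}
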