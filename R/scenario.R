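#' Scenario specification: an increase in wet surface area
#'
#' Defines the counterfactual wet-area increase applied to fitted models.
#' `mode = "relative"` (default) reads "a 15% increase" as 15% of the
#' baseline wet percentage (the site's mean condition unless overridden),
#' i.e. `delta_x = percent/100 * baseline`; `mode = "absolute"` applies the
#' increase as percentage points directly (`delta_x = percent`).
#'
#' @param percent size of the increase (default 15).
#' @param mode `"relative"` or `"absolute"` interpretation.
#' @return list of class `"wet_scenario"`.
#' @export
wet_scenario <- function(percent = 15, mode = c("relative", "absolute")) {
  structure(list(percent = percent, mode = match.arg(mode)),
            class = "wet_scenario")
}

scenario_delta_x <- function(delta_wet, baseline) {
  if (delta_wet$mode == "absolute") delta_wet$percent
  else delta_wet$percent / 100 * baseline
}

coef_and_se <- function(fit, term) {
  if (!term %in% names(fit$coefficients))
    stop("fitted model has no '", term, "' term; refit with a candidate ",
         "that includes it")
  list(beta = unname(fit$coefficients[term]),
       se = sqrt(max(fit$vcov[term, term], 0)))
}

scenario_result <- function(hotspot, chain, delta_wet, pct_draws, point,
                            ns, n_draws, seed) {
  qs <- stats::quantile(pct_draws, c(0.05, 0.5, 0.95), names = FALSE)
  structure(list(
    hotspot_id = hotspot, chain = chain, delta_wet_spec = delta_wet,
    point_pct_change = point, median_pct_change = qs[2],
    p5_pct_change = qs[1], p95_pct_change = qs[3], ns = ns,
    n_draws = n_draws, seed = seed), class = "bud_scenario")
}

#' Direct-chain projection: wet area to visitation
#'
#' Translates the fitted wet-percentage coefficient into the expected
#' percentage change in monthly BuD count under a wet-area increase:
#' the point change is `100 * (exp(beta_wet * delta_x) - 1)`.  The 5th/50th/
#' 95th percentile band comes from `n_draws` draws of the coefficient from
#' a normal with the HAC standard error.  If the wet term is not
#' statistically significant at `sig_level` the result is flagged `ns`
#' (reported but not interpretable as a supported association).
#'
#' @param fit a [bud_glm()] fit whose candidate includes a wet term
#'   (typically candidate 2, previous-month wet percentage).
#' @param delta_wet a [wet_scenario()] (default: 15% relative increase).
#' @param baseline baseline wet percentage for the relative mode; default
#'   is the mean of the fit's wet column.
#' @param n_draws number of coefficient draws (default 10000).
#' @param seed integer seed for the draws.
#' @param sig_level significance level for the `ns` flag (default 0.05).
#' @return object of class `"bud_scenario"` with point, median, 5th and
#'   95th percentile percentage changes.
#' @export
direct_change <- function(fit, delta_wet = wet_scenario(), baseline = NULL,
                          n_draws = 10000L, seed = 1L, sig_level = 0.05) {
  term <- wet_term_name(fit$spec)
  if (is.null(term)) stop("candidate spec has no wet term")
  cs <- coef_and_se(fit, term)
  baseline <- baseline %||% mean(fit$X[, term])
  dx <- scenario_delta_x(delta_wet, baseline)
  p <- 2 * stats::pnorm(-abs(cs$beta / cs$se))
  point <- 100 * (exp(cs$beta * dx) - 1)
  draws <- with_seed(seed, stats::rnorm(n_draws, cs$beta, cs$se))
  scenario_result(fit$hotspot_id %||% NA_character_, "direct", delta_wet,
                  100 * (exp(draws * dx) - 1), point, ns = p >= sig_level,
                  n_draws = n_draws, seed = seed)
}

#' Mediated-chain projection: wet area to richness to visitation
#'
#' Composes two fitted links: the wet-area effect on next-month species
#' richness, and the lagged-richness effect on BuD count.  Step 1 converts
#' the wet increase into an expected richness change
#' `delta_S = S_base * (exp(beta_rich_wet * delta_x) - 1)` at baseline
#' richness `S_base`; step 2 converts that into a BuD change
#' `100 * (exp(beta_bud_spp * delta_S) - 1)`.  The percentile band
#' propagates independent normal draws of both coefficients.  The result is
#' flagged `ns` unless both links are significant at `sig_level`.
#'
#' @param richness_fit a [bud_glm()] richness fit with a wet term.
#' @param bud_fit a [bud_glm()] BuD fit with the lagged richness term
#'   (candidate 3, 4 or 5).
#' @param s_base baseline richness; default is the richness fit's mean
#'   observed response.
#' @inheritParams direct_change
#' @return object of class `"bud_scenario"`.
#' @export
mediated_change <- function(richness_fit, bud_fit,
                            delta_wet = wet_scenario(), baseline = NULL,
                            s_base = NULL, n_draws = 10000L, seed = 1L,
                            sig_level = 0.05) {
  wterm <- wet_term_name(richness_fit$spec)
  if (is.null(wterm)) stop("richness fit has no wet term")
  cw <- coef_and_se(richness_fit, wterm)
  cb <- coef_and_se(bud_fit, "spp_lag1")
  baseline <- baseline %||% mean(richness_fit$X[, wterm])
  s_base <- s_base %||% mean(richness_fit$y)
  dx <- scenario_delta_x(delta_wet, baseline)
  p_w <- 2 * stats::pnorm(-abs(cw$beta / cw$se))
  p_b <- 2 * stats::pnorm(-abs(cb$beta / cb$se))
  dS <- s_base * (exp(cw$beta * dx) - 1)
  point <- 100 * (exp(cb$beta * dS) - 1)
  pct <- with_seed(seed, {
    dw <- stats::rnorm(n_draws, cw$beta, cw$se)
    db <- stats::rnorm(n_draws, cb$beta, cb$se)
    100 * (exp(db * s_base * (exp(dw * dx) - 1)) - 1)
  })
  scenario_result(bud_fit$hotspot_id %||% NA_character_, "mediated",
                  delta_wet, pct, point,
                  ns = p_w >= sig_level || p_b >= sig_level,
                  n_draws = n_draws, seed = seed)
}

#' @export
print.bud_scenario <- function(x, ...) {
  cat(sprintf(
    "%s-chain scenario (%s %g%% wet-area increase)%s\n", x$chain,
    x$delta_wet_spec$mode, x$delta_wet_spec$percent,
    if (!is.na(x$hotspot_id)) paste0(" for hotspot ", x$hotspot_id) else ""))
  cat(sprintf("  BuD change: median %+.1f%% [5th %+.1f%%, 95th %+.1f%%]%s\n",
              x$median_pct_change, x$p5_pct_change, x$p95_pct_change,
              if (x$ns) "  (ns)" else ""))
  invisible(x)
}
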