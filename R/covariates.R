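#' @name covariates
#' @title Monthly covariate construction
#' @description
#' Builders for the monthly regressors: total rainfall, mean daily maximum
#' temperature, wet-surface-area percentage and its cloud-gap interpolation.
#' Rainfall for a hotspot spanning several grid cells is the across-cell
#' daily mean summed over the month; temperature is the mean of daily cell
#' means.  Wet percentage expresses each month's combined waterbody wet area
#' as a percentage of the site's maximum over the window, where the maximum
#' is taken over months with adequate visibility; months with less than half
#' the maximum area visible are gap-filled by linear interpolation between
#' the nearest valid neighbours.
NULL

# month index (1-based) of a date relative to the epoch month
date_month_index <- function(date, epoch) {
  12L * (as.integer(format(date, "%Y")) - as.integer(format(epoch, "%Y"))) +
    (as.integer(format(date, "%m")) - as.integer(format(epoch, "%m"))) + 1L
}

check_daily_coverage <- function(w, hotspot, epoch, n_months) {
  first <- epoch
  last <- seq(epoch, by = "month", length.out = n_months + 1L)[n_months + 1L] - 1L
  expected <- seq(first, last, by = "day")
  have <- unique(w$date)
  miss <- expected[!expected %in% have]
  if (length(miss))
    stop("daily weather gap for hotspot ", hotspot, ": missing ",
         format(miss[1]), if (length(miss) > 1)
           paste0(" (and ", length(miss) - 1L, " more days)"))
  w[w$date >= first & w$date <= last, , drop = FALSE]
}

#' @rdname covariates
#' @param daily_weather data frame with columns `hotspot_id`, `cell_id`,
#'   `date`, `rain_mm`, `tmax_c` (as produced by [sim_weather()]).
#' @param hotspot hotspot id to extract.
#' @param epoch first day of month 1.
#' @param n_months window length in months.
#' @return `monthly_rain()`: data frame `(month_index, rain_mm)` with the
#'   monthly total of across-cell daily mean rainfall.
#' @export
monthly_rain <- function(daily_weather, hotspot, epoch, n_months) {
  w <- daily_weather[daily_weather$hotspot_id == hotspot, , drop = FALSE]
  if (nrow(w) == 0L) stop("no weather rows for hotspot ", hotspot)
  w$date <- as.Date(w$date)
  w <- check_daily_coverage(w, hotspot, epoch, n_months)
  daily <- tapply(w$rain_mm, w$date, mean)
  midx <- date_month_index(as.Date(names(daily)), epoch)
  tot <- tapply(unname(daily), midx, sum)
  data.frame(month_index = as.integer(names(tot)), rain_mm = unname(tot))
}

#' @rdname covariates
#' @return `monthly_tmax()`: data frame `(month_index, tmax_c)` with the
#'   monthly mean of across-cell daily mean maximum temperature.
#' @export
monthly_tmax <- function(daily_weather, hotspot, epoch, n_months) {
  w <- daily_weather[daily_weather$hotspot_id == hotspot, , drop = FALSE]
  if (nrow(w) == 0L) stop("no weather rows for hotspot ", hotspot)
  w$date <- as.Date(w$date)
  w <- check_daily_coverage(w, hotspot, epoch, n_months)
  daily <- tapply(w$tmax_c, w$date, mean)
  midx <- date_month_index(as.Date(names(daily)), epoch)
  avg <- tapply(unname(daily), midx, mean)
  data.frame(month_index = as.integer(names(avg)), tmax_c = unname(avg))
}

#' @rdname covariates
#' @param waterbody_months data frame with columns `hotspot_id`,
#'   `month_index`, `observed_wet_area`, `visible_fraction` (as produced by
#'   [sim_wet_area()]).
#' @param visibility_threshold months with `visible_fraction` below this are
#'   treated as cloud gaps (default 0.5, i.e. less than 50% of the maximum
#'   area visible).
#' @return `wet_percentage()`: data frame `(month_index, wet_pct, valid)`
#'   where `wet_pct` is 100 x observed area / maximum observed area over
#'   valid months, and `valid` flags months meeting the visibility
#'   threshold.  Gapped months still carry their (undercounted) raw
#'   percentage; use [interpolate_gaps()] to fill them.
#' @export
wet_percentage <- function(waterbody_months, hotspot,
                           visibility_threshold = 0.5) {
  wa <- waterbody_months[waterbody_months$hotspot_id == hotspot, , drop = FALSE]
  if (nrow(wa) == 0L) stop("no waterbody rows for hotspot ", hotspot)
  wa <- wa[order(wa$month_index), ]
  if (any(wa$visible_fraction < 0 | wa$visible_fraction > 1))
    stop("visible_fraction outside [0, 1] for hotspot ", hotspot)
  valid <- wa$visible_fraction >= visibility_threshold
  if (!any(valid))
    stop("unusable site ", hotspot,
         ": no month meets the visibility threshold")
  mx <- max(wa$observed_wet_area[valid])
  if (mx <= 0) stop("unusable site ", hotspot, ": maximum wet area is zero")
  data.frame(month_index = wa$month_index,
             wet_pct = 100 * wa$observed_wet_area / mx, valid = valid)
}

#' @rdname covariates
#' @param wet_pct numeric series of wet percentages, ordered by month.
#' @param valid logical flags, `FALSE` marking cloud-gap months to fill.
#' @return `interpolate_gaps()`: the series with flagged months replaced by
#'   linear interpolation between the nearest valid neighbours; flagged
#'   leading/trailing months are extended from the nearest valid value with
#'   a warning.  Valid months are returned untouched.
#' @export
interpolate_gaps <- function(wet_pct, valid) {
  stopifnot(length(wet_pct) == length(valid))
  if (!any(valid)) stop("unusable series: every month is a cloud gap")
  if (all(valid)) return(wet_pct)
  if (!valid[1] || !valid[length(valid)])
    warning("cloud gap at series edge: extending nearest valid value")
  idx <- seq_along(wet_pct)
  filled <- stats::approx(idx[valid], wet_pct[valid], xout = idx,
                          method = "linear", rule = 2)$y
  filled[valid] <- wet_pct[valid]
  filled
}

#' Attach monthly covariates to a BuD/richness panel
#'
#' Joins monthly rainfall, temperature and gap-filled wet percentage (and
#' its one-month lag) onto a panel of monthly site records.
#'
#' @param panel data frame with columns `hotspot_id`, `month_index` (a
#'   complete 1..T panel per hotspot, e.g. from [build_panel()]).
#' @param daily_weather,waterbody_months input tables (see [monthly_rain()],
#'   [wet_percentage()]).
#' @param epoch first day of month 1.
#' @param visibility_threshold see [wet_percentage()].
#' @return the panel with columns `rain_mm`, `tmax_c`, `wet_pct`,
#'   `wet_pct_lag1` added.
#' @export
add_covariates <- function(panel, daily_weather, waterbody_months,
                           epoch, visibility_threshold = 0.5) {
  n_months <- max(panel$month_index)
  out <- vector("list", length(unique(panel$hotspot_id)))
  hs <- unique(panel$hotspot_id)
  for (i in seq_along(hs)) {
    h <- hs[i]
    p <- panel[panel$hotspot_id == h, , drop = FALSE]
    p <- p[order(p$month_index), ]
    rain <- monthly_rain(daily_weather, h, epoch, n_months)
    tmax <- monthly_tmax(daily_weather, h, epoch, n_months)
    wp <- wet_percentage(waterbody_months, h, visibility_threshold)
    filled <- interpolate_gaps(wp$wet_pct, wp$valid)
    p$rain_mm <- rain$rain_mm[match(p$month_index, rain$month_index)]
    p$tmax_c <- tmax$tmax_c[match(p$month_index, tmax$month_index)]
    p$wet_pct <- filled[match(p$month_index, wp$month_index)]
    p$wet_pct_lag1 <- c(NA_real_, p$wet_pct[-nrow(p)])
    out[[i]] <- p
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
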