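#' Candidate driver sets for the hotspot-specific count models
#'
#' Enumerates the candidate combinations of wet-surface-area and lagged
#' species-richness drivers.  For BuD counts there are five candidates:
#' (1) current-month wet percentage alone, (2) previous-month wet percentage
#' alone, (3) previous-month richness alone, (4) current wet + lagged
#' richness, (5) lagged wet + lagged richness.  For richness there are two:
#' (1) current wet, (2) lagged wet.  Monthly rainfall, maximum temperature,
#' month-of-year factor and the month-index trend enter every candidate.
#' Current and lagged wet percentage never enter together (their
#' collinearity fails the VIF screen).
#'
#' @param dependent `"bud"`, `"richness_all"` or `"richness_water"`.
#' @return list of model specs (`dependent`, `candidate_id`, `wet`,
#'   `use_spp_lag`).
#' @export
candidate_specs <- function(dependent = c("bud", "richness_all",
                                          "richness_water")) {
  dependent <- match.arg(dependent)
  mk <- function(id, wet, spp) list(dependent = dependent, candidate_id = id,
                                    wet = wet, use_spp_lag = spp)
  if (dependent == "bud")
    list(mk(1L, "current", FALSE), mk(2L, "lag1", FALSE),
         mk(3L, NULL, TRUE), mk(4L, "current", TRUE), mk(5L, "lag1", TRUE))
  else
    list(mk(1L, "current", FALSE), mk(2L, "lag1", FALSE))
}

response_column <- function(dependent) {
  switch(dependent, bud = "bud_count", richness_all = "richness_all",
         richness_water = "richness_water",
         stop("unknown dependent: ", dependent))
}

#' Build the design matrix and response for one candidate model
#'
#' Columns: intercept, monthly rainfall, monthly mean maximum temperature,
#' the candidate's wet-percentage term (current or one-month lag), lagged
#' all-species richness (candidates that include it), 11 month-of-year
#' indicators (reference level = the month-of-year of month index 1), and
#' the month-index trend.  Rows whose lagged terms are undefined (the first
#' month) are dropped.
#'
#' @param panel single-hotspot panel with columns `month_index`,
#'   `month_of_year`, `bud_count`, `richness_all`, `richness_water`,
#'   `rain_mm`, `tmax_c`, `wet_pct` and `wet_pct_lag1`.
#' @param spec one element of [candidate_specs()].
#' @return list with `X` (design matrix), `y` (response), `month_index`
#'   (retained rows) and `spec`.
#' @export
build_design <- function(panel, spec) {
  p <- panel[order(panel$month_index), , drop = FALSE]
  Tn <- nrow(p)
  if (Tn < 14L)
    stop("insufficient data: need at least 14 months to identify ",
         "11 month-of-year effects plus trend (got ", Tn, ")")
  if (!all(diff(p$month_index) == 1L))
    stop("panel must be a complete consecutive month_index series")
  lag1 <- function(x) c(NA, x[-length(x)])
  wet <- switch(spec$wet %||% "none",
                current = p$wet_pct,
                lag1 = if ("wet_pct_lag1" %in% names(p)) p$wet_pct_lag1
                       else lag1(p$wet_pct),
                none = NULL)
  spp <- if (isTRUE(spec$use_spp_lag)) lag1(p$richness_all) else NULL

  ref <- p$month_of_year[1]
  moy_levels <- setdiff(sort(unique(p$month_of_year)), ref)
  M <- sapply(moy_levels, function(m) as.numeric(p$month_of_year == m))
  colnames(M) <- paste0("moy", moy_levels)

  cols <- list(intercept = rep(1, Tn), rain = p$rain_mm, temp = p$tmax_c)
  if (!is.null(wet)) cols[[wet_term_name(spec)]] <- wet
  if (!is.null(spp)) cols$spp_lag1 <- spp
  X <- cbind(do.call(cbind, cols), M, trend = p$month_index)

  y <- p[[response_column(spec$dependent)]]
  keep <- stats::complete.cases(X)
  list(X = X[keep, , drop = FALSE], y = y[keep],
       month_index = p$month_index[keep], spec = spec)
}

# name of the wet coefficient in a design built from `spec`, or NULL
wet_term_name <- function(spec) {
  if (is.null(spec$wet)) NULL
  else paste0("wet_", if (spec$wet == "current") "t" else "lag1")
}

#' Variance-inflation-factor screen for candidate driver sets
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` for each continuous candidate column,
#' where `R^2_j` comes from the least-squares regression of column j on the
#' remaining columns (plus an intercept).  Any candidate set containing a
#' column with VIF above the threshold is inadmissible; perfectly collinear
#' columns report `Inf` rather than failing.  The canonical exclusion this
#' screen reproduces is current-month with previous-month wet percentage.
#'
#' @param candidate_columns numeric matrix or data frame of the continuous
#'   candidate drivers (two or more columns).
#' @param threshold admissibility cutoff (default 3).
#' @return list with `vif` (named vector) and `admissible` (TRUE iff all
#'   VIFs are at or below the threshold).
#' @export
vif_screen <- function(candidate_columns, threshold = 3) {
  X <- as.matrix(candidate_columns)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (ncol(X) < 2L) {
    v <- stats::setNames(rep(1, ncol(X)), colnames(X))
    return(list(vif = v, admissible = TRUE))
  }
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    Zj <- cbind(1, X[, -j, drop = FALSE])
    res <- tryCatch(stats::lsfit(Zj, yj, intercept = FALSE)$residuals,
                    error = function(e) yj - mean(yj))
    tss <- sum((yj - mean(yj))^2)
    if (tss <= 0) return(Inf)
    r2 <- 1 - sum(res^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vifs) <- colnames(X)
  list(vif = vifs, admissible = all(vifs <= threshold))
}
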