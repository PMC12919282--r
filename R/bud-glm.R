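#' Fit a hotspot count-regression model for visitation or richness
#'
#' The main fitting interface.  For one hotspot's monthly panel it builds
#' the design for a chosen candidate driver set (see [candidate_specs()]),
#' fits the Poisson model by IRLS and -- unless `family` forces one form --
#' the NB2 negative binomial, picks the functional form by the boundary
#' likelihood-ratio test on the overdispersion parameter, and attaches
#' Newey-West HAC standard errors for inference on the coefficients.
#'
#' The fitted object reports a deviance-based pseudo-R-squared
#' (`1 - deviance/null deviance`) together with its "linear equivalent",
#' the squared correlation between fitted and observed counts.
#'
#' @param panel single-hotspot monthly panel (complete consecutive months)
#'   with response and covariate columns; see [build_design()].
#' @param dependent `"bud"`, `"richness_all"` or `"richness_water"`.
#' @param candidate candidate id (BuD: 1-5; richness: 1-2).
#' @param family `"auto"` (LR test chooses), `"poisson"` or `"negbin"`.
#' @param hac_lag Newey-West truncation lag; `NULL` for the plug-in default
#'   `floor(4 * (T/100)^(2/9))`.
#' @param tol,maxit convergence control passed to the engine.
#' @return an object of class `"bud_glm"`.
#' @seealso [run_candidates()] to fit and compare all candidates;
#'   [fit_poisson()] and [fit_negbin()] for the engine;
#'   [direct_change()] / [mediated_change()] for scenario projection.
#' @examples
#' cfg <- sim_config(n_hotspots = 1, n_months = 48, seed = 42)
#' pan <- sim_monthly_panel(cfg)$panel
#' pan$bud_count <- pan$bud
#' pan$wet_pct <- pan$wet_pct_true
#' pan$wet_pct_lag1 <- c(NA, pan$wet_pct[-nrow(pan)])
#' pan$richness_all <- pan$richness_all_true
#' fit <- bud_glm(pan, "bud", candidate = 2)
#' summary(fit)
#' @export
bud_glm <- function(panel, dependent = c("bud", "richness_all",
                                         "richness_water"),
                    candidate = 1L, family = c("auto", "poisson", "negbin"),
                    hac_lag = NULL, tol = 1e-10, maxit = 100L) {
  dependent <- match.arg(dependent)
  family <- match.arg(family)
  specs <- candidate_specs(dependent)
  ids <- vapply(specs, `[[`, integer(1), "candidate_id")
  if (!candidate %in% ids)
    stop("candidate ", candidate, " is not defined for dependent '",
         dependent, "'")
  spec <- specs[[match(candidate, ids)]]
  d <- build_design(panel, spec)
  fit <- fit_bud_design(d, family, hac_lag, tol, maxit)
  fit$hotspot_id <- if ("hotspot_id" %in% names(panel))
    as.character(panel$hotspot_id[1]) else NA_character_
  fit$call <- match.call()
  fit
}

# Core fit on a prepared design; shared by bud_glm() and run_candidates().
fit_bud_design <- function(d, family = "auto", hac_lag = NULL,
                           tol = 1e-10, maxit = 100L) {
  pois <- fit_poisson(d$X, d$y, tol, maxit)
  nb <- NULL; lr <- NULL
  engine <- pois
  if (family != "poisson") {
    nb <- fit_negbin(d$X, d$y, tol, maxit)
    if (family == "negbin") {
      engine <- nb
    } else {
      lr <- lr_overdispersion_test(pois, nb)
      engine <- if (lr$chosen_family == "negbin") nb else pois
    }
  }
  hac_lag <- hac_lag %||% nw_plugin_lag(length(d$y))
  V <- hac_covariance(engine, hac_lag)
  out <- list(
    coefficients = engine$beta, family = engine$family,
    alpha = engine$alpha, alpha_se = engine$alpha_se,
    engine = engine, vcov = V,
    model_vcov = solve_info(engine$info, diag(nrow(engine$info))),
    hac_lag = hac_lag, loglik = engine$loglik, df = engine$df,
    aic = -2 * engine$loglik + 2 * engine$df,
    pseudo_r2 = deviance_pseudo_r2(d$y, engine),
    r2_linear = if (stats::sd(engine$mu) > 0 && stats::sd(d$y) > 0)
      stats::cor(engine$mu, d$y)^2 else NA_real_,
    fitted.values = engine$mu, y = d$y, X = d$X,
    month_index = d$month_index, spec = d$spec, lr_test = lr,
    n = length(d$y))
  dimnames(out$model_vcov) <- dimnames(V)
  class(out) <- "bud_glm"
  out
}

# saturated NB2 log-likelihood (mu = y), with 0 * log(0) taken as 0
nb2_saturated <- function(y, alpha) {
  if (alpha <= 0) return(sum(stats::dpois(y, y, log = TRUE)))
  r <- 1 / alpha
  term <- lgamma(y + r) - lgamma(r) - lfactorial(y) +
    r * log(r / (r + y)) + ifelse(y > 0, y * log(y / (r + y)), 0)
  sum(term)
}

deviance_pseudo_r2 <- function(y, engine) {
  ones <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  null_fit <- if (engine$family == "negbin") fit_negbin(ones, y)
  else fit_poisson(ones, y)
  ll_sat <- if (engine$family == "negbin") nb2_saturated(y, engine$alpha)
  else sum(stats::dpois(y, y, log = TRUE))
  dev <- 2 * (ll_sat - engine$loglik)
  dev0 <- 2 * (ll_sat - null_fit$loglik)
  if (dev0 <= 0) return(NA_real_)
  max(0, min(1, 1 - dev / dev0))
}

#' @export
print.bud_glm <- function(x, ...) {
  cat(sprintf("Count model (%s) for %s, candidate %d%s\n",
              x$family, x$spec$dependent, x$spec$candidate_id,
              if (!is.na(x$hotspot_id)) paste0(", hotspot ", x$hotspot_id)
              else ""))
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.2f, pseudo-R2 = %.3f\n",
              x$n, x$loglik, x$aic, x$pseudo_r2))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.bud_glm <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  z <- object$coefficients / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- cbind(Estimate = object$coefficients, `HAC SE` = se, z = z,
               `Pr(>|z|)` = p)
  out <- list(fit = object, coefficients = tab,
              signif_05 = p < 0.05, signif_10 = p >= 0.05 & p < 0.10)
  class(out) <- "summary.bud_glm"
  out
}

#' @export
print.summary.bud_glm <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nCoefficients (Newey-West HAC, lag", f$hac_lag, "):\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (f$family == "negbin")
    cat(sprintf("Overdispersion alpha = %.4f (SE %.4f)\n", f$alpha,
                f$alpha_se))
  if (!is.null(f$lr_test))
    cat(sprintf("LR overdispersion test: stat %.3f, p %.4f -> %s\n",
                f$lr_test$statistic, f$lr_test$p_value,
                f$lr_test$chosen_family))
  cat(sprintf("Linear R2 equivalent (cor(fitted, y)^2) = %.3f\n",
              f$r2_linear))
  invisible(x)
}

#' @export
coef.bud_glm <- function(object, ...) object$coefficients

#' @export
vcov.bud_glm <- function(object, type = c("hac", "model"), ...) {
  switch(match.arg(type), hac = object$vcov, model = object$model_vcov)
}

#' @export
logLik.bud_glm <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n,
            class = "logLik")
}

#' @export
fitted.bud_glm <- function(object, ...) object$fitted.values

#' @export
residuals.bud_glm <- function(object,
                              type = c("deviance", "pearson", "response"),
                              ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted.values
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu * (1 + object$alpha * mu)),
         deviance = {
           dd <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
           sign(y - mu) * sqrt(pmax(dd, 0))
         })
}

#' @export
predict.bud_glm <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X
  else if (is.matrix(newdata)) newdata
  else build_design(newdata, object$spec)$X
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else exp(eta)
}

#' @export
simulate.bud_glm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  sims <- replicate(nsim, if (object$family == "negbin" && object$alpha > 0)
    stats::rnbinom(length(mu), mu = mu, size = 1 / object$alpha)
    else stats::rpois(length(mu), mu), simplify = FALSE)
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  rownames(out) <- object$month_index
  out
}

#' @export
plot.bud_glm <- function(x, ...) {
  graphics::plot(x$month_index, x$y, type = "h", col = "grey50",
                 xlab = "month index", ylab = x$spec$dependent,
                 main = sprintf("Observed and fitted (%s, candidate %d)",
                                x$family, x$spec$candidate_id), ...)
  graphics::lines(x$month_index, x$fitted.values, col = "firebrick", lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = c(1, 2),
                   col = c("grey50", "firebrick"),
                   legend = c("observed", "fitted"))
  invisible(x)
}

#' Fit and compare all candidate driver sets for one hotspot
#'
#' Fits every VIF-admissible candidate in [candidate_specs()] (Poisson and
#' NB2, form chosen by the overdispersion LR test), and selects the
#' best-fitting candidate by minimum AIC; deviance pseudo-R-squared and its
#' linear equivalent are reported alongside for every candidate.
#'
#' @inheritParams bud_glm
#' @param vif_threshold admissibility cutoff for [vif_screen()].
#' @return object of class `"bud_candidates"`: list with `fits` (per
#'   candidate id), `table` (comparison data frame), `best` (the winning
#'   [bud_glm()] fit) and `vif` (per-candidate VIF vectors).
#' @export
run_candidates <- function(panel, dependent = c("bud", "richness_all",
                                                "richness_water"),
                           family = c("auto", "poisson", "negbin"),
                           hac_lag = NULL, vif_threshold = 3) {
  dependent <- match.arg(dependent)
  family <- match.arg(family)
  specs <- candidate_specs(dependent)
  fits <- list(); vifs <- list()
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    d <- build_design(panel, sp)
    cont <- intersect(colnames(d$X), c("rain", "temp", "wet_t", "wet_lag1",
                                       "spp_lag1"))
    scr <- vif_screen(d$X[, cont, drop = FALSE], vif_threshold)
    vifs[[as.character(sp$candidate_id)]] <- scr$vif
    if (!scr$admissible) {
      rows[[i]] <- data.frame(candidate = sp$candidate_id, admissible = FALSE,
                              family = NA, aic = NA, loglik = NA,
                              pseudo_r2 = NA, r2_linear = NA, alpha = NA)
      next
    }
    f <- fit_bud_design(d, family, hac_lag)
    f$hotspot_id <- if ("hotspot_id" %in% names(panel))
      as.character(panel$hotspot_id[1]) else NA_character_
    fits[[as.character(sp$candidate_id)]] <- f
    rows[[i]] <- data.frame(candidate = sp$candidate_id, admissible = TRUE,
                            family = f$family, aic = f$aic, loglik = f$loglik,
                            pseudo_r2 = f$pseudo_r2,
                            r2_linear = f$r2_linear, alpha = f$alpha)
  }
  tab <- do.call(rbind, rows)
  if (length(fits) == 0L)
    stop("no admissible candidate model (all failed the VIF screen)")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- fits[[names(which.min(aics))]]
  out <- list(fits = fits, table = tab, best = best, vif = vifs,
              dependent = dependent)
  class(out) <- "bud_candidates"
  out
}

#' @export
print.bud_candidates <- function(x, ...) {
  cat("Candidate comparison for", x$dependent, "\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("Best (min AIC): candidate", x$best$spec$candidate_id, "(",
      x$best$family, ")\n")
  invisible(x)
}
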