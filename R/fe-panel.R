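#' Fixed-effects Poisson model for the stacked hotspot panel
#'
#' Estimates common time-varying driver effects across hotspots while
#' absorbing site-specific intercepts, by maximizing the Poisson conditional
#' likelihood: conditioning each site's monthly counts on their site total
#' turns the model into a multinomial with cell probabilities
#' `p_it = exp(x_it b) / sum_s exp(x_is b)`, which eliminates the fixed
#' effects.  The resulting slope estimates coincide with the dummy-variable
#' (one intercept per site) Poisson MLE.  Month-of-year and trend terms are
#' common across sites.  Sites with all-zero counts carry no information and
#' are dropped with a warning.
#'
#' @param stacked_panel monthly panel for two or more hotspots (complete
#'   consecutive months per hotspot), with the columns [build_design()]
#'   expects plus `hotspot_id`.
#' @param dependent,candidate the driver set, as in [bud_glm()].
#' @param tol,maxit Newton convergence control (relative log-likelihood
#'   change below `tol`, default 1e-10).
#' @return object of class `"fe_poisson"` with `coefficients` (the within
#'   slopes; no intercepts), `loglik` (conditional), `n_sites`, `spec`.
#' @seealso [cluster_bootstrap()] for hotspot-clustered inference.
#' @export
fe_poisson <- function(stacked_panel,
                       dependent = c("bud", "richness_all", "richness_water"),
                       candidate = 2L, tol = 1e-10, maxit = 100L) {
  dependent <- match.arg(dependent)
  specs <- candidate_specs(dependent)
  ids <- vapply(specs, `[[`, integer(1), "candidate_id")
  spec <- specs[[match(candidate, ids)]]
  parts <- split_panel_designs(stacked_panel, spec)
  fit <- fe_poisson_engine(parts$Xs, parts$ys, tol, maxit)
  fit$spec <- spec
  fit$hotspots <- parts$hotspots
  fit$panel <- stacked_panel
  class(fit) <- "fe_poisson"
  fit
}

split_panel_designs <- function(stacked_panel, spec) {
  hs <- unique(stacked_panel$hotspot_id)
  Xs <- list(); ys <- list(); keep <- character(0)
  for (h in hs) {
    d <- build_design(stacked_panel[stacked_panel$hotspot_id == h, ,
                                    drop = FALSE], spec)
    if (sum(d$y) == 0) {
      warning("hotspot ", h, " has all-zero counts and is dropped ",
              "from the fixed-effects fit")
      next
    }
    Xs[[h]] <- d$X[, colnames(d$X) != "intercept", drop = FALSE]
    ys[[h]] <- d$y
    keep <- c(keep, h)
  }
  if (length(keep) < 1L) stop("no usable hotspot in panel")
  list(Xs = Xs, ys = ys, hotspots = keep)
}

# Newton-Raphson on the conditional (multinomial) log-likelihood.
fe_poisson_engine <- function(Xs, ys, tol = 1e-10, maxit = 100L) {
  p <- ncol(Xs[[1]])
  beta <- rep(0, p)
  ll_val <- function(beta) {
    ll <- 0
    for (i in seq_along(Xs)) {
      eta <- drop(Xs[[i]] %*% beta)
      ll <- ll + sum(ys[[i]] * (eta - logsumexp(eta)))
    }
    ll
  }
  ll <- -Inf
  for (it in seq_len(maxit)) {
    g <- numeric(p); H <- matrix(0, p, p)
    for (i in seq_along(Xs)) {
      X <- Xs[[i]]; y <- ys[[i]]
      eta <- drop(X %*% beta)
      pr <- exp(eta - logsumexp(eta))
      Yi <- sum(y)
      xbar <- drop(crossprod(X, pr))
      g <- g + drop(crossprod(X, y)) - Yi * xbar
      H <- H + Yi * (crossprod(X, X * pr) - tcrossprod(xbar))
    }
    step <- solve_info(H, g)
    # halve the step until the conditional likelihood does not decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- ll_val(cand)
      if (is.finite(ll_new) && (ll_new >= ll || lam < 1e-8)) break
      lam <- lam / 2
    }
    beta <- cand
    if (is.finite(ll) && abs(ll_new - ll) / (abs(ll_new) + 0.1) < tol) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  list(coefficients = stats::setNames(beta, colnames(Xs[[1]])), loglik = ll,
       n_sites = length(Xs), iter = it, converged = it < maxit)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.fe_poisson <- function(x, ...) {
  cat(sprintf(
    "Fixed-effects Poisson panel fit (%s, candidate %d): %d sites, conditional logLik %.2f\n",
    x$spec$dependent, x$spec$candidate_id, x$n_sites, x$loglik))
  print(round(x$coefficients, 5))
  if (!is.null(x$boot_cov))
    cat(sprintf("Cluster bootstrap: %d replicates, seed %d\n",
                x$n_reps, x$seed))
  invisible(x)
}

#' @export
coef.fe_poisson <- function(object, ...) object$coefficients

#' @export
vcov.fe_poisson <- function(object, ...) {
  if (is.null(object$boot_cov))
    stop("no bootstrap covariance attached; run cluster_bootstrap()")
  object$boot_cov
}

#' @export
summary.fe_poisson <- function(object, ...) {
  if (is.null(object$boot_cov)) {
    print(object)
    return(invisible(object))
  }
  se <- sqrt(pmax(diag(object$boot_cov), 0))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Boot SE` = se, z = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  print(object)
  stats::printCoefmat(tab, P.values = TRUE, has.Pvalue = TRUE)
  invisible(tab)
}

#' @export
confint.fe_poisson <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$boot_cov))
    stop("no bootstrap covariance attached; run cluster_bootstrap()")
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  se <- sqrt(pmax(diag(object$boot_cov)[parm], 0))
  # with few clusters (ten hotspots) t quantiles on G - 1 degrees of
  # freedom give much better finite-sample coverage than normal ones
  crit <- stats::qt(1 - (1 - level) / 2, df = object$n_sites - 1L)
  out <- cbind(cf[parm] - crit * se, cf[parm] + crit * se)
  colnames(out) <- paste(format(100 * c((1 - level) / 2,
                                        1 - (1 - level) / 2)), "%")
  out
}

#' Hotspot-clustered bootstrap covariance for the panel model
#'
#' Resamples entire hotspot series with replacement (the hotspot is the
#' resampling unit), refits the fixed-effects Poisson model on each
#' replicate, and returns the covariance of the replicate coefficient
#' vectors.  Resampled duplicate sites receive distinct cluster labels so
#' each refit is well-posed.  Replicates drawing fewer than two distinct
#' hotspots are redrawn (at most ten redraws each).
#'
#' @param fit a [fe_poisson()] object (its stored panel and spec are
#'   reused).
#' @param n_reps bootstrap replications (default 999).
#' @param seed integer seed for the resampling.
#' @return the `fit` with `boot_cov` (covariance matrix), `boot_reps`
#'   (replicate coefficients), `n_reps` and `seed` attached.
#' @export
cluster_bootstrap <- function(fit, n_reps = 999L, seed = 1L) {
  stopifnot(inherits(fit, "fe_poisson"), n_reps >= 2L)
  spec <- fit$spec
  hs <- fit$hotspots
  designs <- split_panel_designs(fit$panel, spec)
  reps <- matrix(NA_real_, n_reps, length(fit$coefficients),
                 dimnames = list(NULL, names(fit$coefficients)))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      for (attempt in seq_len(10L)) {
        draw <- sample(hs, length(hs), replace = TRUE)
        if (length(unique(draw)) >= 2L) break
        if (attempt == 10L)
          stop("could not draw a replicate with two distinct hotspots")
      }
      Xs <- designs$Xs[draw]
      ys <- designs$ys[draw]
      names(Xs) <- names(ys) <- paste0(draw, ".", seq_along(draw))
      reps[r, ] <- fe_poisson_engine(Xs, ys)$coefficients
    }
  })
  fit$boot_cov <- stats::cov(reps)
  fit$boot_reps <- reps
  fit$n_reps <- n_reps
  fit$seed <- as.integer(seed)
  fit
}
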