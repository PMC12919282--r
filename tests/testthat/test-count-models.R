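test_that("design construction gives the documented shapes", {
  pan <- truth_panel(small_cfg(seed = 1))
  specs <- candidate_specs("bud")
  d1 <- build_design(pan, specs[[1]])
  expect_equal(dim(d1$X), c(72L, 16L))
  d5 <- build_design(pan, specs[[5]])
  expect_equal(nrow(d5$X), 71L)
  expect_equal(ncol(d5$X), 17L)
  # candidates 1 and 2 differ only in the wet column, shifted by one month
  d2 <- build_design(pan, specs[[2]])
  expect_equal(unname(d2$X[, "wet_lag1"]), unname(d1$X[1:71, "wet_t"]))
  same <- setdiff(colnames(d1$X), "wet_t")
  expect_equal(d1$X[2:72, same], d2$X[, same])
  expect_error(build_design(pan[1:13, ], specs[[1]]), "insufficient")
})

test_that("Poisson IRLS solves the score equations and known cases", {
  X <- matrix(1, 2, 1, dimnames = list(NULL, "intercept"))
  f <- fit_poisson(X, c(2L, 4L))
  expect_equal(unname(f$beta), log(3), tolerance = 1e-10)

  pan <- truth_panel(small_cfg(seed = 7))
  d <- build_design(pan, candidate_specs("bud")[[2]])
  fit <- fit_poisson(d$X, d$y)
  expect_lt(max(abs(crossprod(d$X, d$y - fit$mu))), 1e-8)
  expect_equal(sum(fit$mu), sum(d$y), tolerance = 1e-10)
  expect_true(all(fit$mu > 0))
})

test_that("Poisson estimates recover the truth and match glm", {
  set.seed(314)
  n <- 5000
  X <- cbind(intercept = 1, x1 = rnorm(n), x2 = runif(n))
  beta <- c(1.0, 0.25, -0.4)
  y <- rpois(n, exp(drop(X %*% beta)))
  f <- fit_poisson(X, y)
  se <- sqrt(diag(solve(f$info)))
  expect_true(all(abs(f$beta - beta) <= 3 * se))
  g <- stats::glm(y ~ X[, 2] + X[, 3], family = stats::poisson)
  expect_lt(max(abs(f$beta - unname(coef(g)))), 1e-6)
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-8)
})

test_that("NB2 estimation recovers alpha and collapses to Poisson", {
  set.seed(99)
  n <- 5000
  X <- cbind(intercept = 1, x = rnorm(n))
  mu <- exp(1.2 + 0.3 * X[, 2])

  # equidispersed truth: alpha pinned near zero, beta equals Poisson
  y0 <- rpois(n, mu)
  nb0 <- fit_negbin(X, y0)
  p0 <- fit_poisson(X, y0)
  expect_lt(nb0$alpha, 0.05)
  expect_lt(max(abs(nb0$beta - p0$beta)), 1e-4)

  # overdispersed truth: alpha recovered, matches MASS::glm.nb
  y1 <- MASS::rnegbin(n, mu = mu, theta = 2)
  nb1 <- fit_negbin(X, y1)
  expect_lt(abs(nb1$alpha - 0.5), 3 * nb1$alpha_se)
  gn <- MASS::glm.nb(y1 ~ X[, 2])
  expect_lt(max(abs(nb1$beta - unname(coef(gn)))), 1e-5)
  expect_equal(nb1$alpha, 1 / gn$theta, tolerance = 1e-4)
  expect_equal(nb1$loglik, as.numeric(stats::logLik(gn)), tolerance = 1e-6)
})

test_that("HAC covariance matches the brute-force double sum and White", {
  pan <- truth_panel(small_cfg(seed = 23))
  d <- build_design(pan, candidate_specs("bud")[[2]])
  fit <- fit_poisson(d$X, d$y)
  S <- fit$scores
  n <- nrow(S); k <- ncol(S)
  bread <- solve(fit$info)

  # lag 0: the White heteroskedasticity-robust sandwich
  white <- bread %*% (crossprod(S) * n / (n - k)) %*% bread
  expect_lt(max(abs(hac_covariance(fit, lag = 0) - white)), 1e-10)

  # naive double-sum oracle with Bartlett weights
  for (L in c(2, 5)) {
    meat <- matrix(0, k, k)
    for (t in 1:n) for (s in 1:n) {
      l <- abs(t - s)
      if (l <= L) meat <- meat + (1 - l / (L + 1)) * S[t, ] %o% S[s, ]
    }
    oracle <- bread %*% (meat * n / (n - k)) %*% bread
    expect_lt(max(abs(hac_covariance(fit, lag = L) - oracle)), 1e-10)
  }
})

test_that("HAC covariance agrees with sandwich::NeweyWest on a glm fit", {
  pan <- truth_panel(small_cfg(seed = 29))
  d <- build_design(pan, candidate_specs("bud")[[1]])
  fit <- fit_poisson(d$X, d$y)
  df <- as.data.frame(d$X[, -1])
  df$y <- d$y
  g <- stats::glm(y ~ ., data = df, family = stats::poisson)
  V <- sandwich::NeweyWest(g, lag = 3, prewhite = FALSE, adjust = TRUE)
  expect_lt(max(abs(hac_covariance(fit, lag = 3) - V)) / max(abs(V)), 1e-4)
})

test_that("HAC and model-based standard errors agree under iid sampling", {
  set.seed(5150)
  n <- 2000
  X <- cbind(intercept = 1, x = rnorm(n))
  y <- rpois(n, exp(1 + 0.2 * X[, 2]))
  fit <- fit_poisson(X, y)
  hac_se <- sqrt(diag(hac_covariance(fit)))
  mod_se <- sqrt(diag(solve(fit$info)))
  expect_true(all(abs(hac_se / mod_se - 1) < 0.15))
})

test_that("the overdispersion LR test behaves at and off the boundary", {
  fake <- function(ll) list(loglik = ll, beta = 0)
  out <- lr_overdispersion_test(fake(-10), fake(-10))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 0.5)
  expect_equal(out$chosen_family, "poisson")
  expect_error(lr_overdispersion_test(fake(-10), fake(-11)), "inconsistent")

  # strong overdispersion: the negative binomial must win decisively
  set.seed(404)
  X <- cbind(intercept = rep(1, 300))
  y <- MASS::rnegbin(300, mu = 8, theta = 1)
  lr <- lr_overdispersion_test(fit_poisson(X, y), fit_negbin(X, y))
  expect_equal(lr$chosen_family, "negbin")
  expect_lt(lr$p_value, 1e-6)
})

test_that("the VIF screen admits orthogonal and rejects collinear sets", {
  x <- rep(c(-1, 1), 50)
  z <- rep(c(-1, 1), each = 50)
  scr <- vif_screen(cbind(a = x, b = z))
  expect_equal(unname(scr$vif), c(1, 1), tolerance = 1e-12)
  expect_true(scr$admissible)

  dup <- vif_screen(cbind(a = x, b = x))
  expect_true(all(is.infinite(dup$vif)))
  expect_false(dup$admissible)

  # an AR(1) series at rho = 0.95 and its lag: R^2 ~ rho^2, VIF > 3
  set.seed(11)
  n <- 2000
  ar <- as.numeric(stats::arima.sim(list(ar = 0.95), n + 1))
  scr2 <- vif_screen(cbind(cur = ar[-1], lag = ar[-(n + 1)]))
  expect_false(scr2$admissible)
  expect_true(all(scr2$vif > 3))
})

test_that("candidate comparison selects by AIC and reports every fit", {
  pan <- truth_panel(small_cfg(seed = 17))
  rc <- run_candidates(pan, "richness_all")
  expect_equal(nrow(rc$table), 2L)
  ok <- rc$table[rc$table$admissible, ]
  expect_equal(rc$best$spec$candidate_id, ok$candidate[which.min(ok$aic)])
  expect_true(all(ok$pseudo_r2 >= 0 & ok$pseudo_r2 <= 1))

  # AIC is invariant to the order of design columns
  d <- build_design(pan, candidate_specs("bud")[[2]])
  f1 <- fit_poisson(d$X, d$y)
  perm <- sample(ncol(d$X))
  f2 <- fit_poisson(d$X[, perm], d$y)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$beta[colnames(d$X)[perm]], f2$beta, tolerance = 1e-6)
})

test_that("bud_glm methods are coherent", {
  pan <- truth_panel(small_cfg(seed = 37))
  fit <- bud_glm(pan, "bud", candidate = 2)
  expect_s3_class(fit, "bud_glm")
  expect_equal(unname(fitted(fit)), unname(predict(fit)))
  expect_equal(length(residuals(fit)), fit$n)
  expect_equal(dim(vcov(fit)), c(16L, 16L))
  expect_lt(max(abs(vcov(fit) - t(vcov(fit)))), 1e-10)
  expect_true(all(diag(vcov(fit)) >= 0))
  expect_equal(attr(logLik(fit), "df"), fit$df)
  expect_equal(AIC(fit), fit$aic)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n, 3L))
  expect_true(all(sims >= 0))
  s <- summary(fit)
  expect_s3_class(s, "summary.bud_glm")
  expect_output(print(s), "HAC")
})
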