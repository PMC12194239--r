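test_that("trap_haul_table validates levels and counts", {
  df <- data.frame(year = "2016", month = "January", zone = "RC_B",
                   depth_stratum = "50-100", lobster_size = "small",
                   urchin_count = 3)
  tab <- trap_haul_table(df)
  expect_s3_class(tab, "trap_haul_table")
  expect_identical(levels(tab$year)[1], "2015")
  expect_identical(levels(tab$month)[1], "October")
  expect_identical(levels(tab$lobster_size)[1], "large")
  expect_error(trap_haul_table(transform(df, zone = "RC_X")), "outside")
  expect_error(trap_haul_table(transform(df, month = "June")), "outside")
  expect_error(trap_haul_table(transform(df, urchin_count = -1)),
               "non-negative")
  expect_error(trap_haul_table(transform(df, urchin_count = 1.5)),
               "non-negative")
})

test_that("design matrix uses treatment coding with the stated references", {
  tab <- make_trap_table(catch_scenario(n = 600, seed = 3))
  # one predictor with 2 levels: intercept + 1 dummy
  X <- design_matrix(tab, "size")
  expect_equal(ncol(X), 2)
  expect_identical(colnames(X), c("(Intercept)", "lobster_sizesmall"))
  # an all-reference-level record codes as (1, 0, ..., 0)
  ref <- trap_haul_table(data.frame(
    year = "2015", month = "October", zone = "RC_A", depth_stratum = "0-50",
    lobster_size = "large", urchin_count = 0))
  tab2 <- rbind(tab, ref)
  class(tab2) <- class(tab)
  Xf <- design_matrix(tab2, c("year", "month", "zone", "depth", "size"))
  expect_equal(unname(Xf[nrow(Xf), ]), c(1, rep(0, ncol(Xf) - 1)))
  # the full five-predictor design: 24 columns + phi + pi = 26 parameters
  expect_equal(ncol(Xf) + 2, 26)
})

test_that("zinb_loglik matches hand values and reduces to plain NB at pi = 0", {
  # NB(0; mu=1, phi=1) = 1/2, so the zero-record likelihood is 0.75
  expect_equal(zinb_loglik(0, matrix(1), 0, phi = 1, pi = 0.5), log(0.75))
  set.seed(21)
  y <- rpois(40, 2)
  X <- cbind(1, rnorm(40))
  beta <- c(0.3, -0.2)
  expect_equal(zinb_loglik(y, X, beta, phi = 1.7, pi = 0),
               sum(dnbinom(y, size = 1.7, mu = exp(drop(X %*% beta)),
                           log = TRUE)))
  expect_error(zinb_loglik(-1, matrix(1), 0, 1, 0), "non-negative")
  expect_error(zinb_loglik(0.5, matrix(1), 0, 1, 0), "non-negative")
})

test_that("ZINB per-record probabilities sum to one over the support", {
  X <- matrix(1, 1, 1)
  for (par in list(c(beta = 0.0, phi = 1, pi = 0.3),
                   c(beta = 1.5, phi = 0.4, pi = 0.0),
                   c(beta = 2.0, phi = 5, pi = 0.7))) {
    total <- sum(vapply(0:4000, function(k)
      exp(zinb_loglik(k, X, par["beta"], par["phi"], par["pi"])), 0))
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("analytic gradients agree with finite differences for all families", {
  set.seed(31)
  n <- 60
  X <- cbind(1, rbinom(n, 1, 0.5))
  y <- larvconn::rzinb(n, exp(0.4 + 0.3 * X[, 2]), phi = 1.2, pi = 0.3)
  nll <- larvconn:::count_nll
  grd <- larvconn:::count_nll_grad
  fd <- function(theta, family) {
    h <- 1e-6
    vapply(seq_along(theta), function(i) {
      e <- numeric(length(theta)); e[i] <- h
      (nll(theta + e, y, X, family) - nll(theta - e, y, X, family)) / (2 * h)
    }, 0)
  }
  cases <- list(poisson = c(0.2, 0.1),
                nb = c(0.2, 0.1, 0.3),
                zip = c(0.2, 0.1, -0.5),
                zinb = c(0.2, 0.1, 0.3, -0.5))
  for (fam in names(cases)) {
    th <- cases[[fam]]
    expect_equal(grd(th, y, X, fam), fd(th, fam), tolerance = 1e-5,
                 info = fam)
  }
})

test_that("ZINB tends to the ZIP limit as dispersion grows", {
  set.seed(41)
  n <- 50
  X <- cbind(1, rnorm(n))
  beta <- c(0.5, 0.2); pii <- 0.25
  y <- larvconn::rzinb(n, exp(drop(X %*% beta)), phi = Inf, pi = pii)
  lam <- exp(drop(X %*% beta))
  zip_ll <- sum(ifelse(y == 0, log(pii + (1 - pii) * exp(-lam)),
                       log(1 - pii) + dpois(y, lam, log = TRUE)))
  zinb_ll <- zinb_loglik(y, X, beta, phi = 1e6, pi = pii)
  expect_equal(zinb_ll / n, zip_ll / n, tolerance = 1e-4)
})

test_that("intercept-only Poisson fit recovers log(mean) analytically", {
  tab <- make_trap_table(catch_scenario(n = 400, pi = 0, phi = Inf,
                                        seed = 17))
  fit <- fit_count_model(character(0), tab, family = "poisson")
  expect_equal(unname(coef(fit)[1]), log(mean(tab$urchin_count)),
               tolerance = 1e-8)
  expect_equal(fit$df, 1)
  expect_equal(fit$aic, 2 * fit$df - 2 * fit$loglik)
})

test_that("Poisson regression recovers simulated coefficients within 3 SE", {
  sc <- catch_scenario(n = 5000, phi = Inf, pi = 0,
                       beta = c("zoneRC_D" = 0.5, "lobster_sizesmall" = -0.4),
                       predictors = c("zone", "size"), seed = 23)
  tab <- make_trap_table(sc)
  fit <- fit_count_model(c("zone", "size"), tab, family = "poisson")
  expect_true(fit$converged)
  sm <- summary(fit)
  truth <- attr(tab, "truth")$beta[rownames(sm$coef_table)]
  zdev <- abs(sm$coef_table[, "Estimate"] - truth) /
    sm$coef_table[, "Std. Error"]
  expect_true(all(zdev < 3))
})

test_that("ZINB fit recovers the generator's parameters and matches glmmTMB", {
  sc <- catch_scenario(n = 8000, phi = 1.2, pi = 0.35,
                       beta = c("zoneRC_C" = 0.6, "lobster_sizesmall" = 0.3),
                       predictors = c("zone", "size"), seed = 29)
  tab <- make_trap_table(sc)
  fit <- fit_count_model(urchin_count ~ zone + lobster_size, tab,
                         family = "zinb")
  expect_true(fit$converged)
  expect_lt(abs(fit$pi - 0.35), 0.05)
  expect_lt(abs(fit$phi - 1.2) / 1.2, 0.25)
  truth <- attr(tab, "truth")$beta[names(coef(fit))]
  expect_lt(max(abs(coef(fit) - truth)), 0.15)
  skip_if_not_installed("glmmTMB")
  ref <- glmmTMB::glmmTMB(urchin_count ~ zone + lobster_size,
                          ziformula = ~1, family = glmmTMB::nbinom2,
                          data = tab)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
  expect_equal(coef(fit), glmmTMB::fixef(ref)$cond, tolerance = 1e-3)
  expect_equal(fit$pi,
               plogis(unname(glmmTMB::fixef(ref)$zi)), tolerance = 1e-3)
  expect_equal(fit$phi, glmmTMB::sigma(ref), tolerance = 1e-3)
})

test_that("NB fit agrees with an independent glm.nb fit", {
  skip_if_not_installed("MASS")
  tab <- make_trap_table(catch_scenario(n = 4000, phi = 0.9, pi = 0,
                                        beta = c("zoneRC_D" = 0.5),
                                        predictors = "zone", seed = 53))
  fit <- fit_count_model(urchin_count ~ zone, tab, family = "nb")
  ref <- MASS::glm.nb(urchin_count ~ zone, data = tab)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(coef(fit), coef(ref), tolerance = 1e-4)
  expect_equal(fit$phi, ref$theta, tolerance = 1e-3)
})

test_that("overdispersion statistic separates equidispersed from NB data", {
  sc_p <- catch_scenario(n = 5000, phi = Inf, pi = 0, seed = 37)
  fit_p <- fit_count_model("zone", make_trap_table(sc_p), family = "poisson")
  stat_p <- overdispersion_check(fit_p)
  expect_gt(stat_p, 0.9); expect_lt(stat_p, 1.1)
  sc_nb <- catch_scenario(n = 5000, phi = 0.5, pi = 0, seed = 37)
  fit_nb <- fit_count_model("zone", make_trap_table(sc_nb),
                            family = "poisson")
  expect_gt(overdispersion_check(fit_nb), 1.5)
  # saturated toy: response identical to the fitted mean gives 0
  toy <- make_trap_table(catch_scenario(n = 50, seed = 1))
  toy$urchin_count <- rep(3L, 50)
  fit0 <- fit_count_model(character(0), toy, family = "poisson")
  expect_equal(overdispersion_check(fit0), 0, tolerance = 1e-12)
})

test_that("AIC selection ranks the generating model first and breaks ties by df", {
  sc <- catch_scenario(n = 6000, phi = 1.0, pi = 0.3,
                       beta = c("year2021" = 1.0, "zoneRC_C" = 0.7,
                                "lobster_sizesmall" = 0.4,
                                "depth_stratum50-100" = -0.5,
                                "monthMay" = 0.6),
                       seed = 43)
  tab <- make_trap_table(sc)
  lad <- abundance_ladders()
  sel <- model_selection(tab, lad$cumulative, family = "zinb")
  expect_identical(sel$model[1], "M5")
  expect_true(all(diff(sel$aic) >= 0))
  expect_true(all(sel$aic == 2 * sel$df - 2 * sel$loglik))
  # duplicate candidates: identical AIC, tie broken by df against a super-model
  sel2 <- model_selection(tab, list(a = "year", b = "year"), family = "nb")
  expect_equal(sel2$aic[1], sel2$aic[2])
  sel3 <- model_selection(tab, list(single = "zone"), family = "nb")
  expect_equal(nrow(sel3), 1)
})

test_that("fit methods behave: predict, residuals, simulate, logLik", {
  tab <- make_trap_table(catch_scenario(n = 1500, seed = 47))
  fit <- fit_count_model("zone", tab, family = "zinb")
  expect_equal(AIC(fit), fit$aic)
  expect_equal(attr(logLik(fit), "df"), fit$df)
  mu <- predict(fit, type = "response")
  expect_equal(mu, (1 - fit$pi) * predict(fit, type = "count"))
  expect_equal(mean(residuals(fit, "response")), 0, tolerance = 0.1)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_equal(dim(sims), c(1500, 2))
  expect_true(all(sims >= 0))
  newd <- tab[1:5, ]
  expect_length(predict(fit, newdata = newd, type = "response"), 5)
})
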