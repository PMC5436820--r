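test_that("hurdle_loglik matches closed forms on single observations", {
  d0 <- hurdle_design(0, 10, zero_terms = "intercept",
                      count_terms = "intercept", family = "poisson")
  # y = 0 with zero-part predictor 0: log(1 - plogis(0)) = log(0.5)
  expect_equal(hurdle_loglik(c(0, 0), 0L, d0), log(0.5))
  # y = 3, mu = 2, hurdle certainly crossed (huge intercept)
  ll <- hurdle_loglik(c(50, log(2)), 3L, d0)
  expect_equal(ll, log(dpois(3, 2) / (1 - exp(-2))), tolerance = 1e-10)
})

test_that("hurdle_loglik equals brute-force truncated-pmf enumeration", {
  # property suite: random small datasets, both families
  for (rep in 1:20) {
    set.seed(rep)
    n <- sample(5:50, 1)
    theta <- if (rep %% 2) Inf else runif(1, 0.5, 4)
    dat <- gen_hurdle_data(n, c(-0.5, 0.3, 0.02, 0.01),
                           c(0.1, 0.2, 0.01, 0.005), theta, seed = rep)
    keep <- dat$y <= 10
    y <- dat$y[keep]; ntz <- dat$ntz[keep]; pots <- dat$pots[keep]
    if (!length(y)) next
    fam <- if (is.finite(theta)) "negbin" else "poisson"
    d <- hurdle_design(ntz, pots, family = fam)
    # coefficients kept small enough that mu stays inside the oracle's
    # enumeration range (pots reaches ~80, so |pots coef| <= 0.02)
    bz <- c(rnorm(2, 0, 0.3), runif(2, -0.02, 0.02))
    bc <- c(rnorm(2, 0, 0.2), runif(2, -0.015, 0.015))
    params <- if (is.finite(theta)) c(bz, bc, log(theta)) else c(bz, bc)
    pi <- plogis(bz[1] + bz[2] * ntz + bz[3] * pots + bz[4] * ntz * pots)
    mu <- exp(bc[1] + bc[2] * ntz + bc[3] * pots + bc[4] * ntz * pots)
    expect_equal(hurdle_loglik(params, y, d),
                 oracle_hurdle_loglik(y, pi, mu, theta), tolerance = 1e-8)
  }
})

test_that("intercept-only zero part has the closed-form MLE", {
  y <- c(rep(0L, 40), rep(1L, 30), rep(2L, 30))
  d <- hurdle_design(rep(0, 100), rep(1, 100), zero_terms = "intercept",
                     count_terms = "intercept", family = "poisson")
  fit <- fit_hurdle(y, d)
  expect_equal(unname(fit$zero_coefs["intercept"]), qlogis(0.6),
               tolerance = 1e-6)
  expect_true(fit$converged)
  # separability: the combined loglik equals hurdle_loglik at the MLE
  expect_equal(fit$loglik,
               hurdle_loglik(c(fit$zero_coefs, fit$count_coefs), y, d),
               tolerance = 1e-9)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
})

test_that("degenerate responses are rejected informatively", {
  d <- hurdle_design(rep(0, 10), rep(1, 10), family = "poisson")
  expect_error(fit_hurdle(rep(0L, 10), d), "all counts are zero")
  expect_error(fit_hurdle(rep(2L, 10), d), "no zero counts")
  expect_error(fit_hurdle(c(-1, 2, 0), d), "non-negative integers")
})

test_that("ZANB recovers known coefficients within 3 standard errors", {
  bz <- c(-1.2, 0.2, 0.065, 0.02)
  bc <- c(-0.2, 0.5, 0.025, 0.012)
  dat <- gen_hurdle_data(3000, bz, bc, theta = 1.5, seed = 99)
  fit <- fit_hurdle(dat$y, hurdle_design(dat$ntz, dat$pots,
                                         family = "negbin"))
  expect_true(fit$converged)
  expect_true(all(abs(fit$zero_coefs - bz) < 3 * fit$zero_se))
  expect_true(all(abs(fit$count_coefs - bc) < 3 * fit$count_se))
  expect_lt(abs(log(fit$theta) - log(1.5)), 3 * fit$log_theta_se)
})

test_that("ZANB never has lower loglik than ZAP on the same data", {
  for (s in 1:5) {
    dat <- gen_hurdle_data(400, c(0, 0.3, 0.02, 0), c(0.2, 0.3, 0.02, 0),
                           theta = if (s %% 2) 2 else Inf, seed = 100 + s)
    dz <- hurdle_design(dat$ntz, dat$pots, family = "poisson")
    dn <- hurdle_design(dat$ntz, dat$pots, family = "negbin")
    f1 <- fit_hurdle(dat$y, dz)
    f2 <- fit_hurdle(dat$y, dn)
    # theta sits on the boundary for equidispersed data; the supremum is
    # approached, not attained, hence the small numerical slack
    expect_gte(f2$loglik, f1$loglik - 1e-3)
  }
})

test_that("Poisson truth fitted as ZANB gives a large dispersion", {
  dat <- gen_hurdle_data(2000, c(0.2, 0, 0.02, 0), c(0.3, 0, 0.02, 0),
                         theta = Inf, seed = 7)
  fit <- fit_hurdle(dat$y, hurdle_design(dat$ntz, dat$pots,
                                         family = "negbin"))
  expect_gt(fit$theta, 20)
  zap <- fit_hurdle(dat$y, hurdle_design(dat$ntz, dat$pots,
                                         family = "poisson"))
  expect_lte(zap$aic, fit$aic + 2.01)
})

test_that("likelihood-ratio test plumbing", {
  dat <- gen_hurdle_data(500, c(-0.5, 0.3, 0.02, 0), c(0, 0.3, 0.02, 0),
                         theta = Inf, seed = 3)
  full <- fit_hurdle(dat$y, hurdle_design(dat$ntz, dat$pots,
                                          family = "poisson"))
  # identical fits: chi2 = 0, p = 1
  self <- lrt(full, full)
  expect_equal(self$chi2, 0)
  expect_equal(self$p_value, 1)
  red <- fit_hurdle(dat$y, hurdle_design(
    dat$ntz, dat$pots, zero_terms = c("intercept", "ntz", "pots"),
    count_terms = c("intercept", "ntz", "pots"), family = "poisson"))
  r <- lrt(full, red)
  expect_gte(r$chi2, 0)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, pchisq(r$chi2, 2, lower.tail = FALSE))
  expect_error(lrt(red, full), "not nested")
  # chi2 -> p mapping at the chi-squared critical value
  expect_equal(lrt_pvalue(3.84, 1), 0.05, tolerance = 2e-3)
  # boundary mixture halves the plain p
  b <- lrt(full, red, boundary = TRUE)
  expect_equal(b$p_value, r$p_value / 2)
})

test_that("family selection recovers the generating family", {
  nb <- gen_hurdle_data(1500, c(0.3, 0, 0.02, 0), c(0.5, 0.3, 0.02, 0),
                        theta = 0.8, seed = 41)
  sel <- select_family(nb$y, hurdle_design(nb$ntz, nb$pots))
  expect_equal(sel$family, "negbin")
  po <- gen_hurdle_data(1500, c(0.3, 0, 0.02, 0), c(0.5, 0.3, 0.02, 0),
                        theta = Inf, seed = 42)
  sel <- select_family(po$y, hurdle_design(po$ntz, po$pots))
  expect_equal(sel$family, "poisson")
})

test_that("stepwise simplification honours marginality and alpha", {
  # truth without interactions: the MAM drops them
  dat <- gen_hurdle_data(2500, c(-0.5, 0.4, 0.03, 0), c(0, 0.4, 0.02, 0),
                         theta = Inf, seed = 55)
  fit <- fit_hurdle(dat$y, hurdle_design(dat$ntz, dat$pots,
                                         family = "poisson"))
  mam <- stepwise_simplify(fit)
  expect_false("ntz_pots" %in% mam$design$zero_terms)
  expect_false("ntz_pots" %in% mam$design$count_terms)
  expect_true(all(c("intercept", "ntz", "pots") %in%
                    mam$design$count_terms))
  # strong interactions in both parts: the full model is the MAM
  dat2 <- gen_hurdle_data(2500, c(-1.5, 0.2, 0.04, 0.08),
                          c(-0.3, 0.2, 0.02, 0.05), theta = Inf, seed = 56)
  fit2 <- fit_hurdle(dat2$y, hurdle_design(dat2$ntz, dat2$pots,
                                           family = "poisson"))
  mam2 <- stepwise_simplify(fit2)
  expect_setequal(mam2$design$zero_terms,
                  c("intercept", "ntz", "pots", "ntz_pots"))
  expect_setequal(mam2$design$count_terms,
                  c("intercept", "ntz", "pots", "ntz_pots"))
  # intercept-only truth simplifies to intercept-only in both parts
  dat3 <- gen_hurdle_data(2500, c(0.2, 0, 0, 0), c(0.4, 0, 0, 0),
                          theta = Inf, seed = 57)
  fit3 <- fit_hurdle(dat3$y, hurdle_design(dat3$ntz, dat3$pots,
                                           family = "poisson"))
  mam3 <- stepwise_simplify(fit3)
  expect_equal(mam3$design$zero_terms, "intercept")
  expect_equal(mam3$design$count_terms, "intercept")
})

test_that("predict_cpue is the unconditional hurdle mean", {
  y <- c(0L, 3L, 2L, 0L)
  fit <- fit_hurdle(y, hurdle_design(c(0, 1, 0, 1), c(10, 12, 11, 13),
                                     zero_terms = c("intercept", "ntz"),
                                     count_terms = "intercept",
                                     family = "poisson"))
  # closed form: pi = 1 gives mu / (1 - e^-mu); pi = 0 gives 0
  mu <- unname(exp(fit$count_coefs["intercept"]))
  manual_pi <- plogis(fit$zero_coefs["intercept"] + fit$zero_coefs["ntz"])
  expect_equal(predict_cpue(fit, 1, 12),
               unname(manual_pi * mu / (1 - exp(-mu))), tolerance = 1e-8)
  # Monte-Carlo check of the unconditional mean at fixed covariates
  bz <- c(0.4, 0, 0, 0); bc <- c(0.6, 0, 0, 0); theta <- 1.2
  dat <- gen_hurdle_data(3000, bz, bc, theta, seed = 77)
  fitn <- fit_hurdle(dat$y, hurdle_design(dat$ntz, dat$pots,
                                          zero_terms = "intercept",
                                          count_terms = "intercept",
                                          family = "negbin"))
  set.seed(1234)
  n_mc <- 1e5
  pos <- runif(n_mc) < plogis(bz[1])
  mu0 <- exp(bc[1])
  p0 <- pnbinom(0, size = theta, mu = mu0)
  draws <- ifelse(pos, qnbinom(runif(n_mc, p0, 1), size = theta, mu = mu0),
                  0)
  se <- sd(draws) / sqrt(n_mc)
  truth_mean <- plogis(bz[1]) * mu0 /
    (1 - (theta / (theta + mu0))^theta)
  expect_lt(abs(mean(draws) - truth_mean), 4 * se)
  expect_lt(abs(predict_cpue(fitn, 0, 20) - truth_mean), 0.1)
})

test_that("residuals are centred for a well-specified model", {
  dat <- gen_hurdle_data(2000, c(-0.5, 0.3, 0.03, 0), c(0, 0.3, 0.02, 0),
                         theta = 2, seed = 88)
  fit <- fit_hurdle(dat$y, hurdle_design(dat$ntz, dat$pots,
                                         family = "negbin"))
  rv <- residuals_vs_fitted(fit)
  expect_equal(nrow(rv), 2000)
  expect_lt(abs(mean(rv$residual)), 0.1)
  expect_lt(sd(rv$residual), 1.2)
  expect_gt(sd(rv$residual), 0.8)
  # no strong monotone trend in residuals vs fitted
  expect_lt(abs(cor(rv$fitted, rv$residual, method = "spearman")), 0.15)
  # misspecification (Poisson fit to NB data) inflates the spread
  mis <- fit_hurdle(dat$y, hurdle_design(dat$ntz, dat$pots,
                                         family = "poisson"))
  rv_mis <- residuals_vs_fitted(mis)
  expect_gt(sd(rv_mis$residual), sd(rv$residual) + 0.05)
})

test_that("design construction enforces marginality and binary NTZ", {
  expect_error(hurdle_design(c(0, 2), c(1, 1)), "binary")
  expect_error(hurdle_design(c(0, 1), c(1, 1),
                             zero_terms = c("intercept", "ntz_pots")),
               "marginality")
  expect_error(hurdle_design(c(0, 1), c(1, 1),
                             zero_terms = c("ntz", "intercept")),
               "intercept")
})
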