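mk_model_data <- function(n_id = 20, ntr = 25, u_sd = 0.1, seed = 1) {
  set.seed(seed)
  n <- n_id * ntr
  d <- data.frame(
    id = factor(rep(sprintf("p%02d", 1:n_id), each = ntr)),
    volume = factor(sample(c("none", "low", "high"), n, TRUE),
                    c("none", "low", "high")),
    age = factor(rep(rep(c("5mo", "10mo"), each = ntr), n_id / 2),
                 c("5mo", "10mo")),
    isi_s = runif(n, 0.08, 0.40))
  u <- rnorm(n_id, 0, u_sd)
  d$y <- 0.05 * (d$volume == "low") + 0.09 * (d$volume == "high") +
    u[as.integer(d$id)] + rnorm(n, 0, 0.1)
  d
}

test_that("gaussian fits without group variance reproduce OLS", {
  d <- mk_model_data(u_sd = 0)
  f <- fit_mixed(y ~ volume + isi_s + (1 | id), d)
  ols <- stats::lm(y ~ volume + isi_s, d,
                   contrasts = list(volume = "contr.sum"))
  expect_lt(f$ranef_var, 1e-8)   # boundary estimate at zero
  expect_equal(unname(f$coef), unname(stats::coef(ols)), tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("maximum-likelihood fitting recovers injected fixed effects", {
  d <- mk_model_data(seed = 2)
  f <- fit_mixed(y ~ volume + (1 | id), d)
  mc <- marginal_contrasts(f, "volume")
  hl <- mc$contrasts[mc$contrasts$contrast == "low - high", ]
  expect_lt(abs(hl$estimate - (-0.04)), 0.02)
  expect_lt(abs(sqrt(f$ranef_var) - 0.1), 0.05)
})

test_that("single-term deletion LRT has correct df and guards interactions", {
  d <- mk_model_data(seed = 3)
  f <- fit_mixed(y ~ volume + age + isi_s + (1 | id), d)
  lr <- lrt_single_term(f, "volume")
  expect_equal(lr$df, 2L)        # 3-level factor drops 2 parameters
  expect_gte(lr$chisq, 0)
  expect_lt(lr$p, 0.001)         # strong injected effect

  lr2 <- lrt_single_term(f, "isi_s")
  expect_equal(lr2$df, 1L)
  expect_gt(lr2$p, 0.001)        # isi has no injected effect here

  # LRT is invariant to the contrast coding of the dropped factor
  f_tr <- fit_mixed(y ~ volume + age + isi_s + (1 | id), d,
                    contrasts = "contr.treatment")
  lr_tr <- lrt_single_term(f_tr, "volume")
  expect_equal(lr$chisq, lr_tr$chisq, tolerance = 1e-6)

  # dropping a term inside a retained interaction raises
  f2 <- fit_mixed(y ~ volume * age + (1 | id), d)
  expect_error(lrt_single_term(f2, "volume"), "interaction")
  expect_no_error(lrt_single_term(f2, "volume:age"))

  expect_error(lrt_single_term(f, "nonexistent"), "not in the model")
})

test_that("binomial fits estimate conditional log-odds", {
  set.seed(4)
  n_id <- 30; ntr <- 40
  d <- data.frame(id = factor(rep(1:n_id, each = ntr)),
                  age = factor(rep(rep(c("5mo", "10mo"), each = ntr),
                                   n_id / 2), c("5mo", "10mo")))
  u <- rnorm(n_id, 0, 0.4)
  eta <- -0.6 + 0.94 * (d$age == "10mo") + u[as.integer(d$id)]
  d$yb <- as.integer(runif(nrow(d)) < stats::plogis(eta))
  f <- fit_mixed(yb ~ age + (1 | id), d, family = "binomial")
  mc <- marginal_contrasts(f, "age", pairs = list(c("10mo", "5mo")))
  expect_lt(abs(mc$contrasts$estimate - 0.94), 0.35)
  # no residual scale parameter in the binomial fit
  expect_equal(f$df, length(f$coef) + 1L)
})

test_that("marginal contrasts agree with the emmeans reference grid", {
  skip_if_not_installed("emmeans")
  d <- mk_model_data(seed = 5)
  f <- fit_mixed(y ~ volume + age + isi_s + (1 | id), d)
  mc <- marginal_contrasts(f, "volume", at = list(isi_s = 0.23))
  em <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(f$model, "volume", at = list(isi_s = 0.23),
                     lmer.df = "asymptotic"), "pairwise", adjust = "none"))
  expect_equal(mc$contrasts$estimate, em$estimate, tolerance = 1e-8)
  expect_equal(mc$contrasts$se, em$SE, tolerance = 1e-8)
})

test_that("contrasts at covariate values match hand-computed combinations", {
  set.seed(6)
  n_id <- 24; ntr <- 30
  d <- data.frame(id = factor(rep(1:n_id, each = ntr)),
                  age = factor(rep(rep(c("5mo", "10mo"), each = ntr),
                                   n_id / 2), c("5mo", "10mo")),
                  isi_s = runif(n_id * ntr, 0.08, 0.40))
  u <- rnorm(n_id, 0, 0.05)
  # known coefficients: age difference shrinks with ISI
  d$y <- 0.4 - 0.125 * (d$age == "10mo") + 0.1 * d$isi_s +
    0.203 * (d$age == "10mo") * (d$isi_s - 0.08) +
    u[as.integer(d$id)] + rnorm(nrow(d), 0, 0.05)
  f <- fit_mixed(y ~ age * isi_s + (1 | id), d,
                 contrasts = "contr.treatment")
  b <- f$coef
  for (isi in c(0.08, 0.23, 0.40)) {
    mc <- marginal_contrasts(f, "age", at = list(isi_s = isi),
                             pairs = list(c("10mo", "5mo")))
    hand <- b[["age10mo"]] + b[["age10mo:isi_s"]] * isi
    expect_equal(mc$contrasts$estimate, hand, tolerance = 1e-10)
  }
  # the injected interaction makes the age gap shrink with ISI
  g80 <- marginal_contrasts(f, "age", at = list(isi_s = 0.08),
                            pairs = list(c("10mo", "5mo")))$contrasts$estimate
  g400 <- marginal_contrasts(f, "age", at = list(isi_s = 0.40),
                             pairs = list(c("10mo", "5mo")))$contrasts$estimate
  expect_lt(abs(g400), abs(g80))

  # a level contrasted with itself is exactly zero with zero SE
  self <- marginal_contrasts(f, "age", pairs = list(c("5mo", "5mo")))
  expect_equal(self$contrasts$estimate, 0)
  expect_equal(self$contrasts$se, 0)

  # a model with a single binary factor: contrast equals the coefficient
  f1 <- fit_mixed(y ~ age + (1 | id), d, contrasts = "contr.treatment")
  mc1 <- marginal_contrasts(f1, "age", pairs = list(c("10mo", "5mo")))
  expect_equal(mc1$contrasts$estimate, unname(f1$coef["age10mo"]),
               tolerance = 1e-10)

  expect_error(marginal_contrasts(f1, "age", pairs = list(c("15mo", "5mo"))),
               "absent")
  expect_error(marginal_contrasts(f1, "isi_s"), "not a factor")
})

test_that("quadratic trend tests trim, centre and recover curvature", {
  set.seed(7)
  n_id <- 30; ntr <- 40
  d <- data.frame(id = factor(rep(1:n_id, each = ntr)))
  u <- rnorm(n_id, 0, 0.1)
  d$x <- rnorm(nrow(d), 4.5, 0.4)
  d$y <- 1 + 0.3 * d$x - 0.5 * (d$x - 4.5)^2 + u[as.integer(d$id)] +
    rnorm(nrow(d), 0, 0.2)
  qt <- quadratic_test(d, "y", "x")
  expect_lt(qt$p, 1e-6)
  expect_lt(abs(qt$quad_coef - (-0.5)), 0.1)

  # full-range trim equals the untrimmed analysis
  qt_full <- quadratic_test(d, "y", "x", trim = c(0, 1))
  d2 <- d; d2$.x <- d2$x - mean(d2$x)
  ref <- fit_mixed(y ~ .x + I(.x^2) + (1 | id), d2)
  expect_equal(qt_full$quad_coef, unname(ref$coef["I(.x^2)"]),
               tolerance = 1e-8)

  # trimming drops the extreme rows before both fits
  expect_equal(qt$fit_linear$nobs, sum(
    d$x >= stats::quantile(d$x, 0.01) & d$x <= stats::quantile(d$x, 0.99)))
  expect_error(quadratic_test(d, "y", "x", trim = c(0.99, 0.01)),
               "every row")
})

test_that("the critical F quantile matches its distributional identities", {
  # the repeated-measures sensitivity analysis value, to 2 decimals
  expect_equal(round(critical_f(0.05, 55, 2420), 2), 1.34)
  # F(1, inf) limit equals the 1-df chi-square critical value
  expect_equal(critical_f(0.05, 1, 1e7), stats::qchisq(0.95, 1) / 1,
               tolerance = 1e-4)
  # Monte-Carlo quantile oracle
  set.seed(8)
  draws <- stats::rf(2e5, 7, 31)
  expect_equal(critical_f(0.05, 7, 31),
               unname(stats::quantile(draws, 0.95)), tolerance = 0.03)
  expect_error(critical_f(0, 1, 1), "alpha")
  expect_error(critical_f(0.05, -1, 10), "degrees of freedom")
})
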