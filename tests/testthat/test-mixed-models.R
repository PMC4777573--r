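test_that("GLMM with null group structure matches the GLM (IRLS) oracle", {
  df <- null_group_data()
  spec <- model_spec("binomial", "y", fixed = "x", random = "g", trials = "size")
  fit <- fit_glmm(spec, df)
  oracle <- glm(cbind(y, size - y) ~ x, binomial(), df)
  expect_lt(max(abs(fit$coefficients$estimate - coef(oracle))), 1e-4)
  expect_lt(fit$ranef_sd[["g"]], 1e-3)

  specp <- model_spec("poisson", "cnt", fixed = "x", random = "g")
  fitp <- fit_glmm(specp, df)
  oraclep <- glm(cnt ~ x, poisson(), df)
  expect_lt(max(abs(fitp$coefficients$estimate - coef(oraclep))), 1e-4)
})

test_that("LMM with null group structure matches the OLS oracle", {
  df <- null_group_data()
  spec <- model_spec("gaussian", "yl", fixed = "x", random = "g")
  fit <- fit_lmm(spec, df)
  ols <- lm(yl ~ x, df)
  expect_lt(max(abs(fit$coefficients$estimate - coef(ols))), 1e-6)
  expect_true(all(is.na(fit$coefficients$p)))  # no LMM p-values by convention
})

test_that("balanced one-way LMM reproduces closed-form ANOVA components", {
  set.seed(103)
  k <- 12; m <- 8   # groups x replicates, balanced
  g <- factor(rep(seq_len(k), each = m))
  u <- rnorm(k, 0, 2)
  y <- 5 + u[as.integer(g)] + rnorm(k * m, 0, 1)
  df <- data.frame(y = y, g = g)
  fit <- fit_lmm(model_spec("gaussian", "y", fixed = "1", random = "g"), df)
  # method-of-moments: sigma2_e = MSW, sigma2_g = (MSB - MSW) / m
  aov_tab <- anova(lm(y ~ g, df))
  msb <- aov_tab$`Mean Sq`[1]; msw <- aov_tab$`Mean Sq`[2]
  expect_equal(fit$sigma^2, msw, tolerance = 1e-5)
  expect_equal(unname(fit$ranef_sd[["g"]]^2), (msb - msw) / m, tolerance = 1e-5)
})

test_that("nested random intercepts expand to outer + outer:inner", {
  spec <- model_spec("binomial", "dead", fixed = "dist",
                     random = "date/line", trials = "n")
  f <- deparse(spraytrack:::spec_formula(spec))
  expect_match(paste(f, collapse = ""), "\\(1 \\| date\\)")
  expect_match(paste(f, collapse = ""), "\\(1 \\| date:line\\)")
})

test_that("link equivariance: shifting a covariate only moves the intercept", {
  set.seed(104)
  n <- 500
  df <- data.frame(x = rnorm(n), g = factor(rep(1:10, length.out = n)))
  df$y <- 2 - 1.5 * df$x + rnorm(10, 0, 0.8)[as.integer(df$g)] + rnorm(n, 0, 0.5)
  spec <- model_spec("gaussian", "y", fixed = "x", random = "g")
  fit <- fit_lmm(spec, df)
  df2 <- transform(df, x = x + 3)
  fit2 <- fit_lmm(spec, df2)
  cf <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  cf2 <- setNames(fit2$coefficients$estimate, fit2$coefficients$term)
  expect_equal(cf2[["x"]], cf[["x"]], tolerance = 1e-6)
  expect_equal(cf2[["(Intercept)"]], cf[["(Intercept)"]] - 3 * cf[["x"]],
               tolerance = 1e-6)

  # logit link: 1e-4 (the nonlinear optimizer does not refit to 1e-6)
  df$size <- 15L
  df$yb <- rbinom(n, df$size, plogis(0.3 + 0.9 * df$x))
  specb <- model_spec("binomial", "yb", fixed = "x", random = "g", trials = "size")
  fb <- fit_glmm(specb, df)
  fb2 <- fit_glmm(specb, transform(df, x = x + 2))
  cb <- setNames(fb$coefficients$estimate, fb$coefficients$term)
  cb2 <- setNames(fb2$coefficients$estimate, fb2$coefficients$term)
  expect_equal(cb2[["x"]], cb[["x"]], tolerance = 1e-4)
  expect_equal(cb2[["(Intercept)"]], cb[["(Intercept)"]] - 2 * cb[["x"]],
               tolerance = 1e-4)
})

test_that("predict_response applies the inverse link; fixed part by default", {
  set.seed(105)
  df <- data.frame(x = rnorm(200), g = factor(rep(1:8, 25)), size = 10L)
  df$y <- rbinom(200, 10, plogis(0.5 * df$x + rnorm(8, 0, 1)[as.integer(df$g)]))
  fit <- fit_glmm(model_spec("binomial", "y", fixed = "x", random = "g",
                             trials = "size"), df)
  b <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  x0 <- -b[["(Intercept)"]] / b[["x"]]   # linear predictor exactly 0
  expect_equal(predict_response(fit, data.frame(x = x0)), c(`1` = 0.5),
               tolerance = 1e-8)
  # unknown level with random effects requested -> error
  expect_error(predict_response(fit, data.frame(x = 0, g = "new-group"),
                                include_random = TRUE))
  # with known level, prediction includes that group's intercept
  pr <- predict_response(fit, data.frame(x = 0, g = "3"), include_random = TRUE)
  pf <- predict_response(fit, data.frame(x = 0))
  expect_false(isTRUE(all.equal(pr, pf, check.names = FALSE)))
})

test_that("degenerate binomial data warns instead of crashing", {
  df <- data.frame(y = 0L, size = 10L, x = rnorm(40),
                   g = factor(rep(1:4, 10)))
  w <- capture_warnings(
    fit <- fit_glmm(model_spec("binomial", "y", fixed = "x", random = "g",
                               trials = "size"), df))
  expect_match(w, "degenerate|separation|could not be fitted", all = FALSE)
  expect_false(fit$converged)
})
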