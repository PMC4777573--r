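test_that("distance model recovers the generating slope on synthetic cages", {
  cfg <- synthetic_config(seed = 21)
  cages <- simulate_cage_experiment(cfg)
  fit <- run_glmm2(cages)
  expect_true(fit$converged)
  cf <- fit$coefficients
  slope <- cf$estimate[cf$term == "distance_m"]
  se <- cf$se[cf$term == "distance_m"]
  expect_lt(abs(slope - cfg$cage_model$beta_distance), 3 * se)  # single seed
  # permuting rows leaves the fit unchanged
  set.seed(1)
  fit2 <- run_glmm2(cages[sample(nrow(cages)), ])
  expect_equal(fit2$coefficients$estimate, cf$estimate, tolerance = 1e-6)
})

test_that("exposure model has the Table-1 structure and detects exposure", {
  cfg <- synthetic_config(seed = 22)
  cages <- simulate_cage_experiment(cfg)
  fit <- run_glmm1(cages)
  terms <- fit$coefficients$term
  expect_setequal(terms, c("(Intercept)", "sexmale", "permethrin",
                           "exposedexposed", "sexmale:permethrin",
                           "sexmale:exposedexposed"))
  expect_setequal(names(fit$ranef_sd), c("date", "date:line"))
  # exposed cages die more than controls in this world
  expect_gt(fit$coefficients$estimate[terms == "exposedexposed"], 0)
  expect_lt(fit$coefficients$p[terms == "exposedexposed"], 0.05)
})

test_that("validation quantiles match the exact binomial oracle", {
  cfg <- synthetic_config(seed = 23)
  cages <- simulate_cage_experiment(cfg)
  fit <- run_glmm2(cages)
  res <- validate_cages(fit, cages, n_sim = 10000, seed = 99)
  expect_equal(nrow(res), 7 * 2)  # 7 treatments x 2 validation cages
  # at arbitrary predicted p the exact CDF can sit on the 0.025 cut, where
  # a 10k-draw empirical bound is +/- 1; require that accuracy everywhere
  for (i in seq_len(nrow(res))) {
    ex <- exact_binom_bounds(res$n_initial[i], res$predicted_p[i])
    expect_lte(abs(res$q0.025[i] - unname(ex["lower"])), 1)
    expect_lte(abs(res$q0.975[i] - unname(ex["upper"])), 1)
  }
  expect_true(all(res$flag %in% c("under", "within", "over")))
  consistent <- (res$flag == "under") == (res$observed_dead <= res$q0.025) &
    (res$flag == "over") == (res$observed_dead >= res$q0.975)
  expect_true(all(consistent))
  expect_warning(validate_cages(fit, cages, n_sim = 500, seed = 1), "unstable")
})

test_that("rejection bounds reproduce the Binomial(20, 0.5) reference case", {
  set.seed(31)
  draws <- rbinom(50000, 20, 0.5)
  b <- spraytrack:::rejection_bounds(draws, 20)
  expect_equal(unname(b), c(5, 15))
  expect_equal(unname(exact_binom_bounds(20, 0.5)), c(5, 15))
  # exact agreement where the exact CDF is clearly separated from the cut
  cases <- list(c(10, 0.5), c(10, 0.9), c(20, 0.1), c(40, 0.1), c(40, 0.9))
  for (case in cases) {
    n <- case[1]; p <- case[2]
    d <- rbinom(10000, n, p)
    expect_equal(unname(spraytrack:::rejection_bounds(d, n)),
                 unname(exact_binom_bounds(n, p)),
                 info = sprintf("n=%d p=%.2f", n, p))
  }
})

test_that("simulation coverage: observations from the model are ~95% within", {
  # draw validation observations from the fitted model itself; the flag
  # should be "within" about 95% of the time (two-sided 5% rejection)
  cfg <- synthetic_config(seed = 24)
  cages <- simulate_cage_experiment(cfg)
  fit <- run_glmm2(cages)
  set.seed(42)
  n_rep <- 400
  p13 <- predict_response(fit, data.frame(distance_m = 13))
  within <- 0
  bounds <- exact_binom_bounds(40, p13)
  obs <- rbinom(n_rep, 40, p13)
  within <- mean(obs > bounds["lower"] & obs < bounds["upper"])
  expect_gte(within, 0.93)
  expect_lte(within, 0.995)
})

test_that("mortality surface fractions are correct and monotone", {
  cfg <- synthetic_config(seed = 25)
  fit <- run_glmm2(simulate_cage_experiment(cfg))
  cf <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  # distance at which predicted p = 0.8 -> threshold 0.75 gives fraction 1
  d80 <- (qlogis(0.8) - cf[["(Intercept)"]]) / cf[["distance_m"]]
  grid <- matrix(d80, 4, 5)
  surf <- mortality_surface(fit, grid, thresholds = c(0.5, 0.75))
  expect_equal(unname(surf$fractions), c(1, 1))
  # half near, half far
  dlo <- (qlogis(0.9) - cf[["(Intercept)"]]) / cf[["distance_m"]]
  dhi <- (qlogis(0.1) - cf[["(Intercept)"]]) / cf[["distance_m"]]
  grid2 <- matrix(c(dlo, dhi), 2, 10, byrow = TRUE)
  surf2 <- mortality_surface(fit, grid2, thresholds = 0.5)
  expect_equal(unname(surf2$fractions), 0.5)
  # monotone in threshold on a random grid, mask respected
  grid3 <- matrix(runif(100, 0, 120), 10, 10)
  mask <- matrix(rep(c(TRUE, FALSE), 50), 10, 10)
  surf3 <- mortality_surface(fit, grid3, mask, thresholds = c(0.25, 0.5, 0.75))
  expect_true(all(diff(surf3$fractions) <= 0))
  expect_error(mortality_surface(fit, grid3, mask & FALSE), "mask")
})
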