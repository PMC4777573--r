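test_that("config validation catches invalid parameterisations", {
  expect_error(synthetic_config(treatment_effect = 0), "treatment_effect")
  expect_error(synthetic_config(treatment_effect = 1.2), "treatment_effect")
  expect_error(synthetic_config(divergence_index = 99), "divergence_index")
  expect_error(synthetic_config(sd_collection = -1), "SDs")
  expect_error(synthetic_config(collection_share = 1.5), "collection_share")
  expect_error(synthetic_config(seasonal_curve = 1:5), "seasonal_curve")
})

test_that("simulation is reproducible and seed-sensitive", {
  cfg <- synthetic_config(seed = 123)
  a <- simulate_monitoring(cfg)
  b <- simulate_monitoring(cfg)
  expect_identical(a, b)
  c2 <- simulate_monitoring(synthetic_config(seed = 124))
  expect_false(identical(a$traps$n_total, c2$traps$n_total))
  ca <- simulate_cage_experiment(cfg)
  cb <- simulate_cage_experiment(cfg)
  expect_identical(ca, cb)
  # simulation does not disturb the caller's RNG stream
  set.seed(55); before <- rnorm(3)
  set.seed(55); invisible(simulate_monitoring(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("monitoring output respects the design dimensions", {
  cfg <- synthetic_config(seed = 5)
  mon <- simulate_monitoring(cfg)
  expect_s3_class(mon$traps, "trap_records")
  expect_equal(nrow(mon$traps), (24 + 19) * 36)
  expect_equal(length(unique(mon$traps$trap_id[mon$traps$site == "treated"])), 24)
  expect_equal(length(unique(mon$traps$trap_id[mon$traps$site == "untreated"])), 19)
  expect_true(all(mon$traps$n_total == mon$traps$n_female + mon$traps$n_male))
  expect_true(all(mon$traps$water_leftover >= 0 &
                    mon$traps$water_leftover <= cfg$water_model$cap))
})

test_that("identical generative law makes the two sites exchangeable", {
  cfg <- synthetic_config(treatment_effect = 1, site_effect = 0,
                          water_beta = c(untreated = -0.2, treated = -0.2),
                          collection_share = 1, seed = 6)
  mon <- simulate_monitoring(cfg)
  sm <- site_mean_series(mon$traps, "count")
  tr <- site_series_vector(sm, "treated")
  un <- site_series_vector(sm, "untreated")
  # same expected series; per-collection means differ only by sampling noise
  expect_gt(cor(tr, un), 0.9)
  expect_lt(abs(mean(tr) - mean(un)), 0.2 * mean(un) + 0.05)
})

test_that("sample means approach exp(seasonal_curve) under the pure law", {
  # no random effects, no water effect, no site effect: LLN check at 2000 traps
  curve <- seasonal_curve_default(6, peak = 3, width = 2, base = 0.5, amplitude = 1)
  cfg <- synthetic_config(n_traps_treated = 2000, n_traps_untreated = 2000,
                          n_collections = 6, seasonal_curve = curve,
                          divergence_index = 3,
                          site_effect = 0, treatment_effect = 1,
                          water_beta = c(untreated = 0, treated = 0),
                          sd_collection = 0, sd_trap = 0, seed = 7)
  mon <- simulate_monitoring(cfg)
  sm <- site_mean_series(mon$traps, "count")
  for (site in c("treated", "untreated")) {
    v <- site_series_vector(sm, site, 6)
    expect_lt(max(abs(v - exp(curve)) / exp(curve)), 0.02)
  }
})

test_that("cage experiment honours the design and its limits", {
  cfg <- synthetic_config(seed = 8)
  cages <- simulate_cage_experiment(cfg)
  expect_s3_class(cages, "cage_records")
  # 7 treatments x (12 exposed + 2 validation + 3 control) x 2 sexes
  expect_equal(nrow(cages), 7 * 17 * 2)
  expect_setequal(unique(cages$treatment_id), paste0("T", 2:8))
  expect_true(all(cages$permethrin_ug_cm2[cages$role == "control"] == 0))
  expect_true(all(cages$n_dead_24h <= cages$n_initial))
  # permethrin decays with distance on average
  exp_cages <- cages[cages$role == "exposed", ]
  m <- tapply(exp_cages$permethrin_ug_cm2, exp_cages$distance_m, mean)
  expect_gt(m[["10"]], m[["70"]])

  # beta0 -> -Inf: zero deaths everywhere
  cm <- cfg$cage_model; cm$beta0 <- -50; cm$beta0_control <- -50
  cfg0 <- synthetic_config(cage_model = cm, seed = 8)
  expect_equal(sum(simulate_cage_experiment(cfg0)$n_dead_24h), 0)
  expect_error(simulate_cage_experiment(cfg, distances = c(-5, 10)), "distances")
})

test_that("flat distance effect gives equal mortality across distances", {
  # chi-square homogeneity test non-significant at alpha = 0.01 in >= 95/100 seeds
  cm <- synthetic_config()$cage_model
  cm$beta_distance <- 0; cm$sd_date <- 0; cm$sd_line <- 0
  ok <- 0
  for (s in 1:100) {
    cfg <- synthetic_config(cage_model = cm, seed = 4000 + s)
    cages <- simulate_cage_experiment(cfg, n_treatments = 2)
    exp_c <- cages[cages$role == "exposed", ]
    dead <- tapply(exp_c$n_dead_24h, exp_c$distance_m, sum)
    tot <- tapply(exp_c$n_initial, exp_c$distance_m, sum)
    pv <- suppressWarnings(prop.test(dead, tot)$p.value)
    if (pv > 0.01) ok <- ok + 1
  }
  expect_gte(ok, 95)
})
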