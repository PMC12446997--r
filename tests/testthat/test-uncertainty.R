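params <- default_parameters()
cfg <- population_config(n = 200)

test_that("Rubin's rules match the closed form and are order invariant", {
  out <- rubins_rules(c(1, 2, 3), c(0, 0, 0))
  expect_equal(out$pooled, 2)
  expect_equal(out$total_variance, (1 + 1 / 3) * 1)
  expect_equal(rubins_rules(c(3, 1, 2), c(0, 0, 0)), out)
  same <- rubins_rules(rep(5, 4), c(0.1, 0.1, 0.1, 0.1))
  expect_equal(same$pooled, 5)
  expect_equal(same$total_variance, 0.1)
  expect_warning(one <- rubins_rules(7, 0.2), "single imputation")
  expect_equal(one$pooled, 7)
  expect_error(rubins_rules(c(1, 2), c(1)), "equal length")
})

test_that("Monte Carlo standard error follows the closed form and the 1/sqrt(B) law", {
  expect_equal(monte_carlo_se(c(0, 2)), 1)
  expect_equal(monte_carlo_se(rep(3, 10)), 0)
  expect_error(monte_carlo_se(1), "fewer than 2")
  set.seed(1)
  x <- rnorm(4000)
  expect_equal(monte_carlo_se(x) * sqrt(2), monte_carlo_se(x[1:2000]),
               tolerance = 0.1)
})

test_that("PSA draws honour their families and degenerate rows return the mean", {
  d <- draw_psa_params(params, seed = 99)
  spec <- params$psa
  expect_named(d$draws, spec$name)
  # degenerate row (discount rate) passes through
  expect_equal(d$draws[["discount_rate"]], params$sim$discount_rate)
  # gamma/beta draws respect their supports
  expect_true(d$draws[["preventive_cost"]] > 0)
  expect_true(d$draws[["oop_share_medicaid"]] > 0 && d$draws[["oop_share_medicaid"]] < 1)
  # drawn values are written back into the parameter set
  expect_equal(get_parameter(d$params, "preventive_cost"), d$draws[["preventive_cost"]])
  expect_identical(draw_psa_params(params, seed = 99)$draws, d$draws)
})

test_that("degenerate PSA without resampling reproduces the deterministic run", {
  pop <- generate_population(cfg, seed = 71)
  p <- params
  p$psa$sd <- rep(0, nrow(p$psa))
  reps <- run_psa(pop, p, n_boot = 1, seed = 5, config = cfg, resample = FALSE)
  run_seed <- dceacvd:::derive_seed(5, 1, 1, stage = 3L)
  rn <- run_arm(pop, params, "nonexpansion", run_seed, config = cfg)
  re <- run_arm(pop, params, "expansion", run_seed, config = cfg)
  w <- pop$weight
  expect_equal(reps$delta_cost, weighted.mean(re$cost - rn$cost, w), tolerance = 1e-12)
  expect_equal(reps$delta_qalys, weighted.mean(re$qalys - rn$qalys, w), tolerance = 1e-12)
})

test_that("CEAC: dominance, single-replication step at the ICER, large-lambda limit", {
  dominant <- tibble::tibble(delta_cost = c(-10, -5), delta_qalys = c(0.1, 0.2))
  curve <- ceac(dominant, c(0, 1e4, 1e5, 1e6))
  expect_true(all(curve$p_cost_effective == 1))

  one <- tibble::tibble(delta_cost = 5000, delta_qalys = 0.05) # ICER 100,000
  grid <- c(50000, 99999, 100001, 2e5)
  cv <- ceac(one, grid)
  expect_equal(cv$p_cost_effective, c(0, 0, 1, 1))

  set.seed(3)
  mixed <- tibble::tibble(delta_cost = rnorm(400, 0, 500),
                          delta_qalys = rnorm(400, 0.001, 0.01))
  expect_equal(ceac(mixed, 1e12)$p_cost_effective, mean(mixed$delta_qalys > 0))
  # nondecreasing in lambda when every replication is dominant (saves costs
  # and gains health)
  saver <- tibble::tibble(delta_cost = -abs(rnorm(200, 100, 50)),
                          delta_qalys = abs(rnorm(200, 0.001, 0.01)))
  cs <- ceac(saver, seq(1e3, 1e6, length.out = 30))
  expect_true(all(diff(cs$p_cost_effective) >= 0))
})

test_that("DCEA-PSA quadrant probabilities sum to one and match enumeration", {
  reps <- tibble::tibble(
    inhb = c(0.01, 0.02, -0.01, -0.02, 0.03),
    iedeh_income_group = c(0.02, 0.01, 0.00, -0.03, 0.05)
  )
  q <- dcea_psa(reps, partitions = "income_group")
  expect_equal(sum(q$probability), 1)
  expect_equal(q$probability[q$quadrant == "efficient, equity enhancing"], 2 / 5)
  expect_equal(q$probability[q$quadrant == "efficient, equity reducing"], 1 / 5)
  expect_equal(q$probability[q$quadrant == "not cost-effective, equity enhancing"], 1 / 5)
  expect_equal(q$probability[q$quadrant == "not cost-effective, equity reducing"], 1 / 5)

  degenerate <- tibble::tibble(inhb = rep(0.01, 3), iedeh_income_group = rep(0.02, 3))
  qd <- dcea_psa(degenerate, partitions = "income_group")
  expect_equal(qd$probability[qd$quadrant == "efficient, equity enhancing"], 1)
  expect_error(dcea_psa(degenerate, partitions = "education"), "iedeh_education")
})

test_that("PSA replications are reproducible and carry IEDEH per partition", {
  pop <- generate_population(cfg, seed = 72)
  a <- run_psa(pop, params, n_boot = 2, seed = 10, config = cfg)
  b <- run_psa(pop, params, n_boot = 2, seed = 10, config = cfg)
  expect_equal(a, b)
  expect_equal(nrow(a), 2)
  expect_true(all(c("iedeh_income_group", "iedeh_education",
                    "iedeh_race_ethnicity") %in% names(a)))
  expect_error(run_psa(pop, params, n_boot = 0, seed = 1, config = cfg), "n_boot")
})

test_that("tornado sweep: exclusions, zero-influence parameters, linear symmetry", {
  pop <- generate_population(population_config(n = 250), seed = 73)
  p0 <- null_intervention(params)
  expect_message(t0 <- dsa_tornado(pop, p0, seed = 2, config = cfg),
                 "delta_sbp")
  # parameters with no channel of influence under the null leave a zero range
  # (trajectories identical across arms, base values zero or arm-symmetric)
  zero_inf <- c("preventive_cost", "admin_cost_per_enrollee",
                "avg_annual_earnings", "productivity_event_cost",
                "discount_rate", "cost_intercept", "utility_intercept",
                "event_markup")
  z <- t0[t0$parameter %in% zero_inf, ]
  expect_equal(z$range, rep(0, nrow(z)), tolerance = 1e-12)
  expect_false(any(c("delta_sbp", "delta_hba1c") %in% t0$parameter))
  expect_true("discount_rate" %in% t0$parameter)

  tor <- suppressMessages(dsa_tornado(pop, params, seed = 2, config = cfg))
  expect_true(all(diff(abs(tor$range)) <= 1e-12))
  base <- attr(tor, "base_inhb")
  # the administration cost enters the INHB linearly: symmetric range
  row <- tor[tor$parameter == "admin_cost_per_enrollee", ]
  expect_equal(row$inhb_high - base, base - row$inhb_low,
               tolerance = 1e-8 * max(abs(base), 1e-6))
})
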