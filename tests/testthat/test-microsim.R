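params <- default_parameters()
cfg <- population_config(n = 300)

test_that("intervention shifts risk factors once, floors at bounds, reflags diabetes", {
  ind <- fixture_individual(medicaid_eligible = TRUE, insured = FALSE,
                            income_group = "poor", sbp = 130, hba1c = 6.6)
  ind$diabetes <- TRUE
  out <- apply_intervention(ind, params)
  expect_equal(out$sbp, 126.97)
  expect_equal(out$hba1c, 6.46)
  expect_false(out$diabetes) # crossed the 6.5 threshold
  expect_equal(out[, setdiff(names(out), c("sbp", "hba1c", "diabetes"))],
               ind[, setdiff(names(ind), c("sbp", "hba1c", "diabetes"))])

  p0 <- params
  p0$intervention$delta_sbp <- 0
  p0$intervention$delta_hba1c <- 0
  expect_equal(apply_intervention(ind, p0), ind)

  low <- fixture_individual(medicaid_eligible = TRUE, insured = FALSE,
                            income_group = "poor", sbp = 80)
  expect_equal(apply_intervention(low, params)$sbp, 80) # floored

  expect_error(apply_intervention(fixture_individual(), params), "not eligible")
})

test_that("forced degenerate probabilities give the expected trajectories", {
  # no events, no mortality: survive to 85
  p <- constant_prob_params(p_event_total = 0, fatal_frac = 0.3, p_noncvd = 0)
  ind <- fixture_individual(age = 60)
  tr <- simulate_individual(ind, p, "nonexpansion", seed = 1)
  expect_equal(nrow(tr), 85 - 60)
  expect_true(all(tr$state == "no_cvd"))
  expect_equal(tr$age, 60:84)

  # certain immediate non-CVD death: single cycle
  p1 <- constant_prob_params(p_event_total = 0, p_noncvd = 1 - 1e-16)
  tr1 <- simulate_individual(ind, p1, "nonexpansion", seed = 1)
  expect_equal(nrow(tr1), 1)
  expect_equal(tr1$state, "noncvd_death")
  expect_equal(tr1$alive_fraction_for_hcc, 0.5)
})

test_that("simulated state sequences match an independent hand trace", {
  p <- constant_prob_params(p_event_total = 0.25, fatal_frac = 0.3, p_noncvd = 0.05)
  pop <- rbind(fixture_individual(age = 60),
               fixture_individual(id = 2L, age = 58, sex = "female",
                                  cvd_history = TRUE),
               fixture_individual(id = 3L, age = 62, smoker = FALSE))
  res <- run_arm(pop, p, "nonexpansion", seed = 31, config = cfg,
                 keep_trajectories = TRUE)
  got <- attr(res, "trajectories")
  got <- got[order(got$individual_id, got$cycle), ]
  want <- trace_arm(pop, p, seed = 31)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$state, want$state)
  expect_equal(got$cycle, want$cycle)
  expect_equal(got$event, want$event)
  expect_equal(got$fatal, want$fatal)
})

test_that("state sequences match the hand trace under the full fixture equations", {
  pop <- random_individuals(25, seed = 13)
  res <- run_arm(pop, params, "nonexpansion", seed = 17, config = cfg,
                 keep_trajectories = TRUE)
  got <- attr(res, "trajectories")
  got <- got[order(got$individual_id, got$cycle), ]
  want <- trace_arm(pop, params, seed = 17)
  expect_equal(got$state, want$state)
  expect_equal(got$fatal, want$fatal)
})

test_that("common random numbers: null intervention gives exactly equal arms", {
  pop <- generate_population(cfg, seed = 21)
  p0 <- null_intervention(params)
  rn <- run_arm(pop, p0, "nonexpansion", seed = 4, config = cfg)
  re <- run_arm(pop, p0, "expansion", seed = 4, config = cfg)
  re$arm <- rn$arm
  attr(re, "arm") <- attr(rn, "arm")
  expect_identical(as.data.frame(re), as.data.frame(rn))
})

test_that("run_arm is reproducible and honours the empty sample", {
  pop <- generate_population(cfg, seed = 22)
  a <- run_arm(pop, params, "expansion", seed = 9, config = cfg)
  b <- run_arm(pop, params, "expansion", seed = 9, config = cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  e <- run_arm(pop[0, ], params, "expansion", seed = 9, config = cfg)
  expect_equal(nrow(e), 0)
})

test_that("trajectory and accounting invariants hold on a generated sample", {
  pop <- generate_population(cfg, seed = 23)
  res <- run_arm(pop, params, "expansion", seed = 2, config = cfg,
                 keep_trajectories = TRUE)
  tr <- attr(res, "trajectories")
  # ages increase by one per cycle; nothing recorded after death
  by_id <- split(tr, tr$individual_id)
  for (t in by_id) {
    expect_equal(t$age, t$age[1] + t$cycle - t$cycle[1])
    expect_lte(sum(t$fatal), 1)
    if (any(t$fatal)) expect_true(which(t$fatal) == nrow(t))
  }
  # QALY bound: at most one QALY per year lived
  expect_true(all(res$qalys >= 0 & res$qalys <= 85 - res$entry_age))
  # payer split consistency
  expect_equal(res$hc_total, res$hc_oop + res$hc_nonoop, tolerance = 1e-12)
  # transfer neutrality: attributed costs sum to real resources
  expect_equal(sum(res$weight * res$attributed_cost),
               sum(res$weight * (res$hc_total + res$admin)),
               tolerance = 1e-9 * sum(res$weight * res$hc_total))
  # levy only falls on income groups above 150% FPL
  expect_true(all(res$levy[!res$income_group %in% cfg$income_above_150] == 0))
})

test_that("stronger blood-pressure effects weakly reduce expansion-arm MI incidence", {
  pop <- generate_population(population_config(n = 2000), seed = 30)
  seeds <- 13:17 # mean incidence over a fixed replication set
  mi_at <- function(delta) {
    p <- params
    p$intervention$delta_sbp <- delta
    mean(sapply(seeds, function(s) {
      incidence_rates(run_arm(pop, p, "expansion", seed = s,
                              config = cfg))[["mi"]]
    }))
  }
  r0 <- mi_at(0)
  r3 <- mi_at(-3.03)
  r9 <- mi_at(-9)
  expect_lte(r3, r0)
  expect_lte(r9, r3)
})

test_that("incidence rates are weighted events per 100,000 person-years", {
  res <- tibble::tibble(weight = c(2, 3), person_years = c(20000, 20000),
                        n_mi_nonfatal = c(1, 0), n_stroke_nonfatal = c(0, 0),
                        cvd_death = c(FALSE, TRUE))
  r <- incidence_rates(res)
  expect_equal(r[["mi"]], 2 / 100000 * 1e5)
  expect_equal(r[["stroke"]], 0)
  expect_equal(r[["cvd_death"]], 3 / 100000 * 1e5)
  res2 <- res
  res2$weight <- res$weight * 2 # scale invariance
  expect_equal(incidence_rates(res2), r)
  expect_error(incidence_rates(res[0, ]), "person-years")
})

test_that("medicare switch at 65 ends new cost differences but risk effects persist", {
  pop <- generate_population(population_config(n = 400), seed = 31)
  pop$age <- pmin(pop$age, 60)
  p <- params
  rn <- run_arm(pop, p, "nonexpansion", seed = 3, config = cfg)
  re <- run_arm(pop, p, "expansion", seed = 3, config = cfg)
  # recipients keep reduced sbp after 65: some event histories differ there
  expect_true(any(re$qalys != rn$qalys))
  # admin accrues only while enrolled (< 65): bounded by enrolled person-time
  el <- re$medicaid_eligible
  max_admin_years <- 65 - re$entry_age[el]
  expect_true(all(re$admin[el] <=
                    params$econ$admin_cost_per_enrollee *
                    params$econ$admin_cvd_share * max_admin_years + 1e-9))
  expect_true(all(re$admin[!el] == 0))
})
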