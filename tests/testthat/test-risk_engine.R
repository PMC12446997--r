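params <- default_parameters()

test_that("rate-to-probability conversion matches the closed form", {
  expect_equal(rate_to_probability(0), 0)
  expect_equal(rate_to_probability(0.01), 1 - exp(-0.01), tolerance = 1e-12)
  expect_equal(rate_to_probability(0.01), 0.00995017, tolerance = 1e-6)
  r <- c(0.001, 0.05, 0.5, 2)
  expect_true(all(rate_to_probability(r) < r))
  expect_error(rate_to_probability(-0.1), "nonnegative")
})

test_that("null linear predictor reduces the base risk to 1 - s0", {
  p <- constant_prob_params(p_event_total = 0.01)
  ind <- fixture_individual()
  risks <- base_cvd_risk(ind, p)
  total_rate <- risks$mi + risks$stroke
  # shares sum to 0.85 of the composite rate
  expect_equal(unname(total_rate / sum(p$event_split)), -log(1 - 0.01),
               tolerance = 1e-12)
})

test_that("base risk matches a hand evaluation of the fixture equation", {
  ind <- fixture_individual() # age 55 male, sbp 140 untreated, tc 213, hdl 50, smoker
  risks <- base_cvd_risk(ind, params)
  oracle_total <- naive_framingham_rate(ind, params)
  expect_equal(risks$mi, params$event_split[["mi"]] * oracle_total, tolerance = 1e-12)
  expect_equal(risks$stroke, params$event_split[["stroke"]] * oracle_total, tolerance = 1e-12)
})

test_that("risk is monotone in blood pressure, age, smoking and diabetes", {
  base <- fixture_individual()
  tot <- function(ind) {
    r <- annual_transition(ind, params)
    r$p_mi + r$p_stroke
  }
  expect_gt(tot(fixture_individual(sbp = 160)), tot(fixture_individual(sbp = 120)))
  expect_gt(tot(fixture_individual(age = 60)), tot(fixture_individual(age = 45)))
  expect_gt(tot(base), tot(fixture_individual(smoker = FALSE)))
  expect_gt(tot(fixture_individual(diabetes = TRUE)), tot(base))
})

test_that("relative-risk weighting is the identity at the reference profile", {
  ref <- params$ascvd_reference
  ind <- fixture_individual(sbp = ref$sbp, total_chol = ref$total_chol,
                            hdl_chol = ref$hdl_chol, smoker = ref$smoker,
                            diabetes = ref$diabetes,
                            on_htn_treatment = ref$on_htn_treatment,
                            race_ethnicity = "White")
  expect_equal(ascvd_weight(ind, params), 1, tolerance = 1e-12)
  risks <- base_cvd_risk(ind, params)
  expect_equal(apply_ascvd_weighting(risks, ind, params), risks, tolerance = 1e-12)
})

test_that("weighting ratio equals the hand-computed hazard ratio", {
  ind <- fixture_individual(race_ethnicity = "Black", diabetes = TRUE)
  ref <- params$ascvd_reference
  oracle <- naive_ascvd_hazard(ind$sbp, ind$on_htn_treatment, ind$total_chol,
                               ind$hdl_chol, ind$smoker, ind$diabetes,
                               ind$sex, "black", ind$age, params) /
    naive_ascvd_hazard(ref$sbp, ref$on_htn_treatment, ref$total_chol,
                       ref$hdl_chol, ref$smoker, ref$diabetes, ind$sex,
                       "other", ind$age, params)
  expect_equal(ascvd_weight(ind, params), oracle, tolerance = 1e-12)
  # positive diabetes coefficient: diabetic risk strictly higher
  nd <- fixture_individual(diabetes = FALSE)
  d <- fixture_individual(diabetes = TRUE)
  expect_gt(ascvd_weight(d, params), ascvd_weight(nd, params))
})

test_that("history of CVD doubles event risk and preserves zero", {
  r <- list(mi = 0.01, stroke = 0.005)
  expect_equal(history_multiplier(r, TRUE), list(mi = 0.02, stroke = 0.01))
  expect_equal(history_multiplier(r, FALSE), r)
  expect_equal(history_multiplier(list(mi = 0, stroke = 0), TRUE),
               list(mi = 0, stroke = 0))
})

test_that("fatal fraction is the fixture logistic, rising with age", {
  expect_equal(fatal_fraction(60, "female", "stroke", params),
               plogis(-5.0 + 0.05 * 60), tolerance = 1e-12)
  expect_equal(fatal_fraction(60, "female", "stroke", params), 0.1192029,
               tolerance = 1e-6)
  expect_gt(fatal_fraction(80, "male", "mi", params),
            fatal_fraction(40, "male", "mi", params))
  p <- constant_prob_params(fatal_frac = 0.3)
  expect_equal(fatal_fraction(25, "male", "mi", p), 0.3, tolerance = 1e-12)
  expect_equal(fatal_fraction(80, "female", "stroke", p), 0.3, tolerance = 1e-12)
  expect_error(fatal_fraction(90, "male", "mi", params), "range")
})

test_that("non-CVD death probability subtracts cause-specific rates", {
  tab <- data.frame(age = c(50, 50), sex = c("male", "female"),
                    rate_all_cause = c(0.01, 0.002),
                    rate_mi = c(0.001, 0.001), rate_stroke = c(0.001, 0.001))
  expect_equal(noncvd_death_prob(50, "male", tab), 1 - exp(-0.008), tolerance = 1e-12)
  expect_equal(noncvd_death_prob(50, "male", tab), 0.007968, tolerance = 2e-5)
  expect_equal(noncvd_death_prob(50, "female", tab), 0)
  expect_error(noncvd_death_prob(30, "male", tab), "not covered")
  tab$rate_all_cause[1] <- 0.0015
  expect_error(noncvd_death_prob(50, "male", tab), "negative residual")
})

test_that("engine transitions match the naive oracle on 100 random individuals", {
  pop <- random_individuals(100, seed = 77)
  tr <- annual_transition(pop, params)
  for (i in seq_len(100)) {
    o <- naive_transition(pop[i, ], params)
    expect_equal(tr$p_mi[i], o$p_mi, tolerance = 1e-10)
    expect_equal(tr$p_stroke[i], o$p_stroke, tolerance = 1e-10)
    expect_equal(tr$p_fatal_given_mi[i], o$p_fatal_given_mi, tolerance = 1e-10)
    expect_equal(tr$p_fatal_given_stroke[i], o$p_fatal_given_stroke, tolerance = 1e-10)
    expect_equal(tr$p_noncvd_death[i], o$p_noncvd_death, tolerance = 1e-10)
  }
  expect_true(all(tr$p_mi >= 0 & tr$p_mi <= 1))
  expect_true(all(tr$p_mi + tr$p_stroke <= 1))
})

test_that("probability cap binds with a warning on extreme risks", {
  p <- constant_prob_params(p_event_total = 0.999999)
  p$sim$prob_cap <- 0.9
  ind <- fixture_individual()
  expect_warning(tr <- annual_transition(ind, p), "capped")
  expect_equal(tr$p_mi + tr$p_stroke, 0.9, tolerance = 1e-9)
})

test_that("missing coefficient strata are reported", {
  p <- params
  p$framingham <- p$framingham[p$framingham$sex == "male", ]
  expect_error(base_cvd_risk(fixture_individual(sex = "female"), p), "female")
})
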