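# Independent naive re-evaluations of the model equations, written directly
# against the coefficient tables (term-by-term scalar arithmetic). These are
# the oracles the vectorized engine is checked against.

naive_framingham_rate <- function(p, params) {
  tab <- params$framingham
  cf <- function(term) tab$value[tab$sex == p$sex & tab$term == term]
  lp <- cf("log_age") * log(p$age) +
    cf("log_total_chol") * log(p$total_chol) +
    cf("log_hdl_chol") * log(p$hdl_chol) +
    (if (p$on_htn_treatment) cf("log_sbp_treated") else cf("log_sbp_untreated")) * log(p$sbp) +
    cf("smoker") * as.numeric(p$smoker) +
    cf("diabetes") * as.numeric(p$diabetes)
  -log(cf("s0_annual")) * exp(lp - cf("lp_mean"))
}

naive_ascvd_hazard <- function(sbp, trt, tc, hdl, smoker, diabetes, sex, grp,
                               age, params) {
  tab <- params$ascvd
  cf <- function(term) tab$value[tab$sex == sex & tab$race_group == grp & tab$term == term]
  lp <- cf("log_age") * log(age) +
    cf("log_total_chol") * log(tc) +
    cf("log_hdl_chol") * log(hdl) +
    (if (trt) cf("log_sbp_treated") else cf("log_sbp_untreated")) * log(sbp) +
    cf("smoker") * as.numeric(smoker) +
    cf("diabetes") * as.numeric(diabetes)
  (-log(cf("s0_10yr")) / 10) * exp(lp - cf("lp_mean"))
}

naive_transition <- function(p, params, age = p$age, cvd_history = p$cvd_history) {
  p_aged <- p
  p_aged$age <- age
  total <- naive_framingham_rate(p_aged, params)
  grp <- if (p$race_ethnicity == "Black") "black" else "other"
  ref <- params$ascvd_reference
  w <- naive_ascvd_hazard(p$sbp, p$on_htn_treatment, p$total_chol, p$hdl_chol,
                          p$smoker, p$diabetes, p$sex, grp, age, params) /
    naive_ascvd_hazard(ref$sbp, ref$on_htn_treatment, ref$total_chol,
                       ref$hdl_chol, ref$smoker, ref$diabetes, p$sex,
                       ref$race_group, age, params)
  mult <- if (cvd_history) 2 else 1
  rate_mi <- params$event_split[["mi"]] * total * w * mult
  rate_st <- params$event_split[["stroke"]] * total * w * mult
  ft <- params$fatal
  fat <- function(ev) {
    r <- ft[ft$event == ev & ft$sex == p$sex, ]
    1 / (1 + exp(-(r$intercept + r$slope_age * age)))
  }
  mt <- params$mortality
  row <- mt[mt$age == age & mt$sex == p$sex, ]
  list(p_mi = 1 - exp(-rate_mi), p_stroke = 1 - exp(-rate_st),
       p_fatal_given_mi = fat("mi"), p_fatal_given_stroke = fat("stroke"),
       p_noncvd_death = 1 - exp(-(row$rate_all_cause - row$rate_mi - row$rate_stroke)))
}

naive_cost_utility <- function(p, params, age = p$age,
                               cvd_history = p$cvd_history,
                               event_mi = FALSE, event_stroke = FALSE) {
  cu <- params$cost_utility
  one <- function(outcome) {
    cf <- function(term) cu$value[cu$outcome == outcome & cu$term == term]
    cf("intercept") + cf("age") * age +
      cf("female") * (p$sex == "female") +
      cf("cvd_history") * as.numeric(cvd_history) +
      cf("diabetes") * as.numeric(p$diabetes) +
      cf("smoker") * as.numeric(p$smoker) +
      cf("bmi") * p$bmi +
      cf(paste0("income_", p$income_group)) +
      cf(paste0("edu_", p$education)) +
      cf(paste0("race_", p$race_ethnicity)) +
      cf("event_mi") * as.numeric(event_mi) +
      cf("event_stroke") * as.numeric(event_stroke)
  }
  cost <- max(one("cost"), 0)
  if (event_mi || event_stroke) cost <- cost * params$econ$event_markup
  list(cost = cost, utility = min(max(one("utility"), 0), 1))
}

# A fixed deterministic individual used in several hand-evaluated checks.
fixture_individual <- function(...) {
  p <- tibble::tibble(
    id = 1L, age = 55, sex = "male", race_ethnicity = "White",
    income_group = "medium", education = "ged_hs", insured = TRUE,
    medicaid_eligible = FALSE, sbp = 140, total_chol = 213, hdl_chol = 50,
    hba1c = 5.5, diabetes = FALSE, smoker = TRUE, bmi = 28,
    on_htn_treatment = FALSE, cvd_history = FALSE, weight = 1
  )
  dots <- list(...)
  p[names(dots)] <- dots
  p
}

# Parameter set with constant, hand-specified transition probabilities:
# zero risk-equation coefficients so the composite annual event rate is
# -log(s0) for everyone, flat fatal fractions, flat mortality.
constant_prob_params <- function(p_event_total = 0.10, fatal_frac = 0.3,
                                 p_noncvd = 0.02) {
  params <- default_parameters()
  z <- params$framingham
  z$value[!z$term %in% c("s0_annual")] <- 0
  z$value[z$term == "s0_annual"] <- exp(-(-log(1 - p_event_total)))
  params$framingham <- z
  a <- params$ascvd
  a$value[!a$term %in% c("s0_10yr")] <- 0
  a$value[a$term == "s0_10yr"] <- 0.9
  params$ascvd <- a
  params$fatal$intercept <- log(fatal_frac / (1 - fatal_frac))
  params$fatal$slope_age <- 0
  m <- params$mortality
  m$rate_all_cause <- -log(1 - p_noncvd)
  m$rate_mi <- 0
  m$rate_stroke <- 0
  params$mortality <- m
  params
}

# Independent scalar trace of one individual's state sequence using the
# documented draw layout of run_arm (non-CVD death first, then a single
# categorical event draw, then fatality).
trace_arm <- function(pop, params, seed, end_age = 84) {
  n <- nrow(pop)
  cyc_cap <- end_age + 1 - pop$age
  maxc <- max(cyc_cap)
  set.seed(seed)
  u <- array(runif(n * maxc * 3), dim = c(n, maxc, 3))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pop[i, ]
    hist <- p$cvd_history
    rows <- list()
    for (cyc in 0:(cyc_cap[i] - 1)) {
      age <- p$age + cyc
      tr <- naive_transition(p, params, age = age, cvd_history = hist)
      if (u[i, cyc + 1, 1] < tr$p_noncvd_death) {
        rows[[length(rows) + 1]] <- data.frame(cycle = cyc, age = age,
                                               state = "noncvd_death",
                                               event = "none", fatal = TRUE)
        break
      }
      uev <- u[i, cyc + 1, 2]
      if (uev < tr$p_mi) {
        fatal <- u[i, cyc + 1, 3] < tr$p_fatal_given_mi
        rows[[length(rows) + 1]] <- data.frame(cycle = cyc, age = age,
                                               state = if (fatal) "cvd_death" else "mi_event",
                                               event = "mi", fatal = fatal)
        if (fatal) break
        hist <- TRUE
      } else if (uev < tr$p_mi + tr$p_stroke) {
        fatal <- u[i, cyc + 1, 3] < tr$p_fatal_given_stroke
        rows[[length(rows) + 1]] <- data.frame(cycle = cyc, age = age,
                                               state = if (fatal) "cvd_death" else "stroke_event",
                                               event = "stroke", fatal = fatal)
        if (fatal) break
        hist <- TRUE
      } else {
        rows[[length(rows) + 1]] <- data.frame(cycle = cyc, age = age,
                                               state = if (hist) "history_cvd" else "no_cvd",
                                               event = "none", fatal = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    df$individual_id <- p$id
    out[[i]] <- df
  }
  do.call(rbind, out)
}

random_individuals <- function(n, seed) {
  cfg <- population_config(n = n)
  generate_population(cfg, seed = seed)
}
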