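#' Apply the one-time Medicaid intervention effects
#'
#' Reduces systolic blood pressure and HbA1c by the configured one-time
#' effects (applied at entry, before the first transition draw), floors both
#' at their physiologic lower bounds, and re-derives the diabetes flag from
#' the HbA1c threshold. Only Medicaid-eligible individuals may receive the
#' intervention.
#'
#' @param ind data frame of individuals, all with `medicaid_eligible = TRUE`.
#' @param params a `cvd_params` list (effects in `params$intervention`).
#' @return the modified individuals.
#' @export
apply_intervention <- function(ind, params) {
  if (!all(ind$medicaid_eligible)) {
    stop("apply_intervention called on individual(s) not eligible for Medicaid")
  }
  iv <- params$intervention
  ind$sbp <- pmax(ind$sbp + iv$delta_sbp, params$bounds$sbp[1])
  ind$hba1c <- pmax(ind$hba1c + iv$delta_hba1c, params$bounds$hba1c[1])
  ind$diabetes <- ind$hba1c >= iv$hba1c_diabetes_threshold
  ind
}

horizon_limits <- function(horizon, max_age, medicare_age) {
  switch(horizon,
         lifetime = list(end_age = max_age - 1, max_cycles = Inf),
         "10yr" = list(end_age = max_age - 1, max_cycles = 10),
         to65 = list(end_age = medicare_age - 1, max_cycles = Inf),
         stop("unknown horizon: ", horizon))
}

#' Simulate one arm of the model
#'
#' Runs the annual-cycle Monte Carlo Markov chain for every individual in
#' the sample. Each cycle, conditional on not dying of non-CVD causes first,
#' a single categorical draw selects MI, stroke or no event; event fatality
#' is a further Bernoulli draw on the age-sex fatal-to-total fraction.
#' Survivors of an event carry a history of CVD (doubled risk) from the next
#' cycle. Costs, utilities and person-years accrue with half-cycle weights
#' (0.5 in the entry and death cycles) and 3% discounting; the expansion
#' arm's cost redistribution (reduced recipient OOP, utilization increase
#' plus administration levied on >150% FPL income groups) is applied while
#' recipients are under 65, after which everyone is on Medicare in both arms.
#'
#' Random-number discipline: `set.seed(seed)` then a single
#' `array(runif(n * max_cycles * 3), dim = c(n, max_cycles, 3))` whose slices
#' are, in order, the non-CVD death, event-category and fatality uniforms.
#' The seed and layout do not depend on the arm: with identical samples and
#' seeds the two arms share every draw (common random numbers), so a null
#' intervention yields exactly zero incrementals.
#'
#' @param sample population tibble (see [generate_population()]).
#' @param params a `cvd_params` list.
#' @param arm `"expansion"` or `"nonexpansion"`.
#' @param seed integer seed for the draw array.
#' @param config a [population_config()] (income-band flags for the levy).
#' @param keep_trajectories record per-cycle states (slow; for small n).
#' @return tibble of class `arm_result`, one row per person: subgroup
#'   columns, discounted cost components (`hc_total`, `hc_oop`, `hc_nonoop`,
#'   `admin`, `levy`, `productivity`), `attributed_cost`, `cost`
#'   (= attributed + productivity; the per-person DCEA cost), `qalys`,
#'   nonfatal event counts, death flags and `person_years`. If
#'   `keep_trajectories`, the long per-cycle table is in
#'   `attr(result, "trajectories")`.
#' @export
run_arm <- function(sample, params, arm = c("nonexpansion", "expansion"),
                    seed = 1, config = population_config(),
                    keep_trajectories = FALSE) {
  arm <- match.arg(arm)
  n <- nrow(sample)
  if (n == 0) return(empty_arm_result(arm))
  pop <- sample
  recipients <- pop$medicaid_eligible & arm == "expansion"
  if (any(recipients)) {
    pop[recipients, ] <- apply_intervention(pop[recipients, ], params)
  }

  sim <- params$sim
  e <- params$econ
  r <- sim$discount_rate
  lim <- horizon_limits(sim$horizon, sim$max_age, sim$medicare_age)
  cyc_cap <- pmin(lim$end_age + 1 - pop$age, lim$max_cycles)
  maxc <- max(cyc_cap)
  if (maxc <= 0) return(empty_arm_result(arm))

  set.seed(seed)
  u <- array(stats::runif(n * maxc * 3), dim = c(n, maxc, 3))

  # --- per-person constants -------------------------------------------------
  fra <- params$framingham
  b_age <- coef_lookup(fra, "log_age", pop$sex)
  lp_const <- framingham_lp_const(pop, fra)
  h0 <- -log(coef_lookup(fra, "s0_annual", pop$sex))
  share_mi <- params$event_split[["mi"]]
  share_str <- params$event_split[["stroke"]]

  asc <- params$ascvd
  ref <- params$ascvd_reference
  rg <- ascvd_race_group(pop$race_ethnicity)
  asc_const <- function(sbp, trt, tc, hdl, smk, dia, sex, grp) {
    trt <- rep_len(trt, max(length(sex), length(grp)))
    ascvd_lookup(asc, "log_total_chol", sex, grp) * log(tc) +
      ascvd_lookup(asc, "log_hdl_chol", sex, grp) * log(hdl) +
      ifelse(trt, ascvd_lookup(asc, "log_sbp_treated", sex, grp),
             ascvd_lookup(asc, "log_sbp_untreated", sex, grp)) * log(sbp) +
      ascvd_lookup(asc, "smoker", sex, grp) * smk +
      ascvd_lookup(asc, "diabetes", sex, grp) * dia -
      ascvd_lookup(asc, "lp_mean", sex, grp) +
      log(-log(ascvd_lookup(asc, "s0_10yr", sex, grp)) / 10)
  }
  asc_dage <- ascvd_lookup(asc, "log_age", pop$sex, rg) -
    ascvd_lookup(asc, "log_age", pop$sex, ref$race_group)
  asc_dconst <- asc_const(pop$sbp, pop$on_htn_treatment, pop$total_chol,
                          pop$hdl_chol, pop$smoker, pop$diabetes, pop$sex, rg) -
    asc_const(ref$sbp, ref$on_htn_treatment, ref$total_chol, ref$hdl_chol,
              ref$smoker, ref$diabetes, pop$sex, ref$race_group)

  fat <- params$fatal
  fkey <- paste(fat$event, fat$sex)
  fa <- stats::setNames(fat$intercept, fkey)
  fb <- stats::setNames(fat$slope_age, fkey)
  a_mi <- unname(fa[paste("mi", pop$sex)]); b_mi <- unname(fb[paste("mi", pop$sex)])
  a_st <- unname(fa[paste("stroke", pop$sex)]); b_st <- unname(fb[paste("stroke", pop$sex)])

  mort <- params$mortality
  resid <- mort$rate_all_cause - mort$rate_mi - mort$rate_stroke
  if (any(resid < 0)) stop("mortality table has negative residual (non-CVD) rates")
  pnd_tab <- stats::setNames(1 - exp(-resid), paste(mort$age, mort$sex))

  cost_const <- cu_lp_const(pop, params, "cost")
  util_const <- cu_lp_const(pop, params, "utility")
  c_age <- cu_coef(params, "cost", "age")
  c_hist <- cu_coef(params, "cost", "cvd_history")
  c_emi <- cu_coef(params, "cost", "event_mi")
  c_est <- cu_coef(params, "cost", "event_stroke")
  u_age <- cu_coef(params, "utility", "age")
  u_hist <- cu_coef(params, "utility", "cvd_history")
  u_emi <- cu_coef(params, "utility", "event_mi")
  u_est <- cu_coef(params, "utility", "event_stroke")

  high <- pop$income_group %in% config$income_above_150
  admin_c <- e$admin_cost_per_enrollee * e$admin_cvd_share
  wt <- pop$weight
  v <- 1 / (1 + r)

  # --- state and accumulators ----------------------------------------------
  alive <- rep(TRUE, n)
  hist <- pop$cvd_history
  acc <- list(qalys = numeric(n), hc_total = numeric(n), hc_oop = numeric(n),
              admin = numeric(n), levy = numeric(n), productivity = numeric(n),
              attributed = numeric(n), py = numeric(n))
  n_mi_nf <- integer(n); n_st_nf <- integer(n)
  n_mi_all <- integer(n); n_st_all <- integer(n)
  cvd_death <- rep(FALSE, n); noncvd_death <- rep(FALSE, n)
  death_age <- rep(NA_real_, n)
  any_capped <- FALSE
  traj <- if (keep_trajectories) vector("list", maxc) else NULL

  for (cyc in 0:(maxc - 1)) {
    age <- pop$age + cyc
    active <- alive & (cyc < cyc_cap)
    if (!any(active)) break
    la <- log(age)

    rate_tot <- h0 * exp(lp_const + b_age * la)
    w_asc <- exp(asc_dconst + asc_dage * la)
    mult_hist <- 1 + hist
    p_mi <- 1 - exp(-share_mi * rate_tot * w_asc * mult_hist)
    p_st <- 1 - exp(-share_str * rate_tot * w_asc * mult_hist)
    tot <- p_mi + p_st
    over <- active & tot > sim$prob_cap
    if (any(over)) {
      sc <- sim$prob_cap / tot
      p_mi[over] <- (p_mi * sc)[over]
      p_st[over] <- (p_st * sc)[over]
      any_capped <- TRUE
    }
    p_nd <- unname(pnd_tab[paste(age, pop$sex)])

    d_nc <- active & u[, cyc + 1, 1] < p_nd
    atrisk <- active & !d_nc
    uev <- u[, cyc + 1, 2]
    e_mi <- atrisk & uev < p_mi
    e_st <- atrisk & !e_mi & uev < (p_mi + p_st)
    pf_mi <- stats::plogis(a_mi + b_mi * age)
    pf_st <- stats::plogis(a_st + b_st * age)
    ufa <- u[, cyc + 1, 3]
    fatal <- (e_mi & ufa < pf_mi) | (e_st & ufa < pf_st)
    death <- d_nc | fatal

    hcw <- rep(if (cyc == 0) 0.5 else 1, n)
    hcw[death] <- 0.5
    disc <- v^cyc
    f <- active * hcw * disc

    base0 <- pmax(cost_const + c_age * age + c_hist * hist +
                    c_emi * e_mi + c_est * e_st, 0)
    mk <- ifelse(e_mi | e_st, e$event_markup, 1)
    base_cost <- base0 * mk
    util <- pmin(pmax(util_const + u_age * age + u_hist * hist +
                        u_emi * e_mi + u_est * e_st, 0), 1)

    insured_now <- pop$insured | age >= sim$medicare_age
    oop_share <- ifelse(insured_now, e$oop_share_insured, e$oop_share_uninsured)
    total <- base_cost
    oop <- oop_share * base_cost
    attributed <- base_cost
    levy_amt <- numeric(n)
    admin_amt <- numeric(n)

    med <- recipients & active & age < sim$medicare_age
    if (any(med)) {
      nt <- base_cost[med] * e$expansion_cost_multiplier + e$preventive_cost
      no <- e$oop_share_medicaid * nt
      bo <- oop[med]
      total[med] <- nt
      oop[med] <- no
      admin_amt[med] <- admin_c
      # grouped so a null intervention (no == bo) leaves cost bit-identical
      attributed[med] <- base_cost[med] + (no - bo)
      extra <- sum(wt[med] * hcw[med] * ((nt - base_cost[med]) + admin_c + (bo - no)))
      if (extra > 0) {
        hi <- high & active
        denom <- sum(wt[hi] * hcw[hi])
        if (denom <= 0) stop("no individuals above 150% FPL to bear the redistribution levy")
        levy_amt[hi] <- extra / denom
        attributed[hi] <- attributed[hi] + extra / denom
      }
    }

    prod_ev <- e$productivity_event_cost * (e_mi | e_st)
    le <- numeric(n)
    dd <- death & age < e$retirement_age
    if (any(dd)) le[dd] <- lost_earnings(age[dd], cyc, e, r)

    acc$qalys <- acc$qalys + util * f
    acc$hc_total <- acc$hc_total + total * f
    acc$hc_oop <- acc$hc_oop + oop * f
    acc$admin <- acc$admin + admin_amt * f
    acc$levy <- acc$levy + levy_amt * f
    acc$attributed <- acc$attributed + attributed * f
    acc$productivity <- acc$productivity + prod_ev * f + le
    acc$py <- acc$py + hcw * active

    n_mi_nf <- n_mi_nf + (e_mi & !fatal)
    n_st_nf <- n_st_nf + (e_st & !fatal)
    n_mi_all <- n_mi_all + e_mi
    n_st_all <- n_st_all + e_st
    cvd_death <- cvd_death | fatal
    noncvd_death <- noncvd_death | d_nc
    death_age[death] <- age[death]

    if (keep_trajectories) {
      idx <- which(active)
      state <- ifelse(d_nc[idx], "noncvd_death",
               ifelse(fatal[idx], "cvd_death",
               ifelse(e_mi[idx], "mi_event",
               ifelse(e_st[idx], "stroke_event",
               ifelse(hist[idx], "history_cvd", "no_cvd")))))
      traj[[cyc + 1]] <- tibble::tibble(
        individual_id = pop$id[idx], arm = arm, cycle = cyc, age = age[idx],
        state = state,
        event = ifelse(e_mi[idx], "mi", ifelse(e_st[idx], "stroke", "none")),
        fatal = death[idx], alive_fraction_for_hcc = hcw[idx]
      )
    }

    hist <- hist | ((e_mi | e_st) & !death)
    alive <- alive & !death
  }

  out <- tibble::tibble(
    id = pop$id, weight = wt, arm = arm, entry_age = sample$age,
    sex = pop$sex, race_ethnicity = pop$race_ethnicity,
    income_group = pop$income_group, education = pop$education,
    insured = sample$insured, medicaid_eligible = pop$medicaid_eligible,
    cvd_history = sample$cvd_history,
    qalys = acc$qalys, hc_total = acc$hc_total, hc_oop = acc$hc_oop,
    hc_nonoop = acc$hc_total - acc$hc_oop, admin = acc$admin,
    levy = acc$levy, productivity = acc$productivity,
    attributed_cost = acc$attributed,
    cost = acc$attributed + acc$productivity,
    n_mi_nonfatal = n_mi_nf, n_stroke_nonfatal = n_st_nf,
    n_mi = n_mi_all, n_stroke = n_st_all,
    cvd_death = cvd_death, noncvd_death = noncvd_death,
    death_age = death_age, person_years = acc$py
  )
  class(out) <- c("arm_result", class(out))
  attr(out, "arm") <- arm
  attr(out, "seed") <- seed
  attr(out, "capped") <- any_capped
  if (keep_trajectories) attr(out, "trajectories") <- dplyr::bind_rows(traj)
  out
}

empty_arm_result <- function(arm) {
  out <- tibble::tibble(
    id = integer(), weight = double(), arm = character(), entry_age = double(),
    sex = character(), race_ethnicity = character(), income_group = character(),
    education = character(), insured = logical(), medicaid_eligible = logical(),
    cvd_history = logical(), qalys = double(), hc_total = double(),
    hc_oop = double(), hc_nonoop = double(), admin = double(), levy = double(),
    productivity = double(), attributed_cost = double(), cost = double(),
    n_mi_nonfatal = integer(), n_stroke_nonfatal = integer(), n_mi = integer(),
    n_stroke = integer(), cvd_death = logical(), noncvd_death = logical(),
    death_age = double(), person_years = double()
  )
  class(out) <- c("arm_result", class(out))
  attr(out, "arm") <- arm
  out
}

#' Simulate a single individual, recording the trajectory
#'
#' @param ind one-row data frame with the population schema.
#' @param params a `cvd_params` list.
#' @param arm `"expansion"` or `"nonexpansion"`.
#' @param seed integer seed.
#' @param config a [population_config()].
#' @return tibble of per-cycle records (`cycle`, `age`, `state`, `event`,
#'   `fatal`, `alive_fraction_for_hcc`).
#' @export
simulate_individual <- function(ind, params, arm = "nonexpansion", seed = 1,
                                config = population_config()) {
  res <- run_arm(ind, params, arm, seed, config, keep_trajectories = TRUE)
  attr(res, "trajectories")
}

#' Incidence rates per 100,000 person-years
#'
#' Weighted nonfatal MI and stroke events (deaths excluded from the event
#' numerators) and CVD deaths, divided by weighted person-years (half a year
#' accrues in entry and death cycles).
#'
#' @param results an `arm_result`.
#' @return named numeric vector: `mi`, `stroke`, `cvd_death` per 100,000
#'   person-years.
#' @export
incidence_rates <- function(results) {
  py <- sum(results$weight * results$person_years)
  if (py <= 0) stop("undefined incidence rate: zero person-years")
  c(mi = sum(results$weight * results$n_mi_nonfatal) / py * 1e5,
    stroke = sum(results$weight * results$n_stroke_nonfatal) / py * 1e5,
    cvd_death = sum(results$weight * results$cvd_death) / py * 1e5)
}
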