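cu_coef <- function(params, outcome, term) {
  cu <- params$cost_utility
  v <- cu$value[cu$outcome == outcome & cu$term == term]
  if (!length(v)) stop("cost/utility model missing coefficient '", term, "' for ", outcome)
  v
}

# person-level constant part of the cost/utility linear predictors
# (everything except age, current CVD history and event-cycle terms)
cu_lp_const <- function(ind, params, outcome) {
  cu <- params$cost_utility
  v <- cu$value[cu$outcome == outcome]
  names(v) <- cu$term[cu$outcome == outcome]
  need <- c("intercept", "female", "diabetes", "smoker", "bmi",
            paste0("income_", unique(ind$income_group)),
            paste0("edu_", unique(ind$education)),
            paste0("race_", unique(ind$race_ethnicity)))
  miss <- setdiff(need, names(v))
  if (length(miss)) {
    stop("cost/utility model missing coefficient(s) for ", outcome, ": ",
         paste(miss, collapse = ", "))
  }
  v[["intercept"]] +
    v[["female"]] * (ind$sex == "female") +
    v[["diabetes"]] * ind$diabetes +
    v[["smoker"]] * ind$smoker +
    v[["bmi"]] * ind$bmi +
    unname(v[paste0("income_", ind$income_group)]) +
    unname(v[paste0("edu_", ind$education)]) +
    unname(v[paste0("race_", ind$race_ethnicity)])
}

#' Annual health-care cost and utility for one cycle
#'
#' Evaluates the linear cost and utility prediction models on an
#' individual's characteristics, current age and CVD-history state. In a
#' cycle with an MI or stroke the health-care cost is multiplied by the
#' event-year markup (default 1.33) and the event utility decrement applies.
#' Utility is clipped to `[0, 1]`; cost is floored at 0. One cycle's utility
#' is that cycle's QALY contribution (before half-cycle weighting).
#'
#' @param ind data frame of individuals (vectorized).
#' @param params a `cvd_params` list.
#' @param age current age (defaults to `ind$age`).
#' @param cvd_history current history state (defaults to `ind$cvd_history`).
#' @param event_mi,event_stroke logical vectors flagging an event this cycle.
#' @return list with numeric vectors `cost` (2021 USD, marked up in event
#'   cycles) and `utility` (SF-6D scale).
#' @export
annual_cost_utility <- function(ind, params, age = ind$age,
                                cvd_history = ind$cvd_history,
                                event_mi = FALSE, event_stroke = FALSE) {
  n <- nrow(ind)
  event_mi <- rep_len(event_mi, n)
  event_stroke <- rep_len(event_stroke, n)
  cost <- cu_lp_const(ind, params, "cost") +
    cu_coef(params, "cost", "age") * age +
    cu_coef(params, "cost", "cvd_history") * cvd_history +
    cu_coef(params, "cost", "event_mi") * event_mi +
    cu_coef(params, "cost", "event_stroke") * event_stroke
  cost <- pmax(cost, 0)
  cost <- cost * ifelse(event_mi | event_stroke, params$econ$event_markup, 1)
  util <- cu_lp_const(ind, params, "utility") +
    cu_coef(params, "utility", "age") * age +
    cu_coef(params, "utility", "cvd_history") * cvd_history +
    cu_coef(params, "utility", "event_mi") * event_mi +
    cu_coef(params, "utility", "event_stroke") * event_stroke
  list(cost = cost, utility = pmin(pmax(util, 0), 1))
}

#' Productivity costs along a trajectory
#'
#' Event cycles (MI or stroke, fatal or not) incur the absenteeism /
#' short-term disability cost. A death (any cause) before the retirement age
#' incurs the average annual earnings for every year from the death year
#' through age `retirement_age - 1`, discounted to entry.
#'
#' @param trajectory tibble with columns `cycle`, `age`, `event`
#'   (`"none"/"mi"/"stroke"`), `fatal`, and optionally `state`.
#' @param params a `cvd_params` list.
#' @param r discount rate (defaults to the configured rate).
#' @return total discounted productivity cost (USD) for the trajectory.
#' @export
productivity_costs <- function(trajectory, params, r = params$sim$discount_rate) {
  if (r < 0) stop("discount rate must be nonnegative")
  e <- params$econ
  disc <- (1 + r)^(-trajectory$cycle)
  hcw <- if ("alive_fraction_for_hcc" %in% names(trajectory)) {
    trajectory$alive_fraction_for_hcc
  } else {
    rep(1, nrow(trajectory))
  }
  ev <- trajectory$event %in% c("mi", "stroke")
  total <- sum(e$productivity_event_cost * ev * hcw * disc)
  dead <- trajectory$fatal
  if ("state" %in% names(trajectory)) dead <- dead | trajectory$state == "noncvd_death"
  died <- which(dead)
  if (length(died)) {
    d <- died[1]
    total <- total + lost_earnings(trajectory$age[d], trajectory$cycle[d], e, r)
  }
  total
}

# discounted lost earnings from death at (age, cycle) to retirement;
# the death year counts in full (vectorized over death_age/death_cycle)
lost_earnings <- function(death_age, death_cycle, econ, r) {
  yrs <- pmax(econ$retirement_age - death_age, 0)
  v <- 1 / (1 + r)
  s <- if (r == 0) yrs else (1 - v^yrs) / (1 - v)
  econ$avg_annual_earnings * v^death_cycle * s
}

#' Expansion cost redistribution for one cross-section
#'
#' For Medicaid recipients the out-of-pocket share drops to the Medicaid
#' share while total health-care cost is scaled by the utilization
#' multiplier plus the preventive-care cost, and program administration is
#' added. The financed increase — the rise in total cost plus administration
#' plus the OOP reduction (i.e. the non-OOP increase) — is levied equally
#' per weighted person across individuals in income groups above 150% FPL.
#' A pure transfer: the weighted sum of attributed costs equals the weighted
#' real resource total.
#'
#' @param df tibble with columns `weight`, `income_group`,
#'   `medicaid_eligible`, `insured`, `base_cost` (pre-expansion annual total
#'   health-care cost).
#' @param params a `cvd_params` list.
#' @param arm `"expansion"` or `"nonexpansion"`.
#' @param config a [population_config()] (income band flags).
#' @return tibble with per-person columns `hc_total`, `hc_oop`, `hc_nonoop`,
#'   `admin`, `redistribution_levy`, `attributed` (USD, one cycle).
#' @export
expansion_cost_effects <- function(df, params, arm = "expansion",
                                   config = population_config()) {
  e <- params$econ
  oop_share <- ifelse(df$insured, e$oop_share_insured, e$oop_share_uninsured)
  base_oop <- oop_share * df$base_cost
  out <- tibble::tibble(
    hc_total = df$base_cost, hc_oop = base_oop,
    hc_nonoop = df$base_cost - base_oop,
    admin = 0, redistribution_levy = 0, attributed = df$base_cost
  )
  if (arm != "expansion") return(out)
  rec <- df$medicaid_eligible
  high <- df$income_group %in% config$income_above_150
  new_total <- df$base_cost[rec] * e$expansion_cost_multiplier + e$preventive_cost
  new_oop <- e$oop_share_medicaid * new_total
  admin <- e$admin_cost_per_enrollee * e$admin_cvd_share
  extra <- sum(df$weight[rec] * ((new_total - df$base_cost[rec]) + admin +
                                   (base_oop[rec] - new_oop)))
  out$hc_total[rec] <- new_total
  out$hc_oop[rec] <- new_oop
  out$hc_nonoop[rec] <- new_total - new_oop
  out$admin[rec] <- admin
  out$attributed[rec] <- df$base_cost[rec] + (new_oop - base_oop[rec])
  if (extra > 0) {
    if (!any(high)) stop("no individuals above 150% FPL to bear the redistribution levy")
    levy <- extra / sum(df$weight[high])
    out$redistribution_levy[high] <- levy
    out$attributed[high] <- out$attributed[high] + levy
  }
  out
}

#' Discount and accumulate per-cycle amounts with half-cycle weights
#'
#' @param amounts per-cycle values (costs or utilities).
#' @param cycles integer cycle indices (0-based).
#' @param hcc_weights half-cycle weights in `{0.5, 1}` (0.5 in entry and
#'   death cycles).
#' @param r discount rate (>= 0).
#' @return `sum(amounts * hcc_weights * (1 + r)^(-cycles))`.
#' @export
discount_and_accumulate <- function(amounts, cycles, hcc_weights = rep(1, length(amounts)),
                                    r = 0.03) {
  if (r < 0) stop("discount rate must be nonnegative")
  sum(amounts * hcc_weights * (1 + r)^(-cycles))
}
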