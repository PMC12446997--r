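#' Convert an event rate to an annual probability
#'
#' @param rate nonnegative event rate (events per person-year).
#' @return `1 - exp(-rate)`, in `[0, 1)`.
#' @export
rate_to_probability <- function(rate) {
  if (any(rate < 0)) stop("rate must be nonnegative")
  1 - exp(-rate)
}

coef_lookup <- function(tab, term, sex) {
  # vectorized over sex
  m <- tab$value[tab$term == term]
  names(m) <- tab$sex[tab$term == term]
  unname(m[sex])
}

ascvd_lookup <- function(tab, term, sex, race_group) {
  key <- paste(tab$sex, tab$race_group, tab$term)
  v <- tab$value
  names(v) <- key
  unname(v[paste(sex, race_group, term)])
}

ascvd_race_group <- function(race_ethnicity) {
  ifelse(race_ethnicity == "Black", "black", "other")
}

# linear predictor for the Framingham-style composite CVD equation,
# split into an age part (recomputed each cycle) and a constant part
framingham_lp_const <- function(ind, tab) {
  lsbp <- log(ind$sbp)
  coef_lookup(tab, "log_total_chol", ind$sex) * log(ind$total_chol) +
    coef_lookup(tab, "log_hdl_chol", ind$sex) * log(ind$hdl_chol) +
    ifelse(ind$on_htn_treatment,
           coef_lookup(tab, "log_sbp_treated", ind$sex),
           coef_lookup(tab, "log_sbp_untreated", ind$sex)) * lsbp +
    coef_lookup(tab, "smoker", ind$sex) * ind$smoker +
    coef_lookup(tab, "diabetes", ind$sex) * ind$diabetes -
    coef_lookup(tab, "lp_mean", ind$sex)
}

#' Base annual MI and stroke rates from the composite CVD risk equation
#'
#' Evaluates the proportional-hazards form
#' `rate = -log(s0_annual) * exp(lp - lp_mean)` on the packaged (or supplied)
#' per-sex coefficient table, then splits the composite rate into MI and
#' stroke via the configured event-type shares.
#'
#' @param ind data frame of individuals (vectorized).
#' @param params a `cvd_params` list.
#' @param age optional age override (defaults to `ind$age`); used by the
#'   simulator as individuals age.
#' @return list with numeric vectors `mi` and `stroke` (annual event rates).
#' @export
base_cvd_risk <- function(ind, params, age = ind$age) {
  tab <- params$framingham
  if (!all(unique(ind$sex) %in% tab$sex)) {
    stop("coefficient table missing stratum for sex: ",
         paste(setdiff(unique(ind$sex), tab$sex), collapse = ", "))
  }
  lp <- framingham_lp_const(ind, tab) +
    coef_lookup(tab, "log_age", ind$sex) * log(age)
  h0 <- -log(coef_lookup(tab, "s0_annual", ind$sex))
  total <- h0 * exp(lp)
  list(mi = params$event_split[["mi"]] * total,
       stroke = params$event_split[["stroke"]] * total)
}

ascvd_lp <- function(sbp, on_htn_treatment, total_chol, hdl_chol, smoker,
                     diabetes, sex, race_group, age, tab) {
  # the condition must match the lookup length (sex/race may be vectorized
  # while the reference profile supplies scalars)
  trt <- rep_len(on_htn_treatment, max(length(sex), length(race_group)))
  ascvd_lookup(tab, "log_age", sex, race_group) * log(age) +
    ascvd_lookup(tab, "log_total_chol", sex, race_group) * log(total_chol) +
    ascvd_lookup(tab, "log_hdl_chol", sex, race_group) * log(hdl_chol) +
    ifelse(trt,
           ascvd_lookup(tab, "log_sbp_treated", sex, race_group),
           ascvd_lookup(tab, "log_sbp_untreated", sex, race_group)) * log(sbp) +
    ascvd_lookup(tab, "smoker", sex, race_group) * smoker +
    ascvd_lookup(tab, "diabetes", sex, race_group) * diabetes -
    ascvd_lookup(tab, "lp_mean", sex, race_group)
}

#' Relative-risk weighting factor from the pooled-cohort-style equations
#'
#' Ratio of the individual's hazard under the sex-by-race weighting table to
#' the hazard of an age-sex-matched reference profile (config risk-factor
#' values, "other" race group), including the stratum baseline hazards:
#' `ratio = H0_stratum * exp(lp_ind) / (H0_other * exp(lp_ref))`. An
#' individual identical to the reference profile has ratio 1.
#'
#' @inheritParams base_cvd_risk
#' @return numeric vector of multiplicative weights (> 0).
#' @export
ascvd_weight <- function(ind, params, age = ind$age) {
  tab <- params$ascvd
  ref <- params$ascvd_reference
  rg <- ascvd_race_group(ind$race_ethnicity)
  lp_i <- ascvd_lp(ind$sbp, ind$on_htn_treatment, ind$total_chol,
                   ind$hdl_chol, ind$smoker, ind$diabetes, ind$sex, rg, age, tab)
  lp_r <- ascvd_lp(ref$sbp, ref$on_htn_treatment, ref$total_chol,
                   ref$hdl_chol, ref$smoker, ref$diabetes, ind$sex,
                   ref$race_group, age, tab)
  h0_i <- -log(ascvd_lookup(tab, "s0_10yr", ind$sex, rg)) / 10
  h0_r <- -log(ascvd_lookup(tab, "s0_10yr", ind$sex, ref$race_group)) / 10
  ratio <- h0_i * exp(lp_i) / (h0_r * exp(lp_r))
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("relative-risk weighting produced a nonpositive or nonfinite ratio")
  }
  ratio
}

#' Apply relative-risk weighting to base MI/stroke rates
#'
#' @param risks list with `mi` and `stroke` rate vectors.
#' @inheritParams base_cvd_risk
#' @return weighted risks (same structure).
#' @export
apply_ascvd_weighting <- function(risks, ind, params, age = ind$age) {
  w <- ascvd_weight(ind, params, age)
  list(mi = risks$mi * w, stroke = risks$stroke * w)
}

#' Double event risk for individuals with a history of CVD
#'
#' @param risks list with `mi` and `stroke` rate vectors.
#' @param cvd_history logical vector.
#' @return risks multiplied by 2 where `cvd_history` is `TRUE`.
#' @export
history_multiplier <- function(risks, cvd_history) {
  m <- ifelse(cvd_history, 2, 1)
  list(mi = risks$mi * m, stroke = risks$stroke * m)
}

#' Fatal-to-total event fraction
#'
#' Age- and sex-specific logistic: `plogis(intercept + slope_age * age)` from
#' the packaged fixture table; nondecreasing in age for positive slopes.
#'
#' @param age age in years (vectorized), within `[19, 85]`.
#' @param sex "male"/"female" (vectorized).
#' @param event "mi" or "stroke".
#' @param params a `cvd_params` list.
#' @return probability that an event of this type is fatal.
#' @export
fatal_fraction <- function(age, sex, event, params) {
  if (any(age < 19 | age > 85)) stop("age outside the supported range [19, 85]")
  tab <- params$fatal
  key <- paste(tab$event, tab$sex)
  a <- tab$intercept
  b <- tab$slope_age
  names(a) <- names(b) <- key
  k <- paste(event, sex)
  stats::plogis(unname(a[k]) + unname(b[k]) * age)
}

#' Annual probability of non-CVD death
#'
#' Subtracts the MI and stroke underlying-cause death rates from the
#' all-cause rate at (age, sex) and converts the residual rate to an annual
#' probability.
#'
#' @param age age in years (vectorized).
#' @param sex "male"/"female" (vectorized).
#' @param table mortality table (`age`, `sex`, `rate_all_cause`, `rate_mi`,
#'   `rate_stroke`).
#' @return probability vector.
#' @export
noncvd_death_prob <- function(age, sex, table) {
  key <- paste(table$age, table$sex)
  resid <- table$rate_all_cause - table$rate_mi - table$rate_stroke
  if (any(resid < 0)) stop("mortality table has negative residual (non-CVD) rates")
  names(resid) <- key
  r <- unname(resid[paste(age, sex)])
  if (any(is.na(r))) stop("age/sex not covered by the mortality table")
  rate_to_probability(r)
}

#' Assemble the full annual transition-probability set
#'
#' Applies, in order: base composite-equation rates, relative-risk weighting,
#' the x2 history-of-CVD multiplier, conversion of rates to probabilities,
#' and a cap keeping `p_mi + p_stroke` at or below `params$sim$prob_cap`
#' (proportional rescaling; flagged via the `capped` attribute).
#'
#' @inheritParams base_cvd_risk
#' @param cvd_history logical vector (current, not baseline, history state).
#' @return tibble with columns `p_mi`, `p_stroke`, `p_fatal_given_mi`,
#'   `p_fatal_given_stroke`, `p_noncvd_death`.
#' @export
annual_transition <- function(ind, params, age = ind$age,
                              cvd_history = ind$cvd_history) {
  risks <- base_cvd_risk(ind, params, age)
  risks <- apply_ascvd_weighting(risks, ind, params, age)
  risks <- history_multiplier(risks, cvd_history)
  p_mi <- rate_to_probability(risks$mi)
  p_stroke <- rate_to_probability(risks$stroke)
  tot <- p_mi + p_stroke
  capped <- tot > params$sim$prob_cap
  if (any(capped)) {
    sc <- params$sim$prob_cap / tot
    p_mi[capped] <- (p_mi * sc)[capped]
    p_stroke[capped] <- (p_stroke * sc)[capped]
    warning("p_mi + p_stroke capped at ", params$sim$prob_cap, " for ",
            sum(capped), " individual(s)")
  }
  out <- tibble::tibble(
    p_mi = p_mi, p_stroke = p_stroke,
    p_fatal_given_mi = fatal_fraction(age, ind$sex, "mi", params),
    p_fatal_given_stroke = fatal_fraction(age, ind$sex, "stroke", params),
    p_noncvd_death = noncvd_death_prob(age, ind$sex, params$mortality)
  )
  attr(out, "capped") <- any(capped)
  out
}
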