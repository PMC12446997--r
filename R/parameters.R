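#' Model parameter set
#'
#' Assembles every model input into a single list: cardiovascular risk
#' equation coefficient tables, fatal-to-total event fractions, non-CVD
#' mortality rates, the cost/utility prediction model, economic parameters
#' (out-of-pocket shares, Medicaid utilization multiplier, preventive,
#' administration and productivity costs), the one-time intervention effects
#' on systolic blood pressure and HbA1c, simulation settings (discount rate,
#' willingness-to-pay, inequality aversion, horizon) and probabilistic
#' sensitivity analysis distributions.
#'
#' Coefficient values for the risk and cost/utility equations are synthetic
#' fixture tables packaged under `inst/extdata` (the source publications do
#' not print them); every table is overridable either by editing the CSVs
#' and passing their paths, or by modifying the returned list.
#'
#' @param framingham,ascvd,fatal,mortality,cost_utility optional paths to CSV
#'   tables replacing the packaged fixtures. Column layouts must match the
#'   packaged files.
#' @return A list of class `cvd_params`. Key elements:
#' \describe{
#'   \item{framingham}{per-sex proportional-hazards coefficients with annual
#'     baseline survival `s0_annual` and centering constant `lp_mean`.}
#'   \item{ascvd}{per sex x race-group coefficients used for relative-risk
#'     weighting, with 10-year baseline survival `s0_10yr`.}
#'   \item{fatal}{logistic intercept/age-slope per (event, sex) giving the
#'     fatal-to-total fraction.}
#'   \item{mortality}{age-sex all-cause, MI and stroke death rates
#'     (per person-year).}
#'   \item{cost_utility}{linear-model coefficients for annual health-care
#'     cost (2021 USD) and SF-6D utility.}
#'   \item{econ}{economic scalars; see vignette for units and defaults.}
#'   \item{intervention}{`delta_sbp` (mm Hg), `delta_hba1c` (percentage
#'     points), their 95% CIs, and the HbA1c diabetes threshold.}
#'   \item{sim}{discount rate, WTP, epsilon, ages, horizon, probability cap.}
#'   \item{psa}{tibble of PSA distributions (name, dist, mean, sd).}
#' }
#' @export
default_parameters <- function(framingham = NULL, ascvd = NULL, fatal = NULL,
                               mortality = NULL, cost_utility = NULL) {
  pth <- function(p, f) if (is.null(p)) system.file("extdata", f, package = "dceacvd") else p
  fra <- utils::read.csv(pth(framingham, "framingham_synthetic.csv"), stringsAsFactors = FALSE)
  asc <- utils::read.csv(pth(ascvd, "ascvd_synthetic.csv"), stringsAsFactors = FALSE)
  fat <- utils::read.csv(pth(fatal, "fatal_fraction_synthetic.csv"), stringsAsFactors = FALSE)
  mort <- utils::read.csv(pth(mortality, "mortality_synthetic.csv"), stringsAsFactors = FALSE)
  cu <- utils::read.csv(pth(cost_utility, "cost_utility_synthetic.csv"), stringsAsFactors = FALSE)
  validate_mortality_table(mort)

  params <- list(
    framingham = fra,
    ascvd = asc,
    fatal = fat,
    mortality = mort,
    cost_utility = cu,
    # Share of the composite CVD event rate attributed to each event type.
    event_split = c(mi = 0.50, stroke = 0.35),
    # Reference profile for relative-risk weighting: age-sex matched,
    # stratum "other", with these risk-factor values.
    ascvd_reference = list(
      sbp = 125, on_htn_treatment = FALSE, total_chol = 190, hdl_chol = 50,
      smoker = FALSE, diabetes = FALSE, race_group = "other"
    ),
    econ = list(
      oop_share_uninsured = 0.40,
      oop_share_insured = 0.12,
      oop_share_medicaid = 0.05,
      expansion_cost_multiplier = 2.13,
      preventive_cost = 320,
      admin_cost_per_enrollee = 555,
      admin_cvd_share = 0.096,
      avg_annual_earnings = 58260,
      productivity_event_cost = 7043,
      event_markup = 1.33,
      retirement_age = 65
    ),
    intervention = list(
      delta_sbp = -3.03, delta_sbp_ci = c(-5.33, -0.73),
      delta_hba1c = -0.14, delta_hba1c_ci = c(-0.24, -0.03),
      hba1c_diabetes_threshold = 6.5
    ),
    sim = list(
      discount_rate = 0.03,
      wtp = 150000,
      epsilon = 0.5,
      entry_age_range = c(19, 64),
      max_age = 85,
      medicare_age = 65,
      horizon = "lifetime",
      population_n = 189980531,
      prob_cap = 0.99
    ),
    bounds = list(
      sbp = c(80, 250), total_chol = c(100, 400), hdl_chol = c(20, 120),
      hba1c = c(3, 15), bmi = c(12, 80)
    )
  )
  params$psa <- default_psa_spec(params)
  class(params) <- "cvd_params"
  params
}

#' Default probabilistic sensitivity analysis distributions
#'
#' Intervention effects are normal with SD derived from the printed 95% CIs
#' (`sd = (upper - lower) / (2 * 1.959964)`); cost-type parameters are gamma;
#' shares and the utility intercept are beta. Mean-zero or zero-SD entries
#' are treated as degenerate (always return the mean). `dsa` marks inclusion
#' in the +/-20% one-way sweep; parameters that affect transition
#' probabilities (the intervention effects) are excluded from that sweep.
#'
#' @param params a `cvd_params` list (for CI-derived SDs and point values).
#' @return tibble with columns name, dist, mean, sd, dsa.
#' @export
default_psa_spec <- function(params) {
  ci_sd <- function(ci) (ci[2] - ci[1]) / (2 * stats::qnorm(0.975))
  e <- params$econ
  cu <- params$cost_utility
  cost_int <- cu$value[cu$outcome == "cost" & cu$term == "intercept"]
  util_int <- cu$value[cu$outcome == "utility" & cu$term == "intercept"]
  tibble::tibble(
    name = c("delta_sbp", "delta_hba1c", "expansion_cost_multiplier",
             "preventive_cost", "admin_cost_per_enrollee", "admin_cvd_share",
             "avg_annual_earnings", "productivity_event_cost", "event_markup",
             "oop_share_uninsured", "oop_share_medicaid", "cost_intercept",
             "utility_intercept", "discount_rate"),
    dist = c("normal", "normal", "gamma", "gamma", "gamma", "beta", "gamma",
             "gamma", "gamma", "beta", "beta", "gamma", "beta", "degenerate"),
    mean = c(params$intervention$delta_sbp, params$intervention$delta_hba1c,
             e$expansion_cost_multiplier, e$preventive_cost,
             e$admin_cost_per_enrollee, e$admin_cvd_share,
             e$avg_annual_earnings, e$productivity_event_cost, e$event_markup,
             e$oop_share_uninsured, e$oop_share_medicaid, cost_int, util_int,
             params$sim$discount_rate),
    sd = c(ci_sd(params$intervention$delta_sbp_ci),
           ci_sd(params$intervention$delta_hba1c_ci),
           0.20 * e$expansion_cost_multiplier, 0.20 * e$preventive_cost,
           0.20 * e$admin_cost_per_enrollee, 0.20 * e$admin_cvd_share,
           0.10 * e$avg_annual_earnings, 0.20 * e$productivity_event_cost,
           0.10 * e$event_markup, 0.05, 0.015, 0.10 * cost_int, 0.01, 0),
    dsa = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
            TRUE, TRUE, TRUE, TRUE)
  )
}

#' Write a named parameter value back into a parameter set
#'
#' Maps the flat parameter names used by the PSA/DSA machinery onto their
#' locations inside a `cvd_params` list.
#'
#' @param params a `cvd_params` list.
#' @param name flat parameter name (a `name` from [default_psa_spec()]).
#' @param value replacement value.
#' @return the modified parameter set.
#' @export
set_parameter <- function(params, name, value) {
  econ_names <- c("expansion_cost_multiplier", "preventive_cost",
                  "admin_cost_per_enrollee", "admin_cvd_share",
                  "avg_annual_earnings", "productivity_event_cost",
                  "event_markup", "oop_share_uninsured", "oop_share_insured",
                  "oop_share_medicaid")
  if (name %in% econ_names) {
    params$econ[[name]] <- value
  } else if (name %in% c("delta_sbp", "delta_hba1c")) {
    params$intervention[[name]] <- value
  } else if (name == "discount_rate") {
    params$sim$discount_rate <- value
  } else if (name == "cost_intercept") {
    i <- params$cost_utility$outcome == "cost" & params$cost_utility$term == "intercept"
    params$cost_utility$value[i] <- value
  } else if (name == "utility_intercept") {
    i <- params$cost_utility$outcome == "utility" & params$cost_utility$term == "intercept"
    params$cost_utility$value[i] <- value
  } else {
    stop("unknown parameter name: ", name)
  }
  params
}

#' Read a flat-named parameter value from a parameter set
#' @inheritParams set_parameter
#' @return numeric value.
#' @export
get_parameter <- function(params, name) {
  if (name %in% names(params$econ)) return(params$econ[[name]])
  if (name %in% c("delta_sbp", "delta_hba1c")) return(params$intervention[[name]])
  if (name == "discount_rate") return(params$sim$discount_rate)
  if (name == "cost_intercept") {
    i <- params$cost_utility$outcome == "cost" & params$cost_utility$term == "intercept"
    return(params$cost_utility$value[i])
  }
  if (name == "utility_intercept") {
    i <- params$cost_utility$outcome == "utility" & params$cost_utility$term == "intercept"
    return(params$cost_utility$value[i])
  }
  stop("unknown parameter name: ", name)
}

#' Null-intervention parameter set
#'
#' Returns a copy of `params` with zero intervention effects and zero cost
#' deltas (utilization multiplier 1, no preventive or administration cost,
#' Medicaid OOP share equal to the uninsured share). Under common random
#' numbers the expansion arm is then identical to nonexpansion, and every
#' incremental quantity is exactly zero — the pipeline's null contract.
#'
#' @param params a `cvd_params` list.
#' @return the modified parameter set.
#' @export
null_intervention <- function(params) {
  params$intervention$delta_sbp <- 0
  params$intervention$delta_hba1c <- 0
  params$econ$expansion_cost_multiplier <- 1
  params$econ$preventive_cost <- 0
  params$econ$admin_cost_per_enrollee <- 0
  params$econ$oop_share_medicaid <- params$econ$oop_share_uninsured
  params
}

validate_mortality_table <- function(tab) {
  need <- c("age", "sex", "rate_all_cause", "rate_mi", "rate_stroke")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("mortality table missing columns: ", paste(miss, collapse = ", "))
  bad <- tab$rate_all_cause < tab$rate_mi + tab$rate_stroke | tab$rate_mi < 0 | tab$rate_stroke < 0
  if (any(bad)) {
    stop("mortality table rows with rate_all_cause < rate_mi + rate_stroke (or negative rates): rows ",
         paste(which(bad), collapse = ", "))
  }
  for (s in unique(tab$sex)) {
    ages <- sort(tab$age[tab$sex == s])
    if (ages[1] > 19 || ages[length(ages)] < 85) {
      stop("mortality table for sex '", s, "' must cover ages 19-85")
    }
  }
  invisible(tab)
}
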