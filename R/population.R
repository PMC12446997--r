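#' Configuration for the synthetic population generator
#'
#' The generator emulates the schema and marginal structure of a national
#' fasting-subsample survey of nonelderly US adults: demographics,
#' socioeconomic strata, insurance, cardiovascular risk factors, baseline
#' CVD history and survey weights. Default stratum fractions follow the
#' study population (Medicaid-eligible ~0.10, CVD history ~0.05, and the
#' income/education/race fractions of the base-case reporting table).
#'
#' @param ... overrides for any default element (unknown names are an error).
#' @return list of class `population_config`.
#' @export
population_config <- function(...) {
  cfg <- list(
    n = 8141,
    pop_total = 189980531,
    frac_income = c(poor = 0.18, near_poor = 0.06, low = 0.15,
                    medium = 0.28, high = 0.34),
    frac_education = c(no_degree = 0.14, ged_hs = 0.22,
                       associate_bachelor = 0.33, master_doctorate = 0.31),
    frac_race = c(White = 0.61, Black = 0.12, Hispanic = 0.17,
                  Asian = 0.06, Other = 0.04),
    frac_cvd_history = 0.05,
    frac_medicaid_eligible = 0.10,
    frac_female = 0.51,
    frac_smoker = 0.20,
    frac_htn_treatment = 0.18,
    insured_rate_not_poor = 0.88,
    # Income bands relative to the federal poverty line: eligibility requires
    # income below 138% FPL; the redistribution levy falls on bands above
    # 150% FPL ("low" straddles; assigned above by default).
    income_below_138 = c("poor", "near_poor"),
    income_above_150 = c("low", "medium", "high"),
    age_range = c(19, 64),
    # risk-factor marginals (normal, clamped to physiologic bounds)
    rf_mean = c(sbp = 122, total_chol = 190, hdl_chol = 53, hba1c = 5.6, bmi = 29),
    rf_sd = c(sbp = 15, total_chol = 38, hdl_chol = 15, hba1c = 0.7, bmi = 6.5),
    rf_corr = default_rf_corr(),
    hba1c_diabetes_threshold = 6.5,
    weight_sdlog = 0.3,
    fraction_tolerance = 0.02
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown population_config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  for (f in c("frac_income", "frac_education", "frac_race")) {
    s <- sum(cfg[[f]])
    if (s > 1 + 0.05 || s < 1 - 0.05) {
      stop("infeasible fraction targets in ", f, ": sum = ", format(s))
    }
  }
  class(cfg) <- "population_config"
  cfg
}

default_rf_corr <- function() {
  v <- c("sbp", "total_chol", "hdl_chol", "hba1c", "bmi")
  R <- diag(5)
  dimnames(R) <- list(v, v)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("sbp", "total_chol", 0.10)
  set_r("sbp", "hdl_chol", -0.05)
  set_r("sbp", "hba1c", 0.20)
  set_r("sbp", "bmi", 0.25)
  set_r("total_chol", "hdl_chol", -0.10)
  set_r("total_chol", "hba1c", 0.10)
  set_r("total_chol", "bmi", 0.10)
  set_r("hdl_chol", "hba1c", -0.15)
  set_r("hdl_chol", "bmi", -0.30)
  set_r("hba1c", "bmi", 0.35)
  R
}

population_schema <- function() {
  c(id = "integer", age = "double", sex = "character",
    race_ethnicity = "character", income_group = "character",
    education = "character", insured = "logical",
    medicaid_eligible = "logical", sbp = "double", total_chol = "double",
    hdl_chol = "double", hba1c = "double", diabetes = "logical",
    smoker = "logical", bmi = "double", on_htn_treatment = "logical",
    cvd_history = "logical", weight = "double")
}

# deterministic largest-remainder allocation of n units to target fractions
allocate_counts <- function(n, fracs) {
  p <- fracs / sum(fracs)
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  k
}

#' Generate a synthetic person-level population
#'
#' Categorical strata are allocated by largest-remainder counts (so sample
#' fractions are as close to the targets as `n` allows) and shuffled;
#' correlated risk factors are drawn from a Gaussian copula over
#' (sbp, total cholesterol, HDL, HbA1c, BMI) and clamped to physiologic
#' bounds; diabetes is derived from HbA1c at the configured threshold;
#' Medicaid eligibility is derived (uninsured, aged 19-64, income below the
#' 138% FPL bands) rather than sampled, so the eligibility invariant holds
#' by construction. Survey weights are lognormal, scaled to sum to the
#' weighted population total.
#'
#' @param config a [population_config()].
#' @param seed integer seed; the same (config, seed) yields an identical
#'   sample.
#' @return tibble with one row per individual (see [population_config()] for
#'   the schema), attributes `pop_scale` (sum of weights) and
#'   `imputation_id`.
#' @export
generate_population <- function(config = population_config(), seed = 1) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n
  empty <- tibble::as_tibble(sapply(names(population_schema()), function(x) {
    vector(unname(population_schema()[x]), 0)
  }, simplify = FALSE))
  if (n == 0) {
    attr(empty, "pop_scale") <- 0
    attr(empty, "imputation_id") <- 1L
    return(empty)
  }
  set.seed(seed)

  assign_cat <- function(fracs) {
    k <- allocate_counts(n, fracs)
    sample(rep(names(fracs), k))
  }
  income <- assign_cat(config$frac_income)
  education <- assign_cat(config$frac_education)
  race <- assign_cat(config$frac_race)
  sex <- assign_cat(c(female = config$frac_female, male = 1 - config$frac_female))
  age <- floor(stats::runif(n, config$age_range[1], config$age_range[2] + 1))
  age <- pmin(age, config$age_range[2])

  # CVD history: fixed-count random subset
  cvd_history <- rep(FALSE, n)
  cvd_history[sample.int(n, round(n * config$frac_cvd_history))] <- TRUE

  # eligibility derived from (insured, age, income): choose a fixed-count
  # uninsured subset inside the below-138%-FPL bands
  below138 <- income %in% config$income_below_138
  n_elig <- round(n * config$frac_medicaid_eligible)
  if (n_elig > sum(below138)) {
    stop("infeasible fraction targets: medicaid_eligible target exceeds the below-138% FPL bands")
  }
  insured <- stats::runif(n) < config$insured_rate_not_poor
  idx_elig <- sample(which(below138), n_elig)
  insured[below138] <- TRUE # non-selected low-income persons kept insured
  insured[idx_elig] <- FALSE
  medicaid_eligible <- !insured & below138

  # correlated risk factors via Gaussian copula
  vars <- c("sbp", "total_chol", "hdl_chol", "hba1c", "bmi")
  Z <- matrix(stats::rnorm(n * 5), n, 5) %*% chol(config$rf_corr[vars, vars])
  bounds <- list(sbp = c(80, 250), total_chol = c(100, 400),
                 hdl_chol = c(20, 120), hba1c = c(3, 15), bmi = c(12, 80))
  rf <- lapply(seq_along(vars), function(j) {
    v <- vars[j]
    x <- config$rf_mean[[v]] + config$rf_sd[[v]] * Z[, j]
    pmin(pmax(x, bounds[[v]][1]), bounds[[v]][2])
  })
  names(rf) <- vars

  smoker <- stats::runif(n) < config$frac_smoker
  on_htn <- stats::runif(n) < config$frac_htn_treatment
  w <- stats::rlnorm(n, meanlog = -config$weight_sdlog^2 / 2, sdlog = config$weight_sdlog)
  w <- w / sum(w) * config$pop_total

  pop <- tibble::tibble(
    id = seq_len(n), age = as.numeric(age), sex = sex, race_ethnicity = race,
    income_group = income, education = education, insured = insured,
    medicaid_eligible = medicaid_eligible, sbp = rf$sbp,
    total_chol = rf$total_chol, hdl_chol = rf$hdl_chol, hba1c = rf$hba1c,
    diabetes = rf$hba1c >= config$hba1c_diabetes_threshold, smoker = smoker,
    bmi = rf$bmi, on_htn_treatment = on_htn, cvd_history = cvd_history,
    weight = w
  )
  attr(pop, "pop_scale") <- sum(w)
  attr(pop, "imputation_id") <- 1L
  pop
}

#' Weighted stratum fractions of a population sample
#'
#' @param pop population tibble.
#' @return named list of weighted fractions: medicaid_eligible, cvd_history,
#'   and per income/education/race stratum.
#' @export
population_fractions <- function(pop) {
  wf <- function(flag) sum(pop$weight[flag]) / sum(pop$weight)
  by_cat <- function(col) {
    v <- tapply(pop$weight, pop[[col]], sum) / sum(pop$weight)
    as.list(v)
  }
  list(medicaid_eligible = wf(pop$medicaid_eligible),
       cvd_history = wf(pop$cvd_history),
       income = by_cat("income_group"),
       education = by_cat("education"),
       race = by_cat("race_ethnicity"))
}

#' Validate a population table against the schema and invariants
#'
#' @param pop data frame to validate.
#' @param config a [population_config()] (for the eligibility income bands).
#' @return the validated tibble, invisibly usable; errors name offending
#'   columns or rows.
#' @export
validate_population <- function(pop, config = population_config()) {
  miss <- setdiff(names(population_schema()), names(pop))
  if (length(miss)) stop("population missing required column(s): ", paste(miss, collapse = ", "))
  bounds <- list(sbp = c(80, 250), total_chol = c(100, 400),
                 hdl_chol = c(20, 120), hba1c = c(3, 15), bmi = c(12, 80))
  for (v in names(bounds)) {
    bad <- which(pop[[v]] < bounds[[v]][1] | pop[[v]] > bounds[[v]][2])
    if (length(bad)) {
      stop("column '", v, "' outside physiologic bounds [", bounds[[v]][1],
           ", ", bounds[[v]][2], "] in row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
  }
  if (any(pop$weight <= 0)) {
    stop("nonpositive survey weight in row(s): ",
         paste(utils::head(which(pop$weight <= 0), 10), collapse = ", "))
  }
  if (anyDuplicated(pop$id)) stop("duplicate individual ids")
  ok_elig <- !pop$medicaid_eligible |
    (!pop$insured & pop$age >= 19 & pop$age <= 64 &
       pop$income_group %in% config$income_below_138)
  if (!all(ok_elig)) {
    stop("medicaid_eligible inconsistent with (insured, age, income) in row(s): ",
         paste(utils::head(which(!ok_elig), 10), collapse = ", "))
  }
  tibble::as_tibble(pop)
}

#' Read a population CSV
#'
#' @param path CSV file with the population schema.
#' @param config a [population_config()] used for validation.
#' @return validated population tibble with `pop_scale` attribute.
#' @export
load_population <- function(path, config = population_config()) {
  sch <- population_schema()
  cts <- paste(vapply(unname(sch), function(t) {
    switch(t, integer = "i", double = "d", character = "c", logical = "l")
  }, ""), collapse = "")
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  miss <- setdiff(names(sch), hdr)
  if (length(miss)) stop("population file missing required column(s): ", paste(miss, collapse = ", "))
  pop <- readr::read_csv(path, col_types = cts, col_select = dplyr::all_of(names(sch)))
  pop <- validate_population(pop, config)
  attr(pop, "pop_scale") <- sum(pop$weight)
  attr(pop, "imputation_id") <- 1L
  pop
}

#' Write a population table to CSV
#'
#' Uses shortest-round-trip formatting so that [load_population()] recovers
#' the sample exactly.
#'
#' @param pop population tibble.
#' @param path output path.
#' @export
write_population <- function(pop, path) {
  readr::write_csv(pop[, names(population_schema())], path)
  invisible(path)
}

#' Perturbed population replicates for multiple-imputation plumbing
#'
#' The generator emits complete data; this helper produces M replicates with
#' small Gaussian perturbations of the continuous risk factors (a stand-in
#' for between-imputation variability, so Rubin's-rules pooling can be
#' exercised without an imputation engine).
#'
#' @param pop population tibble.
#' @param m number of replicates.
#' @param seed integer seed.
#' @param rel_sd perturbation SD as a fraction of each factor's marginal SD.
#' @return list of m population tibbles with `imputation_id` attributes 1..m.
#' @export
population_imputations <- function(pop, m = 10, seed = 1, rel_sd = 0.05) {
  set.seed(seed)
  cfg <- population_config()
  bounds <- list(sbp = c(80, 250), total_chol = c(100, 400),
                 hdl_chol = c(20, 120), hba1c = c(3, 15), bmi = c(12, 80))
  out <- vector("list", m)
  for (i in seq_len(m)) {
    p <- pop
    if (i > 1) { # first replicate is the observed data
      for (v in names(bounds)) {
        x <- p[[v]] + stats::rnorm(nrow(p), 0, rel_sd * cfg$rf_sd[[v]])
        p[[v]] <- pmin(pmax(x, bounds[[v]][1]), bounds[[v]][2])
      }
      p$diabetes <- p$hba1c >= cfg$hba1c_diabetes_threshold
    }
    attr(p, "imputation_id") <- i
    attr(p, "pop_scale") <- sum(p$weight)
    out[[i]] <- p
  }
  out
}
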