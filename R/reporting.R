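#' Validated run configuration
#'
#' Fills base-case defaults (WTP $150,000/QALY, inequality aversion 0.5, 3%
#' discounting, lifetime horizon) and cross-checks ranges. Accepts a named
#' list or a path to a JSON/YAML file; unknown keys are an error so typos
#' cannot silently fall back to defaults.
#'
#' @param config named list of overrides, or a path to a JSON/YAML file.
#' @return list of class `run_config` with the resolved settings.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("[.]ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required for YAML configs")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
    if (is.null(config)) config <- list()
  }
  defaults <- list(
    wtp = 150000,
    epsilon = 0.5,
    epsilon_grid = c(0, 0.5, 1, 1.5, 2, 2.5, 3),
    discount_rate = 0.03,
    horizon = "lifetime",
    seed = 1,
    n_boot = 50,
    m_imputations = 10,
    n_population = 2000,
    lambda_grid = seq(0, 1e6, by = 25000),
    perspective = "limited_societal",
    population_path = NULL,
    out_dir = "results"
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (cfg$wtp <= 0) stop("wtp must be positive")
  if (cfg$epsilon < 0 || cfg$epsilon > 20) stop("epsilon must be in [0, 20]")
  if (cfg$discount_rate < 0) stop("discount_rate must be nonnegative")
  if (!cfg$horizon %in% c("lifetime", "10yr", "to65")) {
    stop("horizon must be one of lifetime, 10yr, to65")
  }
  if (!cfg$perspective %in% c("limited_societal", "healthcare")) {
    stop("perspective must be limited_societal or healthcare")
  }
  if (cfg$n_boot < 1 || cfg$m_imputations < 1) stop("replication counts must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

#' Apply a run configuration to a parameter set
#'
#' @param params a `cvd_params` list.
#' @param cfg a [run_config()].
#' @return the parameter set with wtp/epsilon/discounting/horizon applied;
#'   under the healthcare-only perspective productivity costs are switched
#'   off.
#' @export
apply_run_config <- function(params, cfg) {
  params$sim$wtp <- cfg$wtp
  params$sim$epsilon <- cfg$epsilon
  params$sim$discount_rate <- cfg$discount_rate
  params$sim$horizon <- cfg$horizon
  if (cfg$perspective == "healthcare") {
    params$econ$productivity_event_cost <- 0
    params$econ$avg_annual_earnings <- 0
  }
  params
}

table1_label <- function(partition, group) {
  lab <- c(poor = "Poor", near_poor = "Near poor", low = "Low",
           medium = "Medium", high = "High", no_degree = "No degree",
           ged_hs = "GED/HS", associate_bachelor = "Associate/Bachelor",
           master_doctorate = "Master/Doctorate", Asian = "Asian",
           Black = "Black", Hispanic = "Hispanic", Other = "Other race",
           White = "White")
  out <- unname(lab[group])
  ifelse(is.na(out), group, out)
}

#' Base-case reporting table
#'
#' Assembles the study's main reporting shape: per-person incremental costs
#' (whole 2021 dollars), incremental QALYs and INHB (4 decimals) for the
#' total population, Medicaid-eligible-only and history-of-CVD subgroups and
#' each income/education/race stratum, with the per-partition IEDEH across
#' the epsilon grid and population fractions. Unrounded values are kept in
#' `_raw` columns.
#'
#' @param summary output of [dcea_summary()] (run with the epsilon grid of
#'   interest).
#' @return tibble; header-only when the summary is empty.
#' @export
build_table1 <- function(summary) {
  empty <- tibble::tibble(
    label = character(), partition = character(), fraction = double(),
    delta_cost = double(), delta_qalys = double(), inhb = double(),
    delta_cost_raw = double(), delta_qalys_raw = double(), inhb_raw = double()
  )
  if (is.null(summary$total) || nrow(summary$total) == 0) return(empty)
  rows <- dplyr::bind_rows(
    dplyr::mutate(summary$total, partition = NA_character_),
    summary$subgroups
  )
  rows$label <- ifelse(is.na(rows$partition) | rows$label %in% c("Total",
                       "Medicaid eligible only", "History of CVD"),
                       rows$label, table1_label(rows$partition, rows$label))
  out <- tibble::tibble(
    label = rows$label, partition = rows$partition,
    fraction = round(rows$fraction, 2),
    delta_cost = round(rows$delta_cost),
    delta_qalys = round(rows$delta_qalys, 4),
    inhb = round(rows$inhb, 4),
    delta_cost_raw = rows$delta_cost, delta_qalys_raw = rows$delta_qalys,
    inhb_raw = rows$inhb
  )
  if (!is.null(summary$equity) && nrow(summary$equity)) {
    eq <- summary$equity[, c("partition", "epsilon", "iedeh")]
    eq <- tidyr::pivot_wider(eq, names_from = "epsilon", values_from = "iedeh",
                             names_prefix = "iedeh_eps_")
    out <- dplyr::left_join(out, eq, by = "partition")
    for (cl in grep("^iedeh_eps_", names(out), value = TRUE)) {
      # IEDEH shown on the partition's first row only, as in the source table
      first <- !duplicated(out$partition) & !is.na(out$partition)
      out[[cl]][!first] <- NA_real_
      out[[cl]] <- round(out[[cl]], 4)
    }
  }
  out
}
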