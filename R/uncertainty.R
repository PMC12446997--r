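derive_seed <- function(master, imputation = 0L, boot = 0L, stage = 0L) {
  # deterministic 31-bit seed from the master seed and loop indices
  s <- (as.numeric(master) * 1000003 + imputation * 10007 + boot * 101 + stage * 13) %% 2147483647
  as.integer(s)
}

draw_one <- function(dist, mean, sd) {
  if (dist == "degenerate" || sd == 0) return(mean)
  switch(dist,
    normal = stats::rnorm(1, mean, sd),
    gamma = {
      shape <- (mean / sd)^2
      stats::rgamma(1, shape = shape, rate = shape / mean)
    },
    beta = {
      # method-of-moments (mean, sd) -> (alpha, beta)
      v <- sd^2
      k <- mean * (1 - mean) / v - 1
      stats::rbeta(1, mean * k, (1 - mean) * k)
    },
    stop("unknown PSA distribution: ", dist)
  )
}

#' Draw one parameter vector for probabilistic sensitivity analysis
#'
#' Samples every row of `params$psa` from its declared distribution (normal
#' for intervention effects with CI-derived SDs, gamma for costs, beta for
#' shares) and writes the draws back into the parameter set. Degenerate
#' (zero-SD) rows return their means, so a fully degenerate specification
#' reproduces the deterministic base case exactly.
#'
#' @param params a `cvd_params` list.
#' @param seed integer seed for the draw.
#' @return list with `params` (the updated set) and `draws` (named vector).
#' @export
draw_psa_params <- function(params, seed) {
  set.seed(seed)
  spec <- params$psa
  draws <- numeric(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    draws[i] <- draw_one(spec$dist[i], spec$mean[i], spec$sd[i])
    params <- set_parameter(params, spec$name[i], draws[i])
  }
  names(draws) <- spec$name
  list(params = params, draws = draws)
}

#' Probabilistic (and bootstrap) sensitivity analysis
#'
#' For each imputed data set and bootstrap replication: resample individuals
#' with replacement, draw one parameter vector from the PSA distributions,
#' run both arms on identical draws (common random numbers), and record the
#' per-person-mean incremental cost, incremental QALYs, and the incremental
#' EDEH per equity partition at (`wtp`, `epsilon`).
#'
#' @param samples a population tibble or list of them (one per imputation).
#' @param params a `cvd_params` list.
#' @param n_boot bootstrap replications per imputation.
#' @param seed master seed; every replication's seeds derive from it.
#' @param wtp,epsilon threshold and inequality aversion for the IEDEH
#'   columns.
#' @param partitions equity partitions to track.
#' @param config a [population_config()].
#' @param resample bootstrap-resample individuals per replication (TRUE, the
#'   default); with `FALSE` and all-degenerate distributions the PSA
#'   reproduces the deterministic base case exactly.
#' @return tibble with one row per (imputation, boot): `delta_cost`,
#'   `delta_qalys`, `inhb`, and `iedeh_<partition>` columns.
#' @export
run_psa <- function(samples, params, n_boot = 50, seed = 1,
                    wtp = params$sim$wtp, epsilon = params$sim$epsilon,
                    partitions = c("income_group", "education", "race_ethnicity"),
                    config = population_config(), resample = TRUE) {
  if (is.data.frame(samples)) samples <- list(samples)
  if (n_boot < 1) stop("n_boot must be at least 1")
  rows <- vector("list", length(samples) * n_boot)
  k <- 0
  for (m in seq_along(samples)) {
    pop <- samples[[m]]
    for (b in seq_len(n_boot)) {
      if (resample) {
        set.seed(derive_seed(seed, m, b, stage = 1L))
        idx <- sample.int(nrow(pop), replace = TRUE)
        boot <- pop[idx, ]
        boot$id <- seq_len(nrow(boot))
      } else {
        boot <- pop
      }
      drawn <- draw_psa_params(params, derive_seed(seed, m, b, stage = 2L))
      run_seed <- derive_seed(seed, m, b, stage = 3L)
      res_n <- run_arm(boot, drawn$params, "nonexpansion", run_seed, config)
      res_e <- run_arm(boot, drawn$params, "expansion", run_seed, config)
      w <- boot$weight
      dc <- weighted_mean(res_e$cost - res_n$cost, w)
      de <- weighted_mean(res_e$qalys - res_n$qalys, w)
      row <- tibble::tibble(
        imputation = m, boot = b, delta_cost = dc, delta_qalys = de,
        inhb = net_health_benefit(dc, de, wtp)
      )
      for (p in partitions) {
        row[[paste0("iedeh_", p)]] <- iedeh(res_e, res_n, wtp, epsilon, p)
      }
      k <- k + 1
      rows[[k]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "wtp") <- wtp
  attr(out, "epsilon") <- epsilon
  out
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of replications with positive incremental net health benefit at
#' each willingness-to-pay value. As `lambda` grows the INHB sign is
#' dominated by the incremental effect, so the curve tends to
#' `P(delta_qalys > 0)`.
#'
#' @param replications tibble from [run_psa()] (needs `delta_cost`,
#'   `delta_qalys`).
#' @param lambda_grid willingness-to-pay grid (USD/QALY), positive.
#' @return tibble with `wtp` and `p_cost_effective`.
#' @export
ceac <- function(replications, lambda_grid = seq(0, 1e6, by = 25000)) {
  if (nrow(replications) < 1) stop("need at least one replication")
  lambda_grid <- lambda_grid[lambda_grid >= 0]
  p <- vapply(lambda_grid, function(l) {
    inhb <- if (l == 0) {
      -replications$delta_cost # WTP 0: cost-effective iff cost saving
    } else {
      net_health_benefit(replications$delta_cost, replications$delta_qalys, l)
    }
    mean(inhb > 0)
  }, 0)
  tibble::tibble(wtp = lambda_grid, p_cost_effective = p)
}

#' DCEA-PSA quadrant probabilities
#'
#' Classifies each replication on the equity-efficiency plane (efficient:
#' INHB > 0; equity enhancing: IEDEH > INHB) and returns, per partition, the
#' probability of each quadrant. The four probabilities sum to 1.
#'
#' @param replications tibble from [run_psa()].
#' @param partitions partitions to summarize (must have `iedeh_*` columns).
#' @return tibble: partition, quadrant, probability.
#' @export
dcea_psa <- function(replications,
                     partitions = c("income_group", "education", "race_ethnicity")) {
  dplyr::bind_rows(lapply(partitions, function(p) {
    ie <- replications[[paste0("iedeh_", p)]]
    if (is.null(ie)) stop("replications lack column iedeh_", p)
    eff <- replications$inhb > 0
    eq <- ie > replications$inhb
    tibble::tibble(
      partition = p,
      quadrant = c("efficient, equity enhancing", "efficient, equity reducing",
                   "not cost-effective, equity enhancing",
                   "not cost-effective, equity reducing"),
      probability = c(mean(eff & eq), mean(eff & !eq), mean(!eff & eq),
                      mean(!eff & !eq))
    )
  }))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Sequentially sets each swept parameter to 0.8x and 1.2x its base value
#' (other parameters at base values, fixed seed, no resampling) and records
#' the total-population INHB. Parameters flagged as affecting transition
#' probabilities are excluded.
#'
#' @param sample population tibble.
#' @param params a `cvd_params` list.
#' @param seed integer seed for the paired runs.
#' @param wtp willingness-to-pay threshold.
#' @param config a [population_config()].
#' @return tibble sorted by `abs(range)` descending: parameter, base value,
#'   INHB at low/high, range.
#' @export
dsa_tornado <- function(sample, params, seed = 1, wtp = params$sim$wtp,
                        config = population_config()) {
  spec <- params$psa
  swept <- spec$name[spec$dsa]
  skipped <- spec$name[!spec$dsa]
  if (length(skipped)) {
    message("excluded from the +/-20% sweep (affect transition probabilities): ",
            paste(skipped, collapse = ", "))
  }
  run_inhb <- function(p) {
    res_n <- run_arm(sample, p, "nonexpansion", seed, config)
    res_e <- run_arm(sample, p, "expansion", seed, config)
    w <- sample$weight
    net_health_benefit(weighted_mean(res_e$cost - res_n$cost, w),
                       weighted_mean(res_e$qalys - res_n$qalys, w), wtp)
  }
  base_inhb <- run_inhb(params)
  rows <- lapply(swept, function(nm) {
    base <- get_parameter(params, nm)
    lo <- run_inhb(set_parameter(params, nm, 0.8 * base))
    hi <- run_inhb(set_parameter(params, nm, 1.2 * base))
    tibble::tibble(parameter = nm, base_value = base, inhb_low = lo,
                   inhb_high = hi, range = hi - lo)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(abs(out$range), decreasing = TRUE), ]
  attr(out, "base_inhb") <- base_inhb
  out
}

#' Pool estimates across imputations with Rubin's rules
#'
#' @param estimates per-imputation point estimates.
#' @param variances per-imputation (within-imputation) variances.
#' @return list with `pooled` (mean of estimates) and `total_variance`
#'   (within-mean + (1 + 1/M) x between-imputation variance).
#' @export
rubins_rules <- function(estimates, variances = rep(0, length(estimates))) {
  m <- length(estimates)
  if (length(variances) != m) stop("estimates and variances must have equal length")
  if (m < 1) stop("need at least one imputation")
  if (m == 1) {
    warning("single imputation: between-imputation variance is zero")
    return(list(pooled = estimates, total_variance = variances))
  }
  between <- stats::var(estimates)
  list(pooled = mean(estimates),
       total_variance = mean(variances) + (1 + 1 / m) * between)
}

#' Monte Carlo standard error of a replication mean
#'
#' @param values replication values (length >= 2).
#' @return `sd(values) / sqrt(length(values))`.
#' @export
monte_carlo_se <- function(values) {
  b <- length(values)
  if (b < 2) stop("Monte Carlo standard error undefined for fewer than 2 replications")
  stats::sd(values) / sqrt(b)
}
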