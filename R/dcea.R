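#' Net health benefit
#'
#' Converts costs to health units at the willingness-to-pay threshold:
#' `NHB = qalys - cost / wtp`. Applied to incremental quantities it gives the
#' incremental net health benefit `INHB = dE - dC / wtp`.
#'
#' @param cost (incremental) cost in USD.
#' @param qalys (incremental) effects in QALYs.
#' @param wtp willingness-to-pay threshold (USD/QALY), > 0.
#' @return net health benefit in QALYs.
#' @export
net_health_benefit <- function(cost, qalys, wtp = 150000) {
  if (any(wtp <= 0)) stop("willingness-to-pay threshold must be positive")
  qalys - cost / wtp
}

#' Atkinson equally distributed equivalent of health
#'
#' The equal-for-all health level with the same social welfare as the actual
#' distribution under the Atkinson function with inequality aversion
#' `epsilon`: for `epsilon != 1`, `(sum(w * h^(1 - epsilon)))^(1 / (1 -
#' epsilon))`; for `epsilon = 1`, `exp(sum(w * log(h)))`. Equal to the
#' weighted mean at `epsilon = 0` or when all `h` are equal, and weakly
#' decreasing in `epsilon`.
#'
#' @param health positive per-group health levels (e.g. net health benefit).
#' @param weights population fractions summing to 1.
#' @param epsilon inequality aversion, >= 0.
#' @return the EDEH (same units as `health`).
#' @export
atkinson_ede <- function(health, weights, epsilon) {
  if (epsilon < 0) stop("epsilon must be nonnegative")
  if (any(health <= 0)) {
    stop("Atkinson EDE undefined for nonpositive health values; ",
         "see the affine-shift option in dcea_summary()")
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (epsilon == 1) {
    exp(sum(weights * log(health)))
  } else {
    sum(weights * health^(1 - epsilon))^(1 / (1 - epsilon))
  }
}

#' Atkinson inequality index
#'
#' `A = 1 - EDEH / NHB`, the relative welfare loss from inequality; in
#' `[0, 1)` for positive NHB, 0 when there is no inequality or no aversion.
#' Undefined (returned as `NA` with a warning) for nonpositive mean NHB.
#'
#' @param edeh equally distributed equivalent health.
#' @param nhb mean (per-person) net health benefit.
#' @return dimensionless index.
#' @export
atkinson_index <- function(edeh, nhb) {
  if (nhb <= 0) {
    warning("Atkinson index undefined for nonpositive net health benefit")
    return(NA_real_)
  }
  1 - edeh / nhb
}

#' Change in the population burden of health inequality
#'
#' The inequality burden of an arm is `A_eps x NHB` per person; expansion's
#' change is `(A x NHB)_nonexpansion - (A x NHB)_expansion`, scaled to the
#' population. Positive values are equity enhancing.
#'
#' @param nhb_exp,edeh_exp per-person NHB and EDEH in the expansion arm.
#' @param nhb_non,edeh_non same for nonexpansion.
#' @param population_n population size the sample represents.
#' @return change in inequality burden, QALYs at population scale.
#' @export
inequality_burden_change <- function(nhb_exp, edeh_exp, nhb_non, edeh_non,
                                     population_n = 189980531) {
  a_exp <- atkinson_index(edeh_exp, nhb_exp)
  a_non <- atkinson_index(edeh_non, nhb_non)
  (a_non * nhb_non - a_exp * nhb_exp) * population_n
}

#' Equity-efficiency plane coordinates
#'
#' y: the population welfare gain through cost-effectiveness (INHB x N);
#' x: the excess welfare gain through redistribution ((IEDEH - INHB) x N).
#' The top-right quadrant is efficient and equity enhancing; the
#' bottom-right is not cost-effective but equity enhancing.
#'
#' @param inhb_pp per-person incremental net health benefit.
#' @param iedeh_pp per-person incremental EDEH at the same wtp and epsilon.
#' @param population_n population scale.
#' @return list with `x`, `y` and a `quadrant` label.
#' @export
equity_efficiency_point <- function(inhb_pp, iedeh_pp, population_n = 189980531) {
  y <- inhb_pp * population_n
  x <- (iedeh_pp - inhb_pp) * population_n
  quadrant <- paste0(
    if (inhb_pp > 0) "efficient" else "not cost-effective", ", ",
    if (iedeh_pp > inhb_pp) "equity enhancing" else "equity reducing"
  )
  list(x = x, y = y, quadrant = quadrant)
}

weighted_mean <- function(x, w) sum(x * w) / sum(w)

group_stats <- function(res, col) {
  g <- res[[col]]
  tibble::tibble(
    group = names(tapply(res$weight, g, sum)),
    fraction = as.numeric(tapply(res$weight, g, sum)) / sum(res$weight),
    cost = as.numeric(tapply(res$weight * res$cost, g, sum) / tapply(res$weight, g, sum)),
    qalys = as.numeric(tapply(res$weight * res$qalys, g, sum) / tapply(res$weight, g, sum))
  )
}

#' Distributional cost-effectiveness summary of a paired run
#'
#' Computes, from the paired (common-random-numbers) expansion and
#' nonexpansion arm results: overall and per-subgroup incremental costs,
#' incremental QALYs and INHB; per-partition Atkinson EDEH per arm, the
#' incremental EDEH (IEDEH), Atkinson indices, the population change in
#' inequality burden and equity-efficiency plane coordinates. Equity
#' distributions operate on per-subgroup mean net health weighted by
#' population fractions.
#'
#' @param res_exp,res_non `arm_result` tibbles for the expansion and
#'   nonexpansion arms (same individuals, same seed).
#' @param params a `cvd_params` list (wtp, epsilon, population size).
#' @param wtp willingness-to-pay threshold (USD/QALY).
#' @param epsilon inequality aversion value(s).
#' @param partitions equity-relevant partition columns.
#' @param shift optional affine shift added to group NHB before the Atkinson
#'   computation (and removed after), for distributions with nonpositive
#'   values; default 0 (refuse on nonpositive NHB).
#' @return list with elements `total` (one-row tibble), `subgroups`
#'   (per-group incrementals for every partition plus the eligible-only and
#'   history-of-CVD rows), and `equity` (per partition x epsilon: EDEH and
#'   Atkinson per arm, IEDEH, burden change, plane coordinates).
#' @export
dcea_summary <- function(res_exp, res_non, params,
                         wtp = params$sim$wtp, epsilon = params$sim$epsilon,
                         partitions = c("income_group", "education", "race_ethnicity"),
                         shift = 0) {
  stopifnot(nrow(res_exp) == nrow(res_non), all(res_exp$id == res_non$id))
  w <- res_non$weight
  pop_n <- params$sim$population_n
  d_cost <- res_exp$cost - res_non$cost
  d_qaly <- res_exp$qalys - res_non$qalys
  inhb_pp <- net_health_benefit(weighted_mean(d_cost, w), weighted_mean(d_qaly, w), wtp)

  total <- tibble::tibble(
    label = "Total", fraction = 1,
    delta_cost = weighted_mean(d_cost, w),
    delta_qalys = weighted_mean(d_qaly, w),
    inhb = inhb_pp
  )

  sub_row <- function(flag, label) {
    tibble::tibble(
      label = label, fraction = sum(w[flag]) / sum(w),
      delta_cost = weighted_mean(d_cost[flag], w[flag]),
      delta_qalys = weighted_mean(d_qaly[flag], w[flag]),
      inhb = net_health_benefit(weighted_mean(d_cost[flag], w[flag]),
                                weighted_mean(d_qaly[flag], w[flag]), wtp)
    )
  }
  subgroups <- dplyr::bind_rows(
    sub_row(res_non$medicaid_eligible, "Medicaid eligible only"),
    sub_row(res_non$cvd_history, "History of CVD"),
    dplyr::bind_rows(lapply(partitions, function(p) {
      g <- res_non[[p]]
      dplyr::bind_rows(lapply(sort(unique(g)), function(lev) {
        row <- sub_row(g == lev, lev)
        row$partition <- p
        row
      }))
    }))
  )

  equity <- dplyr::bind_rows(lapply(partitions, function(p) {
    ge <- group_stats(res_exp, p)
    gn <- group_stats(res_non, p)
    nhb_e <- net_health_benefit(ge$cost, ge$qalys, wtp) + shift
    nhb_n <- net_health_benefit(gn$cost, gn$qalys, wtp) + shift
    mean_e <- sum(ge$fraction * nhb_e)
    mean_n <- sum(gn$fraction * nhb_n)
    dplyr::bind_rows(lapply(epsilon, function(eps) {
      ede_e <- atkinson_ede(nhb_e, ge$fraction, eps) - shift
      ede_n <- atkinson_ede(nhb_n, gn$fraction, eps) - shift
      iedeh <- ede_e - ede_n
      plane <- equity_efficiency_point(inhb_pp, iedeh, pop_n)
      tibble::tibble(
        partition = p, epsilon = eps, wtp = wtp,
        nhb_expansion = mean_e - shift, nhb_nonexpansion = mean_n - shift,
        edeh_expansion = ede_e, edeh_nonexpansion = ede_n,
        atkinson_expansion = atkinson_index(ede_e, mean_e - shift),
        atkinson_nonexpansion = atkinson_index(ede_n, mean_n - shift),
        inhb = inhb_pp, iedeh = iedeh,
        burden_change = inequality_burden_change(mean_e - shift, ede_e,
                                                 mean_n - shift, ede_n, pop_n),
        plane_x = plane$x, plane_y = plane$y, quadrant = plane$quadrant
      )
    }))
  }))
  list(total = total, subgroups = subgroups, equity = equity)
}

#' Paired-arm incremental EDEH for one partition
#'
#' Helper used by the sensitivity machinery: per-subgroup mean NHB per arm,
#' Atkinson EDEH at `epsilon`, and their incremental difference.
#'
#' @inheritParams dcea_summary
#' @param partition one partition column name.
#' @return `IEDEH = EDEH_expansion - EDEH_nonexpansion` (QALYs per person).
#' @export
iedeh <- function(res_exp, res_non, wtp, epsilon, partition = "income_group") {
  ge <- group_stats(res_exp, partition)
  gn <- group_stats(res_non, partition)
  atkinson_ede(net_health_benefit(ge$cost, ge$qalys, wtp), ge$fraction, epsilon) -
    atkinson_ede(net_health_benefit(gn$cost, gn$qalys, wtp), gn$fraction, epsilon)
}

#' Inequality aversion at which expansion becomes welfare enhancing
#'
#' Bisection (via [stats::uniroot()]) on `IEDEH(epsilon) = 0` over
#' `[0, 20]`; returns `NA` with a message when there is no sign change in
#' range.
#'
#' @inheritParams iedeh
#' @param interval search interval for epsilon.
#' @param tol bisection tolerance.
#' @return the break-even epsilon, or `NA_real_` if none in range.
#' @export
break_even_epsilon <- function(res_exp, res_non, wtp, partition = "income_group",
                               interval = c(0, 20), tol = 1e-4) {
  f <- function(eps) iedeh(res_exp, res_non, wtp, eps, partition)
  lo <- f(interval[1])
  hi <- f(interval[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0) {
    message("no break-even inequality aversion in [", interval[1], ", ",
            interval[2], "]")
    return(NA_real_)
  }
  stats::uniroot(f, interval, tol = tol)$root
}
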