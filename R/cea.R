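#' Incremental cost-effectiveness comparison
#'
#' Increments are intervention minus comparator. The ICER is the incremental
#' cost per incremental QALY, reported only when the incremental QALY is
#' non-zero; negative ICERs keep their sign. A strategy is `dominant` when it
#' is cheaper and more effective, `dominated` when costlier and less
#' effective. Net monetary benefit at the willingness-to-pay threshold
#' (`d_qaly * wtp - d_cost`) is also reported.
#'
#' @param comparator,intervention `outcomes` objects with the same horizon
#'   and discount rate.
#' @param wtp willingness-to-pay threshold in US$/QALY (default 30000, the
#'   1 x GDP-per-capita reference).
#' @return a `ce_result`: list with the two outcome sets, `d_cost`, `d_ly`,
#'   `d_qaly`, `icer`, `label` and `nmb`.
#' @export
compare_strategies <- function(comparator, intervention, wtp = 30000) {
  if (comparator$horizon_years != intervention$horizon_years ||
      comparator$discount_rate != intervention$discount_rate) {
    stop("comparator and intervention must share horizon and discount rate")
  }
  d_cost <- intervention$cost - comparator$cost
  d_ly <- intervention$life_years - comparator$life_years
  d_qaly <- intervention$qalys - comparator$qalys
  label <- if (d_qaly == 0) "undefined ICER"
    else if (d_cost < 0 && d_qaly > 0) "dominant"
    else if (d_cost > 0 && d_qaly < 0) "dominated"
    else "ICER"
  icer <- if (d_qaly == 0) NA_real_ else d_cost / d_qaly
  structure(list(comparator = comparator, intervention = intervention,
                 d_cost = d_cost, d_ly = d_ly, d_qaly = d_qaly,
                 icer = icer, label = label, wtp = wtp,
                 nmb = d_qaly * wtp - d_cost),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  fmt <- function(lab, o) {
    cat(sprintf("  %-13s cost US$%.2f, LY %.4f, QALY %.4f, cases/1000 %.2f\n",
                lab, o$cost, o$life_years, o$qalys, 1000 * o$cases_per_woman))
  }
  fmt("comparator", x$comparator)
  fmt("intervention", x$intervention)
  cat(sprintf("  increments    cost %.2f, LY %.4f, QALY %.4f\n",
              x$d_cost, x$d_ly, x$d_qaly))
  if (x$label %in% c("dominant", "dominated", "undefined ICER")) {
    cat(sprintf("  %s", x$label))
    if (!is.na(x$icer)) cat(sprintf(" (ICER %.2f US$/QALY)", x$icer))
    cat("\n")
  } else {
    cat(sprintf("  ICER %.2f US$/QALY\n", x$icer))
  }
  cat(sprintf("  NMB at WTP %.0f: US$%.2f\n", x$wtp, x$nmb))
  invisible(x)
}

# Evaluate comparator + PRS strategy under a scenario's overrides.
eval_scenario <- function(params, scenario = NULL, wtp = 30000) {
  comp_ages <- c(45, 69)
  if (!is.null(scenario) && !is.null(scenario$comparator_ages)) {
    comp_ages <- scenario$comparator_ages
  }
  p <- params
  if (!is.null(scenario) && !is.null(scenario$proportions)) {
    p$risk_groups$proportion <- scenario$proportions
  }
  comp <- evaluate_strategy(age_based_strategy(p, comp_ages[1], comp_ages[2]), p)
  intv <- evaluate_strategy(prs_strategy(p, scenario), p)
  compare_strategies(comp, intv, wtp = wtp)
}

#' Base-case comparison
#'
#' Evaluates the age-based 45-69 comparator and the base-case PRS-stratified
#' strategy under the given parameters and returns their incremental
#' comparison.
#'
#' @param params a `screen_params` object.
#' @param wtp willingness-to-pay threshold (US$/QALY).
#' @return a `ce_result`.
#' @export
run_base_case <- function(params, wtp = 30000) {
  eval_scenario(params, NULL, wtp = wtp)
}

#' Scenario grid
#'
#' Re-derives both strategies under each scenario's overrides and tabulates
#' the incremental results.
#'
#' @param params a `screen_params` object.
#' @param scenarios list of [scenario_spec()] objects
#'   (default [default_scenarios()]).
#' @param wtp willingness-to-pay threshold (US$/QALY).
#' @return data frame with one row per scenario: scenario, d_cost, d_ly,
#'   d_qaly, icer, label, cases_per_1000_comparator,
#'   cases_per_1000_intervention.
#' @export
run_scenarios <- function(params, scenarios = default_scenarios(), wtp = 30000) {
  rows <- lapply(scenarios, function(sc) {
    ce <- eval_scenario(params, sc, wtp = wtp)
    data.frame(scenario = sc$name, d_cost = ce$d_cost, d_ly = ce$d_ly,
               d_qaly = ce$d_qaly, icer = ce$icer, label = ce$label,
               cases_per_1000_comparator = 1000 * ce$comparator$cases_per_woman,
               cases_per_1000_intervention = 1000 * ce$intervention$cases_per_woman)
  })
  do.call(rbind, rows)
}

#' Discount-rate analysis
#'
#' Re-evaluates the base-case comparison at each discount rate, discounting
#' both costs and health outcomes.
#'
#' @param params a `screen_params` object.
#' @param rates annual discount rates in `[0, 1)`
#'   (default `c(0, 0.01, 0.03, 0.05)`).
#' @param wtp willingness-to-pay threshold (US$/QALY).
#' @return data frame: rate, d_cost, d_ly, d_qaly, icer, label.
#' @export
discount_rate_analysis <- function(params, rates = c(0, 0.01, 0.03, 0.05),
                                   wtp = 30000) {
  if (any(rates < 0 | rates >= 1)) stop("rates must be in [0, 1)")
  rows <- lapply(rates, function(r) {
    p <- params
    p$discount_rate <- r
    ce <- run_base_case(p, wtp = wtp)
    data.frame(rate = r, d_cost = ce$d_cost, d_ly = ce$d_ly,
               d_qaly = ce$d_qaly, icer = ce$icer, label = ce$label)
  })
  do.call(rbind, rows)
}

# Base value and modified parameter set for each one-way factor.
# "stage_costs" low/high are joint multiplicative factors (base 1);
# "stage_utilities" low/high are joint additive shifts (base 0, capped to
# [0, 1]); all other factors are absolute values.
sa_base_value <- function(params, parameter) {
  rg <- stats::setNames(params$risk_groups$multiplier, params$risk_groups$name)
  switch(parameter,
    multiplier_low = rg[["low"]],
    multiplier_intermediate = rg[["intermediate"]],
    multiplier_high = rg[["high"]],
    mammography_sensitivity = params$mammography_sensitivity,
    stage_costs = 1,
    snp_genotyping_cost = params$costs$snp_genotyping,
    genetic_counseling_cost = params$costs$genetic_counseling,
    stage_utilities = 0,
    stop("unknown one-way factor '", parameter, "'")
  )
}

apply_sa_value <- function(params, parameter, value) {
  p <- params
  rgn <- p$risk_groups$name
  switch(parameter,
    multiplier_low = p$risk_groups$multiplier[rgn == "low"] <- value,
    multiplier_intermediate =
      p$risk_groups$multiplier[rgn == "intermediate"] <- value,
    multiplier_high = p$risk_groups$multiplier[rgn == "high"] <- value,
    mammography_sensitivity = p$mammography_sensitivity <- value,
    stage_costs = p$costs$stage_annual <- p$costs$stage_annual * value,
    snp_genotyping_cost = p$costs$snp_genotyping <- value,
    genetic_counseling_cost = p$costs$genetic_counseling <- value,
    stage_utilities = {
      p$utilities$by_stage_year1 <- pmin(pmax(p$utilities$by_stage_year1 + value, 0), 1)
      p$utilities$by_stage_later <- pmin(pmax(p$utilities$by_stage_later + value, 0), 1)
    },
    stop("unknown one-way factor '", parameter, "'")
  )
  p
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the base-case ICER with each factor set to its low and high
#' bound, all other parameters at base values. Default bounds follow the
#' parameter table where it prints an explicit range (costs +-30%, utilities
#' +-0.1 capped at 1.0, varied jointly across stages) and +-20% for the risk
#' multipliers and mammography sensitivity (capped at 1.0).
#'
#' @param params a `screen_params` object.
#' @param ranges data frame with columns parameter, low, high
#'   (default `params$sa_ranges`).
#' @param wtp willingness-to-pay threshold (US$/QALY).
#' @return a `tornado` data frame sorted by decreasing bar width: parameter,
#'   base, low, high, icer_low, icer_high, width.
#' @export
one_way_sa <- function(params, ranges = params$sa_ranges, wtp = 30000) {
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    par <- ranges$parameter[i]
    lo <- ranges$low[i]
    hi <- ranges$high[i]
    base <- sa_base_value(params, par)
    if (!(lo <= base && base <= hi)) {
      stop("one-way range for '", par, "' does not bracket the base value ",
           base)
    }
    icer_lo <- run_base_case(apply_sa_value(params, par, lo), wtp = wtp)$icer
    icer_hi <- run_base_case(apply_sa_value(params, par, hi), wtp = wtp)$icer
    data.frame(parameter = par, base = base, low = lo, high = hi,
               icer_low = icer_lo, icer_high = icer_hi,
               width = abs(icer_hi - icer_lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", class(out))
  out
}
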