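#' Build a biennial (or other fixed-interval) screening schedule
#'
#' Screens occur at `start_age`, `start_age + interval`, ... up to and
#' including `stop_age` when it is hit exactly.
#'
#' @param start_age,stop_age first and last eligible ages (years).
#' @param interval years between screens (default 2, biennial).
#' @return a `screen_schedule`: list with `start_age`, `stop_age`, `interval`
#'   and the integer vector `screen_ages`.
#' @examples
#' build_schedule(45, 69)  # 13 screens at 45, 47, ..., 69
#' @export
build_schedule <- function(start_age, stop_age, interval = 2) {
  if (start_age > stop_age) {
    stop("start_age (", start_age, ") must be <= stop_age (", stop_age, ")")
  }
  if (interval < 1) stop("interval must be >= 1")
  structure(
    list(start_age = start_age, stop_age = stop_age, interval = interval,
         screen_ages = seq(start_age, stop_age, by = interval)),
    class = "screen_schedule"
  )
}

new_arm <- function(label, weight, multiplier, schedule = NULL,
                    one_time_cost = 0, one_time_cost_age = NA_real_) {
  if (weight < 0 || weight > 1) stop("arm weight must be in [0, 1]")
  if (one_time_cost < 0) stop("one_time_cost must be >= 0")
  list(label = label, weight = weight, multiplier = multiplier,
       schedule = schedule, one_time_cost = one_time_cost,
       one_time_cost_age = one_time_cost_age)
}

new_strategy <- function(name, arms) {
  w <- vapply(arms, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) {
    stop("strategy '", name, "': arm weights must sum to 1 (got ", sum(w), ")")
  }
  structure(list(name = name, arms = arms), class = "screen_strategy")
}

#' @export
print.screen_strategy <- function(x, ...) {
  cat(sprintf("<screen_strategy> %s\n", x$name))
  for (a in x$arms) {
    sched <- if (is.null(a$schedule)) "no screening" else {
      sprintf("screens %d-%d every %d y (%d screens)", a$schedule$start_age,
              a$schedule$stop_age, a$schedule$interval,
              length(a$schedule$screen_ages))
    }
    cat(sprintf("  %-13s weight %.2f, incidence x%.2f, %s", a$label, a$weight,
                a$multiplier, sched))
    if (a$one_time_cost > 0) {
      cat(sprintf(", one-time US$%.2f at age %g", a$one_time_cost,
                  a$one_time_cost_age))
    }
    cat("\n")
  }
  invisible(x)
}

#' Age-based comparator strategy
#'
#' The current population program: biennial mammography for every woman
#' between `start` and `stop`, at general-population incidence
#' (multiplier 1.0) and with no one-time testing costs.
#'
#' @param params a `screen_params` object (used only for interface symmetry).
#' @param start,stop screening start/stop ages (defaults 45 and 69).
#' @return a single-arm `screen_strategy`.
#' @export
age_based_strategy <- function(params, start = 45, stop = 69) {
  new_strategy(
    sprintf("age-based %d-%d", start, stop),
    list(new_arm("all women", 1, 1.0, build_schedule(start, stop, 2)))
  )
}

#' Scenario specification
#'
#' Optional overrides for [prs_strategy()] and [run_scenarios()]. `NULL`
#' fields keep the base case. Setting `genotyping_age` moves the one-time
#' genotyping + counseling cost AND the high- and intermediate-risk screening
#' start ages to that age. Setting `comparator_ages` also extends the
#' risk-stratified stop age to the comparator's stop age.
#'
#' @param name label used in scenario tables.
#' @param proportions length-3 numeric (low, intermediate, high), summing to 1.
#' @param high_start high-risk screening start age (base 35).
#' @param stop_age risk-stratified screening stop age (base 69).
#' @param comparator_ages length-2 numeric: age-based start and stop
#'   (base c(45, 69)).
#' @param genotyping_age age of SNP genotyping and counseling (base 35).
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(name = "scenario", proportions = NULL,
                          high_start = NULL, stop_age = NULL,
                          comparator_ages = NULL, genotyping_age = NULL) {
  if (!is.null(proportions)) {
    if (length(proportions) != 3 || abs(sum(proportions) - 1) > 1e-9) {
      stop("proportions must be three fractions (low, intermediate, high) summing to 1")
    }
  }
  if (!is.null(comparator_ages) && comparator_ages[1] > comparator_ages[2]) {
    stop("comparator_ages: start must be <= stop")
  }
  structure(list(name = name, proportions = proportions,
                 high_start = high_start, stop_age = stop_age,
                 comparator_ages = comparator_ages,
                 genotyping_age = genotyping_age),
            class = "scenario_spec")
}

#' PRS-stratified screening strategy
#'
#' Three weighted arms defined by the polygenic-risk groups. Under defaults:
#' the low-risk group (35%, incidence x0.6) receives no mammography; the
#' intermediate group (60%, x1.1) screens biennially from 40 to 69; the
#' high-risk group (5%, x1.5) from 35 to 69. Every woman incurs the one-time
#' SNP genotyping + genetic counseling cost at the genotyping age.
#'
#' @param params a `screen_params` object (risk-group proportions,
#'   multipliers and testing costs are read from it).
#' @param scenario optional [scenario_spec()] with overrides.
#' @return a three-arm `screen_strategy`.
#' @export
prs_strategy <- function(params, scenario = NULL) {
  rg <- params$risk_groups
  props <- stats::setNames(rg$proportion, rg$name)
  mult <- stats::setNames(rg$multiplier, rg$name)
  high_start <- 35
  int_start <- 40
  stop_age <- 69
  geno_age <- params$start_age
  if (!is.null(scenario)) {
    if (!is.null(scenario$proportions)) {
      props <- stats::setNames(scenario$proportions, c("low", "intermediate", "high"))
    }
    if (!is.null(scenario$high_start)) high_start <- scenario$high_start
    if (!is.null(scenario$stop_age)) stop_age <- scenario$stop_age
    if (!is.null(scenario$comparator_ages)) stop_age <- max(stop_age, scenario$comparator_ages[2])
    if (!is.null(scenario$genotyping_age)) {
      geno_age <- scenario$genotyping_age
      high_start <- max(high_start, geno_age)
      int_start <- max(int_start, geno_age)
    }
  }
  if (geno_age > high_start || geno_age > int_start) {
    stop("genotyping age must not exceed the screening start ages it governs")
  }
  one_time <- params$costs$snp_genotyping + params$costs$genetic_counseling
  new_strategy(
    "PRS-stratified",
    list(
      new_arm("low", unname(props["low"]), unname(mult["low"]), NULL,
              one_time, geno_age),
      new_arm("intermediate", unname(props["intermediate"]),
              unname(mult["intermediate"]),
              build_schedule(int_start, stop_age, 2), one_time, geno_age),
      new_arm("high", unname(props["high"]), unname(mult["high"]),
              build_schedule(high_start, stop_age, 2), one_time, geno_age)
    )
  )
}

#' Bundled scenario presets
#'
#' The scenario grid of the analysis: the base case, three alternative
#' risk-group percentile splits, high-risk start at 40, risk-stratified stop
#' at 74, the 40-74 age-based comparator (which also extends the
#' risk-stratified stop to 74), SNP genotyping at 40 (which also moves the
#' high- and intermediate-risk starts to 40), and 40/50/10 population
#' proportions.
#'
#' @return a list of [scenario_spec()] objects (first entry is the base case).
#' @export
default_scenarios <- function() {
  list(
    scenario_spec("base case"),
    scenario_spec("cutoffs 30L-60I-10H", proportions = c(0.30, 0.60, 0.10)),
    scenario_spec("cutoffs 35L-55I-10H", proportions = c(0.35, 0.55, 0.10)),
    scenario_spec("cutoffs 30L-65I-5H",  proportions = c(0.30, 0.65, 0.05)),
    scenario_spec("high-risk start age 40", high_start = 40),
    scenario_spec("risk-stratified stop age 74", stop_age = 74),
    scenario_spec("age-based screening 40-74", comparator_ages = c(40, 74)),
    scenario_spec("SNP genotyping at age 40", genotyping_age = 40),
    scenario_spec("proportions 40/50/10", proportions = c(0.40, 0.50, 0.10))
  )
}
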