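# State space: healthy; first-year (tunnel) and later-year cancer states for
# stages I-IV; absorbing death. 10 states in this fixed order.

#' Markov state names
#'
#' @return character vector of the 10 state labels, in matrix order.
#' @export
state_names <- function() {
  c("healthy", paste0("cancer_year1_", STAGES), paste0("cancer_later_", STAGES),
    "death")
}

#' Transition probabilities out of the healthy state
#'
#' The total cancer rate is `incidence(age) * multiplier`, times mammography
#' sensitivity when the cycle is screened; it is converted to a probability
#' with `1 - exp(-rate)` and split across stages by the screened or
#' unscreened stage distribution. Death uses the all-cause (excluding breast
#' cancer) rate for the age band. The remainder stays healthy.
#'
#' @param age integer age at cycle start.
#' @param screened logical, whether a mammogram occurs this cycle.
#' @param multiplier risk-group incidence multiplier (>= 0).
#' @param params a `screen_params` object.
#' @return named probabilities: stages `I`-`IV`, `death`, `stay`.
#' @export
healthy_transitions <- function(age, screened, multiplier, params) {
  if (age < params$incidence$age_lo[1]) {
    stop("age ", age, " below the incidence table")
  }
  if (multiplier < 0) stop("multiplier must be >= 0")
  rate <- band_value(params$incidence, age) * multiplier *
    (if (screened) params$mammography_sensitivity else 1)
  p_cancer <- 1 - exp(-rate)
  dist <- if (screened) params$stage_dist_screened else params$stage_dist_unscreened
  p_stage <- p_cancer * dist
  p_death <- 1 - exp(-band_value(params$all_cause_mortality, age))
  if (p_cancer + p_death > 1) {
    stop("cancer and death probabilities exceed 1 at age ", age)
  }
  c(p_stage, death = p_death, stay = 1 - p_cancer - p_death)
}

#' Annual death probability in a cancer state
#'
#' The stage-specific breast-cancer mortality rate is scaled by the
#' age-adjustment factor and converted to a probability; when the
#' `cancer_allcause_mortality` option is on (default), all-cause mortality
#' competes independently (cause-specific survival probabilities multiply).
#'
#' @param stage one of `"I"`, `"II"`, `"III"`, `"IV"` (vectorised).
#' @param age integer age at cycle start.
#' @param params a `screen_params` object.
#' @return death probability (or vector, one per stage).
#' @export
cancer_death_prob <- function(stage, age, params) {
  r_bc <- params$stage_mortality$base_rate[stage] * age_factor(age, params)
  p_bc <- 1 - exp(-r_bc)
  if (isTRUE(params$options$cancer_allcause_mortality)) {
    p_ac <- 1 - exp(-band_value(params$all_cause_mortality, age))
    1 - (1 - p_bc) * (1 - p_ac)
  } else {
    p_bc
  }
}

#' Full one-cycle transition matrix
#'
#' Row-stochastic 10 x 10 matrix over [state_names()]: the healthy row from
#' [healthy_transitions()]; each first-year cancer state moves to the
#' matching later-year state with the stage's survival probability (no
#' transitions between stages, no remission); later-year states persist with
#' the same survival; death is absorbing.
#'
#' @inheritParams healthy_transitions
#' @return 10 x 10 matrix with rows and columns named by [state_names()].
#' @export
build_transition_matrix <- function(age, screened, multiplier, params) {
  sn <- state_names()
  m <- matrix(0, 10, 10, dimnames = list(sn, sn))
  ht <- healthy_transitions(age, screened, multiplier, params)
  m["healthy", "healthy"] <- ht[["stay"]]
  m["healthy", "death"] <- ht[["death"]]
  m["healthy", paste0("cancer_year1_", STAGES)] <- ht[STAGES]
  p_die <- cancer_death_prob(STAGES, age, params)
  for (i in seq_along(STAGES)) {
    y1 <- paste0("cancer_year1_", STAGES[i])
    lt <- paste0("cancer_later_", STAGES[i])
    m[y1, lt] <- 1 - p_die[i]
    m[y1, "death"] <- p_die[i]
    m[lt, lt] <- 1 - p_die[i]
    m[lt, "death"] <- p_die[i]
  }
  m["death", "death"] <- 1
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("non-stochastic transition row(s): ",
         paste(sn[abs(rs - 1) > 1e-12], collapse = ", "))
  }
  m
}

arm_screen_flags <- function(arm, params) {
  ages <- params$start_age + seq_len(params$horizon_years) - 1L
  if (is.null(arm$schedule)) rep(FALSE, length(ages))
  else ages %in% arm$schedule$screen_ages
}

#' Run the cohort trace for one strategy arm
#'
#' Deterministic Markov recursion: the whole cohort starts healthy at the
#' model start age, and the state-occupancy vector is propagated through the
#' age-specific transition matrix for each annual cycle. Occupancy is
#' recorded at the start of each cycle (row `t + 1` is cycle `t`, `t = 0`
#' at the start age); `new_cases[t + 1]` is the fraction of the cohort newly
#' transitioning from healthy to any cancer state during cycle `t`.
#'
#' @param arm a strategy arm (element of a `screen_strategy`'s `arms`).
#' @param params a `screen_params` object.
#' @return a `cohort_trace`: list with `occupancy`
#'   (`horizon_years + 1` x 10 matrix), `new_cases`, `ages`, `screened`,
#'   and `arm_label`.
#' @export
run_cohort <- function(arm, params) {
  h_years <- params$horizon_years
  ages <- params$start_age + 0:(h_years - 1)
  screened <- arm_screen_flags(arm, params)
  inc <- band_value(params$incidence, ages)
  acm <- band_value(params$all_cause_mortality, ages)
  af <- age_factor(ages, params)
  se <- params$mammography_sensitivity
  pi_s <- unname(params$stage_dist_screened[STAGES])
  pi_u <- unname(params$stage_dist_unscreened[STAGES])
  mu <- unname(params$stage_mortality$base_rate[STAGES])
  use_acm <- isTRUE(params$options$cancer_allcause_mortality)
  mult <- arm$multiplier

  occ <- matrix(0, h_years + 1, 10, dimnames = list(NULL, state_names()))
  new_cases <- numeric(h_years)
  h <- 1; c1 <- numeric(4); cl <- numeric(4); d <- 0
  occ[1, ] <- c(h, c1, cl, d)
  for (t in seq_len(h_years)) {
    rate <- inc[t] * mult * (if (screened[t]) se else 1)
    p_cancer <- 1 - exp(-rate)
    p_stage <- p_cancer * (if (screened[t]) pi_s else pi_u)
    p_death_h <- 1 - exp(-acm[t])
    p_bc <- 1 - exp(-mu * af[t])
    p_die_c <- if (use_acm) 1 - (1 - p_bc) * (1 - p_death_h) else p_bc
    new_cases[t] <- h * p_cancer
    new_c1 <- h * p_stage
    d <- d + h * p_death_h + sum((c1 + cl) * p_die_c)
    cl <- (c1 + cl) * (1 - p_die_c)
    c1 <- new_c1
    h <- h * (1 - p_cancer - p_death_h)
    occ[t + 1, ] <- c(h, c1, cl, d)
  }
  structure(list(occupancy = occ, new_cases = new_cases, ages = ages,
                 screened = screened, arm_label = arm$label),
            class = "cohort_trace")
}

#' Tidy export of a cohort trace
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @return data frame with columns cycle, age, state, occupancy, new_cases
#'   (new cancer cases attached to the healthy-state rows).
#' @export
trace_to_df <- function(trace) {
  n_cyc <- length(trace$ages)
  occ <- trace$occupancy[seq_len(n_cyc), , drop = FALSE]
  df <- data.frame(
    cycle = rep(seq_len(n_cyc) - 1L, times = ncol(occ)),
    age = rep(trace$ages, times = ncol(occ)),
    state = rep(colnames(occ), each = n_cyc),
    occupancy = as.vector(occ),
    new_cases = NA_real_
  )
  df$new_cases[df$state == "healthy"] <- trace$new_cases
  df
}

#' Accumulate discounted outcomes for one arm
#'
#' With discount factor `v = 1 / (1 + r)` and start-of-cycle accrual
#' (default), cycle `t` contributes weight `v^t` (`v^(t+1)` under the
#' `"end"` discount-timing option). Life years count the alive occupancy;
#' QALYs weight each state by its utility; costs sum the stage-specific
#' annual treatment costs over both tunnel phases, mammography for the
#' healthy occupancy in screened cycles, and the one-time testing cost for
#' the alive fraction at its age. Cumulative cancer cases are undiscounted.
#'
#' @param trace the `cohort_trace` produced by [run_cohort()] for `arm`.
#' @param arm the same strategy arm.
#' @param params a `screen_params` object.
#' @return an `outcomes` object: list with `cost`, `life_years`, `qalys`,
#'   `cases_per_woman`, `horizon_years`, `discount_rate`.
#' @export
accumulate_outcomes <- function(trace, arm, params) {
  if (!identical(trace$arm_label, arm$label) ||
      !identical(trace$screened, arm_screen_flags(arm, params))) {
    stop("trace does not match arm '", arm$label, "'")
  }
  n_cyc <- length(trace$ages)
  occ <- trace$occupancy[seq_len(n_cyc), , drop = FALSE]
  r <- params$discount_rate
  expo <- if (identical(params$options$discount_timing, "end")) 1 else 0
  w <- (1 / (1 + r))^(seq_len(n_cyc) - 1 + expo)

  alive <- 1 - occ[, "death"]
  u <- c(params$utilities$healthy,
         params$utilities$by_stage_year1[STAGES],
         params$utilities$by_stage_later[STAGES],
         params$utilities$death)
  qaly_t <- occ %*% u

  cs <- params$costs$stage_annual[STAGES]
  treat <- occ[, paste0("cancer_year1_", STAGES), drop = FALSE] %*% cs +
    occ[, paste0("cancer_later_", STAGES), drop = FALSE] %*% cs
  mammo <- occ[, "healthy"] * params$costs$mammography * trace$screened
  one_time <- numeric(n_cyc)
  if (!is.na(arm$one_time_cost_age) && arm$one_time_cost > 0) {
    idx <- match(arm$one_time_cost_age, trace$ages)
    if (!is.na(idx)) one_time[idx] <- arm$one_time_cost * alive[idx]
  }
  structure(list(
    cost = sum(w * (treat + mammo + one_time)),
    life_years = sum(w * alive),
    qalys = sum(w * qaly_t),
    cases_per_woman = sum(trace$new_cases),
    horizon_years = n_cyc,
    discount_rate = r
  ), class = "outcomes")
}

#' @export
print.outcomes <- function(x, ...) {
  cat(sprintf(paste0("<outcomes> cost US$%.2f, LY %.4f, QALY %.4f, ",
                     "cases/1000 %.2f (r = %.0f%%, %d cycles)\n"),
              x$cost, x$life_years, x$qalys, 1000 * x$cases_per_woman,
              100 * x$discount_rate, x$horizon_years))
  invisible(x)
}

#' Evaluate a screening strategy
#'
#' Runs the cohort model for every arm and returns the weight-averaged
#' outcomes (the mixture is linear in arm weights).
#'
#' @param strategy a `screen_strategy`.
#' @param params a `screen_params` object.
#' @return an `outcomes` object.
#' @export
evaluate_strategy <- function(strategy, params) {
  w <- vapply(strategy$arms, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) {
    stop("strategy '", strategy$name, "': arm weights must sum to 1")
  }
  acc <- c(cost = 0, life_years = 0, qalys = 0, cases_per_woman = 0)
  for (i in seq_along(strategy$arms)) {
    arm <- strategy$arms[[i]]
    o <- accumulate_outcomes(run_cohort(arm, params), arm, params)
    acc <- acc + w[i] * c(o$cost, o$life_years, o$qalys, o$cases_per_woman)
  }
  structure(list(cost = acc[["cost"]], life_years = acc[["life_years"]],
                 qalys = acc[["qalys"]],
                 cases_per_woman = acc[["cases_per_woman"]],
                 horizon_years = params$horizon_years,
                 discount_rate = params$discount_rate),
            class = "outcomes")
}
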