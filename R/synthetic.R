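# Synthetic parameter sets for property testing, plus an individual-level
# microsimulation that serves as an independent oracle for the cohort engine.

#' Generate a random, valid parameter set
#'
#' Produces a structurally realistic parameter set: a smooth log-linear
#' age-increasing incidence curve, Gompertz-like all-cause mortality,
#' simplex-valued stage distributions with the unscreened mix stochastically
#' later-stage than the screened one (stage III+IV share at least as large),
#' stage-increasing mortality and costs, utilities ordered healthy >=
#' later-year >= first-year and non-increasing in stage, and PSA
#' distributions re-derived from the generated base values. Every generated
#' set passes [validate_parameters()] with zero violations.
#'
#' @param seed RNG seed; the same seed reproduces the same set.
#' @param incidence_scale baseline annual incidence at the start age (drawn
#'   in `(2e-4, 2e-3)` when `NULL`).
#' @param incidence_trend log-linear slope per year of age (drawn in
#'   `(0, 0.04)` when `NULL`).
#' @param stage_concentration Dirichlet concentration for the stage mixes.
#' @param multiplier_spread width multiplier for the gap between risk-group
#'   multipliers.
#' @return a `screen_params` object.
#' @export
generate_params <- function(seed, incidence_scale = NULL,
                            incidence_trend = NULL,
                            stage_concentration = c(4, 4, 2, 1),
                            multiplier_spread = 1) {
  set.seed(seed)
  p <- default_parameters()
  mid <- p$incidence$age_lo + 2
  a0 <- if (is.null(incidence_scale)) stats::runif(1, 2e-4, 2e-3) else incidence_scale
  slope <- if (is.null(incidence_trend)) stats::runif(1, 0, 0.04) else incidence_trend
  p$incidence$value <- pmin(0.049, a0 * exp(slope * (mid - mid[1])))
  q0 <- stats::runif(1, 2e-4, 1e-3)
  g <- stats::runif(1, 0.05, 0.09)
  p$all_cause_mortality$value <- pmin(0.4, q0 * exp(g * (mid - mid[1])))

  rdirichlet1 <- function(alpha) {
    x <- stats::rgamma(length(alpha), shape = alpha)
    x / sum(x)
  }
  s1 <- rdirichlet1(stage_concentration)
  s2 <- rdirichlet1(stage_concentration)
  late1 <- sum(s1[3:4]); late2 <- sum(s2[3:4])
  scr <- if (late1 <= late2) s1 else s2
  uns <- if (late1 <= late2) s2 else s1
  p$stage_dist_screened <- stats::setNames(scr, STAGES)
  p$stage_dist_unscreened <- stats::setNames(uns, STAGES)

  p$stage_mortality$base_rate <- stats::setNames(
    sort(stats::runif(4, 0.002, 0.3)), STAGES)
  p$stage_mortality$age_factors$factor <- c(stats::runif(1, 0.1, 1), 1,
                                            stats::runif(1, 1, 2.5))

  p$mammography_sensitivity <- stats::runif(1, 0.5, 0.98)
  p$costs$stage_annual <- stats::setNames(sort(stats::runif(4, 500, 20000)), STAGES)
  p$costs$mammography <- stats::runif(1, 10, 100)
  p$costs$snp_genotyping <- stats::runif(1, 50, 500)
  p$costs$genetic_counseling <- stats::runif(1, 10, 200)

  u_later <- sort(stats::runif(4, 0.5, 0.99), decreasing = TRUE)
  u_year1 <- u_later * stats::runif(1, 0.6, 0.95)
  p$utilities$by_stage_later <- stats::setNames(u_later, STAGES)
  p$utilities$by_stage_year1 <- stats::setNames(u_year1, STAGES)

  props <- rdirichlet1(c(4, 6, 1))
  gap <- multiplier_spread
  p$risk_groups$proportion <- props
  p$risk_groups$multiplier <- c(
    max(0.05, 1 - gap * stats::runif(1, 0.05, 0.7)),
    stats::runif(1, 0.9, 1.2),
    1 + gap * stats::runif(1, 0.2, 2)
  )
  p$discount_rate <- stats::runif(1, 0, 0.07)

  # PSA specs re-derived so they stay consistent with the generated bases
  specs <- p$psa
  for (i in seq_len(nrow(specs))) {
    id <- specs$parameter[i]
    base <- if (grepl("^cost_stage_", id)) {
      p$costs$stage_annual[[sub("cost_stage_", "", id)]]
    } else if (id == "cost_mammography") p$costs$mammography
    else if (id == "cost_snp_genotyping") p$costs$snp_genotyping
    else if (id == "cost_genetic_counseling") p$costs$genetic_counseling
    else if (id == "mammography_sensitivity") p$mammography_sensitivity
    else if (grepl("^multiplier_", id)) {
      p$risk_groups$multiplier[p$risk_groups$name == sub("multiplier_", "", id)]
    } else {
      phase <- if (grepl("^util_year1_", id)) "by_stage_year1" else "by_stage_later"
      p$utilities[[phase]][[sub("util_(year1|later)_", "", id)]]
    }
    hw <- if (grepl("^cost_", id)) 0.3 * base
      else if (grepl("^util_", id)) min(0.05, 0.5 * base * (1 - base))
      else if (id == "mammography_sensitivity") min(0.05, 0.5 * base * (1 - base))
      else 0.2 * base
    d <- derive_distribution_from_range(base, hw, specs$family[i])
    specs$a[i] <- d$a
    specs$b[i] <- if (d$family == "point") 1e-12 else d$b
  }
  p$psa <- specs
  p$sa_ranges <- default_sa_ranges(p)
  p
}

#' Individual-level microsimulation of one strategy arm
#'
#' Simulates `n_individuals` women through exactly the per-cycle transition
#' probabilities of [build_transition_matrix()] (one categorical draw per
#' woman per cycle, no event-time sub-cycling), so its expected state
#' frequencies equal the cohort trace of [run_cohort()]. Used as the
#' independent oracle for the deterministic engine.
#'
#' @param arm a strategy arm.
#' @param params a `screen_params` object.
#' @param n_individuals number of simulated women.
#' @param seed RNG seed.
#' @return a `microsim_result`: list with `n_individuals`, `counts`
#'   (`horizon_years + 1` x 10 state counts at cycle start), `cases`
#'   (diagnosed fraction), `outcomes` (mean discounted cost, life years,
#'   QALYs per woman), and `event_log` (data frame: id, diagnosis_age,
#'   stage, death_age, cause).
#' @export
microsimulate <- function(arm, params, n_individuals, seed = NULL) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_individuals)
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
  u_y1 <- unname(params$utilities$by_stage_year1[STAGES])
  u_lt <- unname(params$utilities$by_stage_later[STAGES])
  cs <- unname(params$costs$stage_annual[STAGES])
  r <- params$discount_rate
  expo <- if (identical(params$options$discount_timing, "end")) 1 else 0

  st <- rep(1L, n)  # 1 healthy, 2-5 year-1 by stage, 6-9 later, 10 death
  diag_age <- rep(NA_real_, n); diag_stage <- rep(NA_integer_, n)
  death_age <- rep(NA_real_, n); death_cause <- rep(NA_character_, n)
  counts <- matrix(0L, h_years + 1, 10, dimnames = list(NULL, state_names()))
  counts[1, ] <- tabulate(st, 10)
  cost_sum <- ly_sum <- qaly_sum <- 0

  for (t in seq_len(h_years)) {
    w <- (1 / (1 + r))^(t - 1 + expo)
    ct <- counts[t, ]
    alive_n <- n - ct[10]
    ly_sum <- ly_sum + w * alive_n
    qaly_sum <- qaly_sum + w * (ct[1] + sum(ct[2:5] * u_y1) + sum(ct[6:9] * u_lt))
    cost_t <- sum((ct[2:5] + ct[6:9]) * cs) +
      (if (screened[t]) ct[1] * params$costs$mammography else 0) +
      (if (!is.na(arm$one_time_cost_age) && ages[t] == arm$one_time_cost_age)
        arm$one_time_cost * alive_n else 0)
    cost_sum <- cost_sum + w * cost_t

    rate <- inc[t] * arm$multiplier * (if (screened[t]) se else 1)
    p_cancer <- 1 - exp(-rate)
    pst <- p_cancer * (if (screened[t]) pi_s else pi_u)
    p_death_h <- 1 - exp(-acm[t])
    p_bc <- 1 - exp(-mu * af[t])
    p_die_c <- if (use_acm) 1 - (1 - p_bc) * (1 - p_death_h) else p_bc

    hi <- which(st == 1L)
    ci <- which(st >= 2L & st <= 9L)  # before this cycle's new diagnoses
    if (length(hi) > 0) {
      u <- stats::runif(length(hi))
      cuts <- cumsum(c(pst, p_death_h))
      k <- findInterval(u, cuts) + 1L  # 1-4 stage, 5 death, 6 stay
      newly <- hi[k <= 4L]
      if (length(newly) > 0) {
        stg <- k[k <= 4L]
        st[newly] <- 1L + stg
        diag_age[newly] <- ages[t]
        diag_stage[newly] <- stg
      }
      died <- hi[k == 5L]
      if (length(died) > 0) {
        st[died] <- 10L
        death_age[died] <- ages[t]
        death_cause[died] <- "other"
      }
    }
    if (length(ci) > 0) {
      stg <- (st[ci] - 2L) %% 4L + 1L
      u <- stats::runif(length(ci))
      dies <- u < p_die_c[stg]
      dead_ids <- ci[dies]
      st[dead_ids] <- 10L
      death_age[dead_ids] <- ages[t]
      death_cause[dead_ids] <- "cancer_or_other"
      surv <- ci[!dies]
      st[surv] <- ifelse(st[surv] <= 5L, st[surv] + 4L, st[surv])
    }
    counts[t + 1, ] <- tabulate(st, 10)
  }
  structure(list(
    n_individuals = n,
    counts = counts,
    cases = sum(!is.na(diag_age)) / n,
    outcomes = list(cost = cost_sum / n, life_years = ly_sum / n,
                    qalys = qaly_sum / n),
    event_log = data.frame(id = seq_len(n), diagnosis_age = diag_age,
                           stage = ifelse(is.na(diag_stage), NA_character_,
                                          STAGES[diag_stage]),
                           death_age = death_age, cause = death_cause),
    seed = seed
  ), class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> n = %d, diagnosed %.2f/1000, mean cost US$%.2f, LY %.4f, QALY %.4f\n",
              x$n_individuals, 1000 * x$cases, x$outcomes$cost,
              x$outcomes$life_years, x$outcomes$qalys))
  invisible(x)
}
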