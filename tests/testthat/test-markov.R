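test_that("healthy-state transitions follow rate x multiplier x stage mix x sensitivity", {
  p <- default_parameters()
  # screened cycle at 47: rate = 0.002383 * 0.835
  ht <- healthy_transitions(47, TRUE, 1.0, p)
  expect_equal(unname(ht["I"]), (1 - exp(-0.002383 * 0.835)) * 0.49)
  expect_equal(unname(ht["I"]), 9.745e-4, tolerance = 1e-3)
  expect_equal(unname(ht["death"]), 1 - exp(-0.001409))
  expect_equal(sum(ht), 1)
  # unscreened cycle at 36 with the low-risk multiplier
  ht2 <- healthy_transitions(36, FALSE, 0.6, p)
  expect_equal(unname(ht2["IV"]), (1 - exp(-0.000744 * 0.6)) * 0.08)
  expect_equal(unname(ht2["IV"]), 3.571e-5, tolerance = 1e-3)
  # zero multiplier: no cancer, stay = 1 - death
  ht0 <- healthy_transitions(50, TRUE, 0, p)
  expect_equal(unname(ht0[c("I", "II", "III", "IV")]), rep(0, 4))
  expect_equal(unname(ht0["stay"]), 1 - unname(ht0["death"]))
  expect_error(healthy_transitions(20, FALSE, 1, p), "below")
  expect_error(healthy_transitions(50, FALSE, -1, p), "multiplier")
})

test_that("cancer death probability combines stage rate, age factor and background mortality", {
  p <- default_parameters()
  p$options$cancer_allcause_mortality <- FALSE
  expect_equal(unname(cancer_death_prob("IV", 50, p)), 1 - exp(-0.167 * 1.000))
  expect_equal(unname(cancer_death_prob("I", 40, p)), 1 - exp(-0.004 * 0.151))
  expect_equal(unname(cancer_death_prob("III", 70, p)), 1 - exp(-0.025 * 1.739))
  # with competing background mortality, cause-specific survivals multiply
  q <- default_parameters()
  p_bc <- 1 - exp(-0.167)
  p_ac <- 1 - exp(-0.002008)  # all-cause band 50-54
  expect_equal(unname(cancer_death_prob("IV", 50, q)),
               1 - (1 - p_bc) * (1 - p_ac))
})

test_that("transition matrices are row-stochastic with absorbing death and no remission", {
  p <- default_parameters()
  for (age in c(35, 47, 64, 70, 84)) {
    for (scr in c(TRUE, FALSE)) {
      m <- build_transition_matrix(age, scr, 1.1, p)
      expect_equal(unname(rowSums(m)), rep(1, 10))
      expect_equal(unname(m["death", ]), c(rep(0, 9), 1))
      # year-1 states can only move to their own later state or death
      for (s in c("I", "II", "III", "IV")) {
        row <- m[paste0("cancer_year1_", s), ]
        nz <- names(row)[row > 0]
        expect_true(all(nz %in% c(paste0("cancer_later_", s), "death")))
      }
      expect_equal(unname(m["cancer_later_II", "cancer_later_II"]),
                   1 - unname(cancer_death_prob("II", age, p)))
    }
  }
  # no-event limit: nobody moves except through the year-1 tunnel, which
  # always empties into the matching later-year state
  m0 <- build_transition_matrix(50, FALSE, 0, no_event_params())
  expect_equal(unname(m0["healthy", ]), c(1, rep(0, 9)))
  expect_equal(unname(m0["death", ]), c(rep(0, 9), 1))
  for (s in c("I", "II", "III", "IV")) {
    expect_equal(unname(m0[paste0("cancer_year1_", s), paste0("cancer_later_", s)]), 1)
    expect_equal(unname(m0[paste0("cancer_later_", s), paste0("cancer_later_", s)]), 1)
  }
})

test_that("the cohort recursion agrees with explicit transition-matrix propagation", {
  p <- default_parameters()
  arm <- prs_strategy(p)$arms[[3]]  # high-risk: screens from 35, multiplier 1.5
  trace <- run_cohort(arm, p)
  occ <- c(1, rep(0, 9))
  for (t in seq_len(p$horizon_years)) {
    m <- build_transition_matrix(trace$ages[t], trace$screened[t],
                                 arm$multiplier, p)
    occ <- as.vector(occ %*% m)
    expect_equal(unname(trace$occupancy[t + 1, ]), occ, tolerance = 1e-12)
  }
})

test_that("traces conserve mass and death occupancy never decreases", {
  p <- default_parameters()
  for (arm in c(prs_strategy(p)$arms, age_based_strategy(p)$arms)) {
    tr <- run_cohort(arm, p)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
    expect_true(all(tr$occupancy >= -1e-15))
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-15))
    expect_true(all(diff(tr$occupancy[, "healthy"]) <= 1e-15))
  }
})

test_that("a no-event cohort stays healthy and earns the discounted annuity", {
  p <- no_event_params(0.03)
  arm <- age_based_strategy(p)$arms[[1]]
  tr <- run_cohort(arm, p)
  expect_equal(unname(tr$occupancy[, "healthy"]), rep(1, 51))
  o <- accumulate_outcomes(tr, arm, p)
  v <- 1 / 1.03
  expect_equal(o$life_years, (1 - v^50) / (1 - v))  # 26.502
  expect_equal(o$life_years, 26.502, tolerance = 1e-4)
  expect_equal(o$qalys, o$life_years)
  expect_equal(o$cases_per_woman, 0)
  p0 <- no_event_params(0)
  o0 <- accumulate_outcomes(run_cohort(arm, p0), arm, p0)
  expect_equal(o0$life_years, 50)
  # end-of-cycle discounting shifts every weight by one year
  pe <- no_event_params(0.03)
  pe$options$discount_timing <- "end"
  oe <- accumulate_outcomes(run_cohort(arm, pe), arm, pe)
  expect_equal(oe$life_years, v * o$life_years)
})

test_that("QALYs equal life years under unit utilities and never exceed them", {
  p <- default_parameters()
  arm <- age_based_strategy(p)$arms[[1]]
  o <- accumulate_outcomes(run_cohort(arm, p), arm, p)
  expect_lte(o$qalys, o$life_years)
  p1 <- default_parameters()
  p1$utilities$by_stage_year1[] <- 1
  p1$utilities$by_stage_later[] <- 1
  o1 <- accumulate_outcomes(run_cohort(arm, p1), arm, p1)
  expect_equal(o1$qalys, o1$life_years)
})

test_that("accumulation rejects a trace from a different arm", {
  p <- default_parameters()
  s <- prs_strategy(p)
  tr_high <- run_cohort(s$arms[[3]], p)
  expect_error(accumulate_outcomes(tr_high, s$arms[[2]], p), "does not match")
})

test_that("strategy evaluation is the weight-linear mixture of its arms", {
  p <- default_parameters()
  s <- prs_strategy(p)
  whole <- evaluate_strategy(s, p)
  parts <- lapply(s$arms, function(a) accumulate_outcomes(run_cohort(a, p), a, p))
  w <- vapply(s$arms, `[[`, numeric(1), "weight")
  for (field in c("cost", "life_years", "qalys", "cases_per_woman")) {
    expect_equal(whole[[field]],
                 sum(w * vapply(parts, `[[`, numeric(1), field)))
  }
  # a single-arm strategy reproduces its arm exactly
  ab <- age_based_strategy(p)
  arm <- ab$arms[[1]]
  expect_equal(evaluate_strategy(ab, p)$cost,
               accumulate_outcomes(run_cohort(arm, p), arm, p)$cost)
  # duplicating an arm at half weight changes nothing
  dup <- ab
  dup$arms <- list(arm, arm)
  dup$arms[[1]]$weight <- 0.5
  dup$arms[[2]]$weight <- 0.5
  expect_equal(evaluate_strategy(dup, p)$qalys, evaluate_strategy(ab, p)$qalys)
})

test_that("cases rise and life years fall with incidence; discounting shrinks all outcomes", {
  p <- default_parameters()
  s_base <- prs_strategy(p)
  o_base <- evaluate_strategy(s_base, p)
  p_hi <- p
  p_hi$risk_groups$multiplier <- p$risk_groups$multiplier * 1.5
  o_hi <- evaluate_strategy(prs_strategy(p_hi), p_hi)
  expect_gt(o_hi$cases_per_woman, o_base$cases_per_woman)
  expect_lt(o_hi$life_years, o_base$life_years)
  p_disc <- p
  p_disc$discount_rate <- 0.05
  o_disc <- evaluate_strategy(s_base, p_disc)
  expect_lt(o_disc$life_years, o_base$life_years)
  expect_lt(o_disc$qalys, o_base$qalys)
  expect_lt(o_disc$cost, o_base$cost)
})

test_that("the tidy trace export matches the occupancy matrix", {
  p <- default_parameters()
  arm <- age_based_strategy(p)$arms[[1]]
  tr <- run_cohort(arm, p)
  df <- trace_to_df(tr)
  expect_equal(nrow(df), 50 * 10)
  expect_equal(df$occupancy[df$state == "healthy"],
               unname(tr$occupancy[1:50, "healthy"]))
  expect_equal(df$new_cases[df$state == "healthy"], tr$new_cases)
  expect_true(all(is.na(df$new_cases[df$state != "healthy"])))
})
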