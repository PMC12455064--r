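# Shared fixtures, built in code.

# Parameter set with no cancer incidence and no background mortality:
# the cohort stays healthy forever, giving closed-form outcomes.
no_event_params <- function(discount_rate = 0.03) {
  p <- default_parameters()
  p$incidence$value[] <- 0
  p$all_cause_mortality$value[] <- 0
  p$stage_mortality$base_rate[] <- 0
  p$discount_rate <- discount_rate
  p
}

# Degenerate (point-mass) PSA specs at the base-case values, for tests that
# need zero parameter uncertainty.
point_mass_psa <- function(p) {
  specs <- p$psa
  base <- c(p$costs$stage_annual, p$costs$mammography, p$costs$snp_genotyping,
            p$costs$genetic_counseling, p$utilities$by_stage_year1,
            p$utilities$by_stage_later,
            setNames(p$risk_groups$multiplier, p$risk_groups$name)[
              c("high", "intermediate", "low")],
            p$mammography_sensitivity)
  specs$family <- "point"
  specs$a <- unname(base)
  specs$b <- 0
  p$psa <- specs
  p
}

first_arm <- function(strategy) strategy$arms[[1]]
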