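STAGES <- c("I", "II", "III", "IV")

#' Default model parameters
#'
#' Returns the complete parameter set of the base-case model: age-specific
#' invasive breast-cancer incidence and all-cause mortality (excluding breast
#' cancer) for 5-year bands from 35-39 to 80-84, stage distributions at
#' diagnosis for screen-detected and clinically detected cases, stage-specific
#' annual breast-cancer mortality with age-adjustment factors, mammography
#' sensitivity, risk-group proportions and incidence multipliers, costs
#' (2021 US$), tunnel-state utilities, the 3% annual discount rate, and the
#' probabilistic-sensitivity-analysis distribution specifications.
#'
#' All monetary values are 2021 US$ (converted at 27.69 NTD/US$; no currency
#' adjustment is performed by the package).
#'
#' The `options` element collects structural switches that the model leaves
#' open:
#' \describe{
#'   \item{discount_timing}{`"start"` (default) accrues costs and outcomes at
#'     cycle start with discount exponent t (t = 0 at the start age);
#'     `"end"` uses exponent t + 1.}
#'   \item{cancer_allcause_mortality}{if `TRUE` (default), women in cancer
#'     states face all-cause mortality in addition to stage-specific
#'     breast-cancer mortality, with independent cause-specific survivals
#'     multiplied.}
#'   \item{psa_source}{`"printed"` (default) samples PSA draws from the
#'     distribution parameters as specified; `"range"` re-derives each
#'     distribution from the base value and its one-way range by method of
#'     moments (see [derive_distribution_from_range()]).}
#' }
#'
#' @return An object of class `screen_params` (a named list).
#' @examples
#' p <- default_parameters()
#' band_value(p$incidence, 47)   # annual incidence at age 47
#' validate_parameters(p)        # character(0): defaults are valid
#' @export
default_parameters <- function() {
  age_lo <- seq(35, 80, by = 5)
  age_hi <- age_lo + 4
  p <- list(
    incidence = data.frame(
      age_lo = age_lo, age_hi = age_hi,
      value = c(0.000744, 0.001513, 0.002383, 0.002232, 0.002141,
                0.002262, 0.002298, 0.001974, 0.001666, 0.001620)
    ),
    all_cause_mortality = data.frame(
      age_lo = age_lo, age_hi = age_hi,
      value = c(0.000590, 0.000910, 0.001409, 0.002008, 0.002856,
                0.004460, 0.006986, 0.012718, 0.024427, 0.046523)
    ),
    stage_dist_screened   = c(I = 0.49, II = 0.36, III = 0.13, IV = 0.02),
    stage_dist_unscreened = c(I = 0.35, II = 0.39, III = 0.18, IV = 0.08),
    stage_mortality = list(
      base_rate = c(I = 0.004, II = 0.006, III = 0.025, IV = 0.167),
      age_factors = data.frame(
        age_lo = c(35, 45, 65), age_hi = c(44, 64, 200),
        factor = c(0.151, 1.000, 1.739)
      )
    ),
    mammography_sensitivity = 0.835,
    costs = list(
      stage_annual = c(I = 2444.00, II = 3039.56, III = 4678.02, IV = 13396.20),
      mammography = 44.96,
      snp_genotyping = 126.40,
      genetic_counseling = 54.17
    ),
    utilities = list(
      healthy = 1.0,
      by_stage_year1 = c(I = 0.85, II = 0.85, III = 0.70, IV = 0.52),
      by_stage_later = c(I = 0.95, II = 0.95, III = 0.85, IV = 0.60),
      death = 0.0
    ),
    risk_groups = data.frame(
      name = c("low", "intermediate", "high"),
      proportion = c(0.35, 0.60, 0.05),
      multiplier = c(0.6, 1.1, 1.5)
    ),
    discount_rate = 0.03,
    start_age = 35L,
    horizon_years = 50L,
    cycle_length = 1L,
    psa = default_psa_distributions(),
    sa_ranges = NULL,  # filled below, needs the base values
    options = list(
      discount_timing = "start",
      cancer_allcause_mortality = TRUE,
      psa_source = "printed"
    )
  )
  p$sa_ranges <- default_sa_ranges(p)
  class(p) <- "screen_params"
  p
}

# One-way sensitivity ranges: where the parameter table prints an explicit
# min/max (costs: +-30%; utilities: +-0.1 capped at 1.0) those bounds are
# used; for the multipliers and mammography sensitivity, which print no
# min/max, the stated +-20% rule applies (sensitivity capped at 1.0).
default_sa_ranges <- function(p) {
  rg <- p$risk_groups
  mult <- stats::setNames(rg$multiplier, rg$name)
  data.frame(
    parameter = c("multiplier_intermediate", "multiplier_low", "multiplier_high",
                  "mammography_sensitivity", "stage_costs",
                  "snp_genotyping_cost", "genetic_counseling_cost",
                  "stage_utilities"),
    low  = c(0.8 * mult[["intermediate"]], 0.8 * mult[["low"]], 0.8 * mult[["high"]],
             0.8 * p$mammography_sensitivity, 0.7, 0.7 * p$costs$snp_genotyping,
             0.7 * p$costs$genetic_counseling, -0.1),
    high = c(1.2 * mult[["intermediate"]], 1.2 * mult[["low"]], 1.2 * mult[["high"]],
             min(1, 1.2 * p$mammography_sensitivity), 1.3,
             1.3 * p$costs$snp_genotyping, 1.3 * p$costs$genetic_counseling, 0.1)
  )
}

# PSA distribution specifications. Gamma "b" is a SCALE parameter: only the
# scale reading reproduces the base-case means (42.7 * 57.3 = 2446.7 ~ 2444).
default_psa_distributions <- function() {
  rbind(
    data.frame(parameter = paste0("cost_stage_", STAGES), family = "gamma",
               a = 42.7, b = c(57.3, 71.2, 109.6, 313.9)),
    data.frame(parameter = "cost_mammography", family = "gamma", a = 42.7, b = 1.1),
    data.frame(parameter = "cost_snp_genotyping", family = "gamma", a = 42.7, b = 3.0),
    data.frame(parameter = "cost_genetic_counseling", family = "gamma", a = 42.7, b = 1.3),
    data.frame(parameter = paste0("util_year1_", STAGES), family = "beta",
               a = c(40.8, 40.8, 55.8, 49.3), b = c(8.2, 8.2, 24.9, 46.5)),
    data.frame(parameter = paste0("util_later_", STAGES), family = "beta",
               a = c(29.9, 29.9, 40.8, 54.7), b = c(2.6, 2.6, 8.2, 37.5)),
    data.frame(parameter = paste0("multiplier_", c("high", "intermediate", "low")),
               family = "normal", a = c(1.5, 1.1, 0.6), b = c(0.23, 0.17, 0.09)),
    data.frame(parameter = "mammography_sensitivity", family = "beta",
               a = 27.3, b = 6.4)
  )
}

#' Look up an age-band table
#'
#' Age-band tables (incidence, all-cause mortality) are data frames with
#' columns `age_lo`, `age_hi`, `value`; intervals are closed and membership
#' uses the integer age at the start of the cycle. Ages beyond the last band
#' clamp to the nearest band.
#'
#' @param table age-band data frame.
#' @param age age in years (vectorised).
#' @return numeric value(s) for the band containing each age.
#' @export
band_value <- function(table, age) {
  age <- floor(age)
  idx <- findInterval(age, table$age_lo)
  idx[idx < 1L] <- 1L
  out <- table$value[idx]
  out
}

#' Age-adjustment factor for stage-specific breast-cancer mortality
#'
#' Stage-specific mortality rates are aggregated over all ages and taken to
#' represent ages 45-64 (factor 1.000); rates at other ages are scaled by the
#' ratio of the age group's crude breast-cancer mortality to the reference
#' group's (0.151 for ages 35-44, 1.739 for ages >= 65).
#'
#' @param age age in years (vectorised).
#' @param stage_mortality a `stage_mortality` list with an `age_factors`
#'   table, or a full `screen_params` object.
#' @return the multiplier of the interval containing `age`.
#' @examples
#' age_factor(40, default_parameters())  # 0.151
#' age_factor(70, default_parameters())  # 1.739
#' @export
age_factor <- function(age, stage_mortality) {
  if (inherits(stage_mortality, "screen_params")) {
    stage_mortality <- stage_mortality$stage_mortality
  }
  af <- stage_mortality$age_factors
  idx <- findInterval(floor(age), af$age_lo)
  idx[idx < 1L] <- 1L
  af$factor[idx]
}

#' Derive age-adjustment factors from crude mortality rates
#'
#' Each factor is the interval's crude rate divided by the reference
#' interval's rate (e.g. crude breast-cancer deaths per 100,000 of 5.5 /
#' 36.4 / 63.3 for ages 35-44 / 45-64 / >= 65 give factors 0.151 / 1.000 /
#' 1.739 with reference 45-64).
#'
#' @param crude_rates named numeric vector of crude rates per interval.
#' @param reference name of the reference interval.
#' @return named numeric vector of multipliers; reference maps to 1.
#' @examples
#' derive_age_factors(c("35-44" = 5.5, "45-64" = 36.4, ">=65" = 63.3), "45-64")
#' @export
derive_age_factors <- function(crude_rates, reference) {
  if (!reference %in% names(crude_rates)) {
    stop("reference interval '", reference, "' not present in crude_rates")
  }
  ref <- crude_rates[[reference]]
  if (!is.finite(ref) || ref <= 0) {
    stop("reference interval '", reference, "' must have a positive rate")
  }
  crude_rates / ref
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model parameters and reports
#' violations as a character vector (empty when the set is valid). Validation
#' reports; it never throws.
#'
#' @param params a `screen_params` object.
#' @return character vector of violation descriptions, each naming the field
#'   and the failed rule.
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)

  check_band_table <- function(tab, name, max_value = 1) {
    if (!is.data.frame(tab) || !all(c("age_lo", "age_hi", "value") %in% names(tab))) {
      add(sprintf("%s: must be a data frame with age_lo, age_hi, value", name))
      return(invisible(NULL))
    }
    if (any(tab$age_hi < tab$age_lo)) {
      add(sprintf("%s: bands must satisfy age_lo <= age_hi", name))
    }
    if (nrow(tab) > 1) {
      if (any(diff(tab$age_lo) <= 0)) {
        add(sprintf("%s: bands must be strictly increasing", name))
      }
      if (any(tab$age_lo[-1] != tab$age_hi[-nrow(tab)] + 1)) {
        add(sprintf("%s: bands must be contiguous and non-overlapping", name))
      }
    }
    if (any(tab$value < 0)) add(sprintf("%s: values must be >= 0", name))
    if (any(tab$value >= max_value)) {
      add(sprintf("%s: values must be < %s", name, max_value))
    }
    lo <- params$start_age
    hi <- params$start_age + params$horizon_years - 1
    if (length(lo) == 1 && length(hi) == 1 && nrow(tab) > 0 &&
        (tab$age_lo[1] > lo || tab$age_hi[nrow(tab)] < hi)) {
      add(sprintf("%s: bands must cover model ages %d-%d", name, lo, hi))
    }
  }
  check_band_table(params$incidence, "incidence")
  check_band_table(params$all_cause_mortality, "all_cause_mortality")

  check_simplex <- function(x, name) {
    if (!all(STAGES %in% names(x))) {
      add(sprintf("%s: must name stages I-IV", name))
      return(invisible(NULL))
    }
    if (any(x < 0 | x > 1)) add(sprintf("%s: proportions must be in [0, 1]", name))
    if (abs(sum(x) - 1) > 1e-9) {
      add(sprintf("%s: stage proportions must sum to 1 (simplex rule); got %.6f",
                  name, sum(x)))
    }
  }
  check_simplex(params$stage_dist_screened, "stage_dist_screened")
  check_simplex(params$stage_dist_unscreened, "stage_dist_unscreened")

  sm <- params$stage_mortality
  if (any(sm$base_rate < 0 | sm$base_rate >= 1)) {
    add("stage_mortality$base_rate: rates must be in [0, 1)")
  }
  if (any(sm$age_factors$factor <= 0)) {
    add("stage_mortality$age_factors: factors must be > 0")
  }
  if (!any(abs(sm$age_factors$factor - 1) < 1e-12)) {
    add("stage_mortality$age_factors: the reference interval must have factor 1.0")
  }

  se <- params$mammography_sensitivity
  if (!(se > 0 && se <= 1)) {
    add("mammography_sensitivity: must satisfy 0 < sensitivity <= 1")
  }

  cu <- unlist(params$costs)
  if (any(cu < 0)) add("costs: all cost entries must be >= 0")

  ut <- params$utilities
  uw <- c(ut$healthy, ut$by_stage_year1, ut$by_stage_later, ut$death)
  if (any(uw < 0 | uw > 1)) add("utilities: every weight must be in [0, 1]")
  if (!isTRUE(all.equal(ut$healthy, 1.0))) add("utilities$healthy: must equal 1.0")
  if (!isTRUE(all.equal(ut$death, 0.0))) add("utilities$death: must equal 0.0")

  rg <- params$risk_groups
  if (abs(sum(rg$proportion) - 1) > 1e-9) {
    add("risk_groups: proportions must sum to 1")
  }
  if (any(rg$proportion < 0 | rg$proportion > 1)) {
    add("risk_groups: proportions must be in [0, 1]")
  }
  if (any(rg$multiplier <= 0)) add("risk_groups: multipliers must be > 0")

  r <- params$discount_rate
  if (!(r >= 0 && r < 1)) add("discount_rate: must be in [0, 1)")
  if (params$horizon_years < 1) add("horizon_years: must be >= 1")

  if (!is.null(params$psa)) {
    bad <- params$psa$b <= 0 | (params$psa$family != "normal" & params$psa$a <= 0)
    if (any(bad)) {
      add(paste0("psa: non-positive distribution parameters for ",
                 paste(params$psa$parameter[bad], collapse = ", ")))
    }
  }
  v
}

#' @export
print.screen_params <- function(x, ...) {
  cat("<screen_params>\n")
  cat(sprintf("  cohort: start age %d, %d annual cycles, discount %.1f%%\n",
              x$start_age, x$horizon_years, 100 * x$discount_rate))
  cat(sprintf("  incidence bands: %d (%.6f-%.6f), mammography sensitivity %.3f\n",
              nrow(x$incidence), min(x$incidence$value), max(x$incidence$value),
              x$mammography_sensitivity))
  rg <- x$risk_groups
  cat(sprintf("  risk groups: %s\n",
              paste(sprintf("%s %.0f%% x%.1f", rg$name, 100 * rg$proportion,
                            rg$multiplier), collapse = ", ")))
  nv <- length(validate_parameters(x))
  cat(sprintf("  validation: %s\n", if (nv == 0) "OK" else paste(nv, "violation(s)")))
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

params_to_list <- function(params) {
  p <- unclass(params)
  p$incidence <- as.list(p$incidence)
  p$all_cause_mortality <- as.list(p$all_cause_mortality)
  p$stage_mortality$age_factors <- as.list(p$stage_mortality$age_factors)
  p$risk_groups <- as.list(p$risk_groups)
  p$psa <- as.list(p$psa)
  p$sa_ranges <- as.list(p$sa_ranges)
  p
}

list_to_params <- function(lst) {
  defaults <- default_parameters()
  known <- names(defaults)
  unknown <- setdiff(names(lst), known)
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  }
  stage_named <- function(x, field) {
    x <- unlist(x)
    if (is.null(names(x)) && length(x) == length(STAGES)) names(x) <- STAGES
    extra <- setdiff(names(x), STAGES)
    if (length(extra) > 0) {
      stop(field, ": unknown stage '", paste(extra, collapse = "', '"), "'")
    }
    x[STAGES]
  }
  p <- defaults
  omitted <- setdiff(known, names(lst))
  if (length(omitted) > 0) {
    message("load_parameters: field(s) ", paste(omitted, collapse = ", "),
            " omitted; using defaults")
  }
  for (nm in intersect(names(lst), known)) {
    x <- lst[[nm]]
    p[[nm]] <- switch(nm,
      incidence = ,
      all_cause_mortality = as.data.frame(x),
      stage_dist_screened = stage_named(x, nm),
      stage_dist_unscreened = stage_named(x, nm),
      stage_mortality = list(
        base_rate = stage_named(x$base_rate, "stage_mortality$base_rate"),
        age_factors = as.data.frame(x$age_factors)
      ),
      costs = list(
        stage_annual = stage_named(x$stage_annual, "costs$stage_annual"),
        mammography = x$mammography,
        snp_genotyping = x$snp_genotyping,
        genetic_counseling = x$genetic_counseling
      ),
      utilities = list(
        healthy = x$healthy,
        by_stage_year1 = stage_named(x$by_stage_year1, "utilities$by_stage_year1"),
        by_stage_later = stage_named(x$by_stage_later, "utilities$by_stage_later"),
        death = x$death
      ),
      risk_groups = as.data.frame(x),
      psa = as.data.frame(x),
      sa_ranges = as.data.frame(x),
      options = utils::modifyList(defaults$options, x),
      x
    )
  }
  p$start_age <- as.integer(p$start_age)
  p$horizon_years <- as.integer(p$horizon_years)
  p$cycle_length <- as.integer(p$cycle_length)
  class(p) <- "screen_params"
  p
}

#' Save model parameters to YAML or JSON
#'
#' @param params a `screen_params` object.
#' @param path output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  lst <- params_to_list(params)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stop("unsupported parameter file extension '.", ext, "' (use .yaml or .json)")
  }
  invisible(path)
}

#' Load model parameters from YAML or JSON
#'
#' Fields omitted from the file fall back to the bundled defaults (with a
#' message). The two age-band tables may be given inline or as the path
#' (relative to the config file) of a 3-column CSV (`age_lo`, `age_hi`,
#' `value`). The loaded set is validated; violations raise an error listing
#' every failed rule.
#'
#' @param path parameter file (`.yaml`/`.yml` or `.json`).
#' @return a validated `screen_params` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported parameter file extension '.", ext, "' (use .yaml or .json)")
  }
  for (tab in c("incidence", "all_cause_mortality")) {
    if (is.character(lst[[tab]]) && length(lst[[tab]]) == 1) {
      csv <- lst[[tab]]
      if (!file.exists(csv)) csv <- file.path(dirname(path), lst[[tab]])
      if (!file.exists(csv)) stop(tab, ": age-table CSV not found: ", lst[[tab]])
      lst[[tab]] <- utils::read.csv(csv)
    }
  }
  p <- list_to_params(lst)
  viol <- validate_parameters(p)
  if (length(viol) > 0) {
    stop("invalid parameters in ", path, ":\n  ",
         paste(viol, collapse = "\n  "))
  }
  p
}
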