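# Parameter ids sampled in the PSA and where they land in the parameter set.
psa_apply_draw <- function(params, values) {
  p <- params
  p$costs$stage_annual <- stats::setNames(
    values[paste0("cost_stage_", STAGES)], STAGES)
  p$costs$mammography <- values[["cost_mammography"]]
  p$costs$snp_genotyping <- values[["cost_snp_genotyping"]]
  p$costs$genetic_counseling <- values[["cost_genetic_counseling"]]
  p$utilities$by_stage_year1 <- stats::setNames(
    values[paste0("util_year1_", STAGES)], STAGES)
  p$utilities$by_stage_later <- stats::setNames(
    values[paste0("util_later_", STAGES)], STAGES)
  rgn <- p$risk_groups$name
  for (g in c("low", "intermediate", "high")) {
    p$risk_groups$multiplier[rgn == g] <- values[[paste0("multiplier_", g)]]
  }
  p$mammography_sensitivity <- values[["mammography_sensitivity"]]
  p
}

#' Derive a PSA distribution from a base value and range
#'
#' Method-of-moments alternative to the printed distribution parameters: the
#' standard deviation is `half_width / 1.96` (a symmetric range read as an
#' approximate 95% interval), then gamma(shape, scale), beta(alpha, beta) or
#' normal(mean, sd) parameters are matched to the mean and that sd. A
#' half-width of zero yields a degenerate point mass.
#'
#' @param mean base-case value (must lie in the family's support).
#' @param half_width absolute half-width of the range (e.g. `0.3 * mean` for
#'   a +-30% range).
#' @param family `"gamma"`, `"beta"` or `"normal"`.
#' @return list with `family`, `a`, `b` (`a`/`b` are shape/scale for gamma,
#'   alpha/beta for beta, mean/sd for normal; `family = "point"` when
#'   `half_width` is 0).
#' @examples
#' derive_distribution_from_range(2444, 0.3 * 2444, "gamma")$a  # ~42.7
#' derive_distribution_from_range(0.835, 0.15 * 0.835, "beta")$a  # ~27.3
#' @export
derive_distribution_from_range <- function(mean, half_width, family) {
  if (half_width < 0) stop("half_width must be >= 0")
  if (half_width == 0) return(list(family = "point", a = mean, b = 0))
  sd <- half_width / 1.96
  switch(family,
    gamma = {
      if (mean <= 0) stop("gamma mean must be > 0")
      list(family = "gamma", a = (mean / sd)^2, b = sd^2 / mean)
    },
    beta = {
      if (mean <= 0 || mean >= 1) stop("beta mean must be in (0, 1)")
      nu <- mean * (1 - mean) / sd^2 - 1
      if (nu <= 0) stop("range too wide for a beta distribution at this mean")
      list(family = "beta", a = mean * nu, b = (1 - mean) * nu)
    },
    normal = list(family = "normal", a = mean, b = sd),
    stop("unsupported distribution family '", family, "'")
  )
}

# Distribution table actually used for sampling, honouring the psa_source
# option ("printed" = the published alpha/beta verbatim; "range" = method of
# moments from the base value and its stated range: costs +-30%, utilities
# +-0.1, multipliers +-30%, sensitivity +-15%).
psa_distribution_table <- function(params) {
  if (!identical(params$options$psa_source, "range")) return(params$psa)
  specs <- params$psa
  base_of <- function(id) {
    if (grepl("^cost_stage_", id)) {
      params$costs$stage_annual[[sub("cost_stage_", "", id)]]
    } else switch(id,
      cost_mammography = params$costs$mammography,
      cost_snp_genotyping = params$costs$snp_genotyping,
      cost_genetic_counseling = params$costs$genetic_counseling,
      mammography_sensitivity = params$mammography_sensitivity,
      multiplier_low = ,
      multiplier_intermediate = ,
      multiplier_high = {
        g <- sub("multiplier_", "", id)
        params$risk_groups$multiplier[params$risk_groups$name == g]
      },
      {
        phase <- if (grepl("^util_year1_", id)) "by_stage_year1" else "by_stage_later"
        params$utilities[[phase]][[sub("util_(year1|later)_", "", id)]]
      }
    )
  }
  for (i in seq_len(nrow(specs))) {
    id <- specs$parameter[i]
    base <- base_of(id)
    hw <- if (grepl("^cost_", id)) 0.30 * base
      else if (grepl("^util_", id)) 0.1
      else if (grepl("^multiplier_", id)) 0.30 * base
      else 0.15 * base
    d <- derive_distribution_from_range(base, hw, specs$family[i])
    if (d$family == "point") { specs$a[i] <- d$a; specs$b[i] <- 0 }
    else { specs$a[i] <- d$a; specs$b[i] <- d$b }
  }
  specs
}

#' Sample one PSA parameter draw
#'
#' Each uncertain parameter is drawn independently from its distribution
#' specification: costs from gamma(shape, scale), utilities and mammography
#' sensitivity from beta (clipped to `[0, 1]`), risk-group multipliers from
#' normal truncated at 0 (resampled). Uses the current RNG state.
#'
#' @param params a `screen_params` object.
#' @return a `psa_draw`: list with `values` (named numeric) and `params`
#'   (the parameter set with the draw applied).
#' @export
sample_psa_draw <- function(params) {
  specs <- psa_distribution_table(params)
  vals <- numeric(nrow(specs))
  names(vals) <- specs$parameter
  for (i in seq_len(nrow(specs))) {
    a <- specs$a[i]; b <- specs$b[i]
    x <- switch(specs$family[i],
      gamma = stats::rgamma(1, shape = a, scale = b),
      beta = min(1, max(0, stats::rbeta(1, a, b))),
      normal = {
        y <- stats::rnorm(1, a, b)
        while (y <= 0) y <- stats::rnorm(1, a, b)
        y
      },
      point = a,
      stop("invalid distribution family '", specs$family[i], "' for ",
           specs$parameter[i])
    )
    vals[i] <- x
  }
  list(values = vals, params = psa_apply_draw(params, vals))
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of the parameter distributions: for each of
#' `n_iterations` draws, both strategies are evaluated under the SAME
#' sampled parameter set with the unchanged deterministic engine, and the
#' incremental cost, life years and QALYs are recorded.
#'
#' @param params a `screen_params` object.
#' @param n_iterations number of Monte Carlo draws (default 10000).
#' @param seed RNG seed for reproducibility.
#' @param wtp reference willingness-to-pay for the per-draw net monetary
#'   benefit column (US$/QALY).
#' @return a `psa_result`: list with `draws` (data frame: draw, d_cost,
#'   d_ly, d_qaly, nmb), `n_iterations`, `seed`, `wtp`, and `source`
#'   (printed vs range-derived distributions).
#' @export
run_psa <- function(params, n_iterations = 10000, seed = NULL, wtp = 30000) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  d_cost <- d_ly <- d_qaly <- numeric(n_iterations)
  for (k in seq_len(n_iterations)) {
    draw <- sample_psa_draw(params)
    ce <- run_base_case(draw$params, wtp = wtp)
    d_cost[k] <- ce$d_cost
    d_ly[k] <- ce$d_ly
    d_qaly[k] <- ce$d_qaly
  }
  structure(list(
    draws = data.frame(draw = seq_len(n_iterations), d_cost = d_cost,
                       d_ly = d_ly, d_qaly = d_qaly,
                       nmb = d_qaly * wtp - d_cost),
    n_iterations = n_iterations, seed = seed, wtp = wtp,
    source = if (identical(params$options$psa_source, "range"))
      "range-derived" else "printed"
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (%s distributions%s)\n", x$n_iterations,
              x$source,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  cat(sprintf("  mean increments: cost US$%.2f, LY %.4f, QALY %.4f\n",
              mean(x$draws$d_cost), mean(x$draws$d_ly), mean(x$draws$d_qaly)))
  cat(sprintf("  cost-effective at WTP %.0f: %.1f%%\n", x$wtp,
              100 * mean(x$draws$nmb > 0)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with strictly positive net monetary benefit
#' (`d_qaly * wtp - d_cost > 0`) at each willingness-to-pay grid point.
#'
#' @param result a `psa_result` from [run_psa()].
#' @param wtp_grid non-negative thresholds (default 0-1000 US$/QALY in steps
#'   of 10, plus 30000).
#' @return data frame: wtp, prob_ce.
#' @export
ceac <- function(result, wtp_grid = c(seq(0, 1000, by = 10), 30000)) {
  if (any(wtp_grid < 0)) stop("wtp_grid values must be >= 0")
  d <- result$draws
  prob <- vapply(wtp_grid,
                 function(w) mean(d$d_qaly * w - d$d_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_ce = prob)
}
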