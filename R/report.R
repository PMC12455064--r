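# Report writers: Table-2/Table-3-style CSVs, tornado and discount-rate
# tables, PSA exports, and a plain-text run manifest per command.

config_hash <- function(params) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_parameters(params, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, command, files, params, seed = NULL,
                           n_iterations = NULL) {
  path <- file.path(out_dir, paste0(command, "_manifest.txt"))
  lines <- c(
    sprintf("command: %s", command),
    sprintf("package: prsscreen %s",
            as.character(utils::packageVersion("prsscreen"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("config_hash: %s", config_hash(params)),
    sprintf("discount_timing: %s", params$options$discount_timing),
    sprintf("cancer_allcause_mortality: %s",
            params$options$cancer_allcause_mortality),
    sprintf("psa_source: %s", params$options$psa_source)
  )
  if (!is.null(seed)) lines <- c(lines, sprintf("seed: %d", seed))
  if (!is.null(n_iterations)) {
    lines <- c(lines, sprintf("n_iterations: %d", n_iterations))
  }
  lines <- c(lines, paste0("output: ", files))
  writeLines(lines, path)
  path
}

outcome_row <- function(strategy_name, o) {
  data.frame(strategy = strategy_name, cost = o$cost, life_years = o$life_years,
             qalys = o$qalys, cases_per_1000 = 1000 * o$cases_per_woman)
}

#' Write the base-case report
#'
#' Writes `base_case.csv` (one row per strategy: discounted lifetime cost,
#' life years, QALYs, cases per 1000) and `base_case_incremental.csv`
#' (increments, ICER, dominance label, NMB), plus a run manifest.
#'
#' @param params a `screen_params` object.
#' @param out_dir output directory (created if missing).
#' @param wtp willingness-to-pay threshold (US$/QALY).
#' @return invisibly, the `ce_result`.
#' @export
write_base_case <- function(params, out_dir, wtp = 30000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ce <- run_base_case(params, wtp = wtp)
  per_strategy <- rbind(outcome_row("age-based 45-69", ce$comparator),
                        outcome_row("PRS-stratified", ce$intervention))
  f1 <- file.path(out_dir, "base_case.csv")
  utils::write.csv(per_strategy, f1, row.names = FALSE)
  inc <- data.frame(d_cost = ce$d_cost, d_ly = ce$d_ly, d_qaly = ce$d_qaly,
                    icer = ce$icer, label = ce$label, wtp = wtp, nmb = ce$nmb)
  f2 <- file.path(out_dir, "base_case_incremental.csv")
  utils::write.csv(inc, f2, row.names = FALSE)
  write_manifest(out_dir, "base_case", c(f1, f2), params)
  invisible(ce)
}

#' Write the scenario-grid report
#'
#' @param params a `screen_params` object.
#' @param out_dir output directory.
#' @param scenarios list of [scenario_spec()] (default the bundled preset).
#' @param wtp willingness-to-pay threshold (US$/QALY).
#' @return invisibly, the scenario table.
#' @export
write_scenarios <- function(params, out_dir, scenarios = default_scenarios(),
                            wtp = 30000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- run_scenarios(params, scenarios, wtp = wtp)
  f <- file.path(out_dir, "scenarios.csv")
  utils::write.csv(tab, f, row.names = FALSE)
  write_manifest(out_dir, "scenarios", f, params)
  invisible(tab)
}

#' Write the sensitivity-analysis reports
#'
#' Writes `tornado.csv` (one-way sensitivity analysis ordered by bar width)
#' and `discount_rates.csv` (discount-rate analysis), plus a manifest.
#'
#' @param params a `screen_params` object.
#' @param out_dir output directory.
#' @param rates discount rates for the discount-rate analysis.
#' @param wtp willingness-to-pay threshold (US$/QALY).
#' @return invisibly, a list with `tornado` and `discount` tables.
#' @export
write_sa <- function(params, out_dir, rates = c(0, 0.01, 0.03, 0.05),
                     wtp = 30000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tor <- one_way_sa(params, wtp = wtp)
  dis <- discount_rate_analysis(params, rates, wtp = wtp)
  f1 <- file.path(out_dir, "tornado.csv")
  f2 <- file.path(out_dir, "discount_rates.csv")
  utils::write.csv(tor, f1, row.names = FALSE)
  utils::write.csv(dis, f2, row.names = FALSE)
  write_manifest(out_dir, "sa", c(f1, f2), params)
  invisible(list(tornado = tor, discount = dis))
}

#' Write the probabilistic-sensitivity-analysis reports
#'
#' Writes `ce_plane.csv` (per-draw incremental cost and QALYs),
#' `ceac.csv` (cost-effectiveness acceptability curve) and
#' `psa_summary.json`, plus a manifest recording seed and iteration count.
#'
#' @param params a `screen_params` object.
#' @param out_dir output directory.
#' @param n_iterations Monte Carlo draws.
#' @param seed RNG seed.
#' @param wtp reference willingness-to-pay threshold (US$/QALY).
#' @return invisibly, the `psa_result`.
#' @export
write_psa <- function(params, out_dir, n_iterations = 10000, seed = 1,
                      wtp = 30000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_psa(params, n_iterations = n_iterations, seed = seed, wtp = wtp)
  curve <- ceac(res)
  f1 <- file.path(out_dir, "ce_plane.csv")
  f2 <- file.path(out_dir, "ceac.csv")
  f3 <- file.path(out_dir, "psa_summary.json")
  utils::write.csv(res$draws, f1, row.names = FALSE)
  utils::write.csv(curve, f2, row.names = FALSE)
  jsonlite::write_json(list(
    n_iterations = res$n_iterations, seed = res$seed, wtp = res$wtp,
    source = res$source,
    mean_d_cost = mean(res$draws$d_cost),
    mean_d_qaly = mean(res$draws$d_qaly),
    prob_ce_at_wtp = mean(res$draws$nmb > 0)
  ), f3, auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "psa", c(f1, f2, f3), params, seed = seed,
                 n_iterations = n_iterations)
  invisible(res)
}
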