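test_that("PSA runs are bitwise reproducible for a given seed", {
  p <- default_parameters()
  r1 <- run_psa(p, n_iterations = 25, seed = 7)
  r2 <- run_psa(p, n_iterations = 25, seed = 7)
  expect_identical(r1$draws, r2$draws)
  expect_equal(nrow(r1$draws), 25)
  r3 <- run_psa(p, n_iterations = 25, seed = 8)
  expect_false(identical(r1$draws$d_cost, r3$draws$d_cost))
  expect_error(run_psa(p, n_iterations = 0), "n_iterations")
})

test_that("degenerate point-mass distributions reproduce the deterministic base case", {
  p <- point_mass_psa(default_parameters())
  draw <- sample_psa_draw(p)
  expect_equal(draw$params$costs$stage_annual, p$costs$stage_annual)
  expect_equal(draw$params$mammography_sensitivity, p$mammography_sensitivity)
  res <- run_psa(p, n_iterations = 1, seed = 1)
  base <- run_base_case(p)
  expect_equal(res$draws$d_cost, base$d_cost)
  expect_equal(res$draws$d_qaly, base$d_qaly)
})

test_that("sampled marginals match their specification moments within 3 standard errors", {
  p <- default_parameters()
  set.seed(42)
  n <- 4000
  vals <- matrix(0, n, nrow(p$psa), dimnames = list(NULL, p$psa$parameter))
  for (k in seq_len(n)) vals[k, ] <- sample_psa_draw(p)$values
  check <- function(id, mean_true, sd_true) {
    se <- sd_true / sqrt(n)
    expect_lt(abs(mean(vals[, id]) - mean_true), 3 * se)
  }
  # gamma: mean = shape * scale, sd = sqrt(shape) * scale
  check("cost_stage_I", 42.7 * 57.3, sqrt(42.7) * 57.3)
  check("cost_stage_IV", 42.7 * 313.9, sqrt(42.7) * 313.9)
  # normal multiplier (truncation at 0 is negligible at sigma = 0.17)
  check("multiplier_intermediate", 1.1, 0.17)
  # beta: mean = a / (a + b)
  ab <- c(27.3, 6.4)
  check("mammography_sensitivity", ab[1] / sum(ab),
        sqrt(prod(ab) / (sum(ab)^2 * (sum(ab) + 1))))
  expect_true(all(vals[, "multiplier_low"] > 0))
  expect_true(all(vals[, grep("^util_", colnames(vals))] <= 1))
})

test_that("the acceptability curve is a bounded fraction, monotone when QALY gains are positive", {
  dom <- structure(list(draws = data.frame(
    draw = 1:4, d_cost = -1, d_ly = 1, d_qaly = 1, nmb = NA)),
    class = "psa_result")
  cc <- ceac(dom, c(0, 100, 1000))
  expect_equal(cc$prob_ce, c(1, 1, 1))
  set.seed(1)
  mixed <- structure(list(draws = data.frame(
    draw = 1:200, d_cost = rnorm(200, 50, 100), d_ly = 1,
    d_qaly = runif(200, 0.01, 1), nmb = NA)), class = "psa_result")
  cc2 <- ceac(mixed, seq(0, 2000, 100))
  expect_true(all(diff(cc2$prob_ce) >= 0))
  expect_true(all(cc2$prob_ce >= 0 & cc2$prob_ce <= 1))
  expect_error(ceac(mixed, c(-5, 10)), "wtp_grid")
})

test_that("range-derived distributions match the printed shapes by method of moments", {
  g <- derive_distribution_from_range(2444, 0.3 * 2444, "gamma")
  expect_equal(g$a, (1.96 / 0.3)^2, tolerance = 1e-12)  # ~42.7, CV^-2
  expect_equal(g$a, 42.7, tolerance = 0.001)
  expect_equal(g$a * g$b, 2444)  # mean preserved
  b <- derive_distribution_from_range(0.835, 0.15 * 0.835, "beta")
  expect_equal(b$a, 27.3, tolerance = 0.01)
  expect_equal(b$a / (b$a + b$b), 0.835)
  n <- derive_distribution_from_range(1.1, 0.3 * 1.1, "normal")
  expect_equal(n$b, 0.3 * 1.1 / 1.96)
  pt <- derive_distribution_from_range(5, 0, "gamma")
  expect_equal(pt$family, "point")
  expect_error(derive_distribution_from_range(0.99, 0.5, "beta"), "too wide")
  expect_error(derive_distribution_from_range(-1, 1, "gamma"), "mean")
})

test_that("the range-derived PSA source plugs into sampling", {
  p <- default_parameters()
  p$options$psa_source <- "range"
  tab <- prsscreen:::psa_distribution_table(p)
  expect_equal(tab$a[tab$parameter == "cost_stage_I"], (1.96 / 0.3)^2,
               tolerance = 1e-10)
  expect_equal(tab$b[tab$parameter == "multiplier_intermediate"],
               0.3 * 1.1 / 1.96)
  r <- run_psa(p, n_iterations = 5, seed = 3)
  expect_equal(r$source, "range-derived")
  expect_equal(nrow(r$draws), 5)
})
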