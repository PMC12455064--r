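test_that("default parameters carry the published inputs and validate cleanly", {
  p <- default_parameters()
  expect_length(validate_parameters(p), 0)
  expect_equal(nrow(p$incidence), 10)
  expect_equal(nrow(p$all_cause_mortality), 10)
  expect_equal(band_value(p$incidence, 47), 0.002383)
  expect_equal(band_value(p$incidence, 36), 0.000744)
  expect_equal(band_value(p$all_cause_mortality, 82), 0.046523)
  expect_equal(unname(p$stage_mortality$base_rate["IV"]), 0.167)
  expect_equal(sum(p$stage_dist_screened), 1)
  expect_equal(sum(p$stage_dist_unscreened), 1)
  expect_equal(sum(p$risk_groups$proportion), 1)
  expect_equal(p$mammography_sensitivity, 0.835)
  expect_equal(p$discount_rate, 0.03)
})

test_that("printed gamma PSA specs reproduce base-case cost means within 5%", {
  p <- default_parameters()
  gam <- p$psa[p$psa$family == "gamma", ]
  base <- c(p$costs$stage_annual, p$costs$mammography, p$costs$snp_genotyping,
            p$costs$genetic_counseling)
  expect_equal(nrow(gam), length(base))
  means <- gam$a * gam$b  # shape x scale
  expect_true(all(abs(means - base) / base < 0.05))
})

test_that("validation reports named violations without throwing", {
  p <- default_parameters()
  p$stage_dist_screened["I"] <- 0.60
  v <- validate_parameters(p)
  expect_length(v, 1)
  expect_match(v, "stage_dist_screened")
  expect_match(v, "simplex")

  p2 <- default_parameters()
  p2$discount_rate <- -0.01
  v2 <- validate_parameters(p2)
  expect_length(v2, 1)
  expect_match(v2, "discount_rate")

  # several independent violations accumulate
  p3 <- default_parameters()
  p3$mammography_sensitivity <- 1.4
  p3$risk_groups$multiplier[1] <- -2
  p3$utilities$healthy <- 0.9
  v3 <- validate_parameters(p3)
  expect_true(length(v3) >= 3)
})

test_that("serialization round-trips through YAML and JSON", {
  p <- default_parameters()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    save_parameters(p, path)
    q <- load_parameters(path)
    expect_equal(q, p)
  }
})

test_that("partial config overrides fall back to defaults with a notice", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("discount_rate: 0.05", path)
  expect_message(q <- load_parameters(path), "omitted")
  expect_equal(q$discount_rate, 0.05)
  q$discount_rate <- 0.03
  expect_equal(q, default_parameters())
})

test_that("unknown stages and fields in a config are schema errors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("stage_dist_screened:",
               "  I: 0.49", "  II: 0.36", "  III: 0.13", "  V: 0.02"), path)
  expect_error(load_parameters(path), "V")
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_field: 1", path2)
  expect_error(load_parameters(path2), "not_a_field")
  expect_error(load_parameters("does/not/exist.yaml"), "not found")
})

test_that("age-band tables can be imported from a sidecar CSV", {
  dir <- withr::local_tempdir()
  p <- default_parameters()
  inc <- p$incidence
  inc$value <- inc$value * 2
  write.csv(inc, file.path(dir, "incidence.csv"), row.names = FALSE)
  writeLines("incidence: incidence.csv", file.path(dir, "config.yaml"))
  q <- suppressMessages(load_parameters(file.path(dir, "config.yaml")))
  expect_equal(q$incidence$value, 2 * p$incidence$value)
  writeLines("incidence: missing.csv", file.path(dir, "bad.yaml"))
  expect_error(suppressMessages(load_parameters(file.path(dir, "bad.yaml"))),
               "missing.csv")
})

test_that("age factors select the interval containing the age", {
  p <- default_parameters()
  expect_equal(age_factor(40, p), 0.151)
  expect_equal(age_factor(44, p), 0.151)
  expect_equal(age_factor(45, p), 1.000)
  expect_equal(age_factor(50, p), 1.000)
  expect_equal(age_factor(64, p), 1.000)
  expect_equal(age_factor(70, p), 1.739)
})

test_that("age factors derive as crude-rate ratios to the reference group", {
  crude <- c("35-44" = 5.5, "45-64" = 36.4, ">=65" = 63.3)
  f <- derive_age_factors(crude, "45-64")
  expect_equal(round(unname(f), 3), c(0.151, 1.000, 1.739))
  expect_equal(unname(derive_age_factors(c(a = 20, ref = 20), "ref")), c(1, 1))
  expect_equal(unname(derive_age_factors(c(A = 10, ref = 20), "ref")), c(0.5, 1))
  expect_error(derive_age_factors(c(a = 1), "ref"), "not present")
  expect_error(derive_age_factors(c(a = 1, ref = 0), "ref"), "positive")
})
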