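write_fixture_table <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c(
    "line_id,region,n_f1_females,n_f1_males,neonates_per_female,control_mortality",
    rows), path)
  path
}

test_that("line-table reader validates rows with descriptive errors", {
  good <- write_fixture_table(c(
    "P001,Tafalla,3,27,11;12;9,0.132",
    "P002,Bajo Cinca,2,3,10,0.1",
    "P003,,1,1,0,0"
  ))
  lines <- read_line_table(good)
  expect_length(lines, 3L)
  expect_equal(lines[[1]]$neonates_per_female, c(11, 12, 9))
  expect_equal(lines[[1]]$n_f1_females, 3L)
  expect_equal(lines[[2]]$neonates_per_female, rep(10, 2))
  bad_mu <- write_fixture_table("P001,Tafalla,27,27,11,1.2")
  expect_error(read_line_table(bad_mu), "row 1")
  bad_k <- write_fixture_table("P001,Tafalla,2,2,5;-1,0.1")
  expect_error(read_line_table(bad_k), "neonates_per_female")
  missing_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("line_id,n_f1_females", "a,2"), missing_col)
  expect_error(read_line_table(missing_col), "missing column")
})

test_that("mean neonate counts are broadcast across females", {
  path <- write_fixture_table("P001,R,3,4,11.4,0.132")
  rec <- read_line_table(path)[[1]]
  expect_equal(rec$neonates_per_female, rep(11.4, 3))
  expect_equal(p_no(rec), p_no(line_record("x", 3, 4, 11.4, 0.132)))
})

test_that("full pipeline reproduces the estimation stage and omits absent blocks", {
  report <- run_full_pipeline(list(estimate = list(positives = 1, lines = 137)))
  expect_s3_class(report, "analysis_report")
  expect_equal(round(report$estimate$expected_q, 4), 0.0036)
  expect_equal(round(report$estimate$ci_low, 4), 0.0004)
  expect_equal(report$estimate$ci_high, 0.0100, tolerance = 0.02)
  expect_null(report$detection)
  expect_null(report$comparison)
  expect_null(report$evolution)
  expect_equal(report$schema_version, "1.0")
  expect_error(run_full_pipeline(list()), class = "f2screen_input_error")
})

test_that("full pipeline chains detection, comparison and evolution stages", {
  sim <- simulate_screen(0.02, 20, seed = 3)
  tab <- withr::local_tempfile(fileext = ".csv")
  generate_line_table(sim, tab)
  config <- list(
    estimate = list(positives = 1, lines = 137),
    detection = list(table = tab),
    compare = list(b_positives = 0, b_lines = 166,
                   power = list(mult_b = 2, n_reps = 50)),
    evolution = list(adoption = data.frame(year = 2016, proportion = 0.74),
                     horizon_years = 50),
    seed = 42
  )
  report <- run_full_pipeline(config)
  expect_equal(report$detection$n_lines, 20L)
  expect_equal(report$detection$experiment_wise,
               detection_summary(sim$lines)$experiment_wise)
  expect_true(report$comparison$p >= 0 && report$comparison$p <= 1)
  expect_equal(report$comparison$power$n_reps, 50L)
  expect_equal(report$evolution$mode, "deterministic")
  expect_equal(report$evolution$initial_q, expected_q(posterior_q(1, 137)))
  # stochastic results carry their seeds; reports are reproducible
  expect_equal(report$comparison$power$seed, 44L)
  report2 <- run_full_pipeline(config)
  report$provenance$created <- report2$provenance$created <- NULL
  expect_identical(unclass(report), unclass(report2))
})

test_that("reports serialise to stable JSON", {
  report <- run_full_pipeline(list(
    estimate = list(positives = 1, lines = 137), seed = 7))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(report, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$schema_version, "1.0")
  expect_equal(back$estimate$expected_q, report$estimate$expected_q,
               tolerance = 1e-12)
  expect_equal(back$provenance$seed, 7)
})

test_that("YAML configs drive the pipeline", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "estimate:",
    "  positives: 1",
    "  lines: 137",
    "  level: 0.95"
  ), cfg)
  report <- run_full_pipeline(cfg)
  expect_equal(round(report$estimate$expected_q, 4), 0.0036)
})
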