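test_that("the packaged base case loads with the published values and validates cleanly", {
  p <- base_params()

  expect_s3_class(p, "oab_parameters")
  expect_equal(nrow(validate_parameter_set(p)), 0)

  expect_equal(p$arms$fesoterodine$doses$`4mg`$response_w8, 0.50)
  expect_equal(p$arms$fesoterodine$doses$`4mg`$response_w12, 0.4367)
  expect_equal(p$arms$placebo$doses$placebo$cond_w12_given_w8resp, 0.8033)
  expect_equal(p$utilities$u_untreated, 0.9332)
  expect_equal(p$unit_costs$pad, 0.58)
  expect_equal(p$unit_costs$drug_per_day$fesoterodine$`8mg`, 2.72)
  expect_equal(p$persistence$shared[["52"]], 0.5927)
  expect_equal(p$persistence$week8_by_arm[["tolterodine"]], 0.9576)
  expect_equal(p$productivity$baseline_nocturia_prevalence, 0.4858)
})

test_that("marginal/conditional consistency holds for every arm and dose of the fixture", {
  p <- base_params()
  for (arm in p$arms) {
    for (dd in arm$doses) {
      expect_lt(
        abs(dd$cond_w12_given_w8resp * dd$response_w8 - dd$response_w12),
        0.005
      )
    }
  }
})

test_that("loading rejects invalid files with named paths and accepts degenerate-but-valid ones", {
  raw <- yaml::read_yaml(system.file("extdata", "oab_basecase.yaml",
                                     package = "oabcea"))

  # missing section
  broken <- raw
  broken$utilities <- NULL
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(broken, f)
  expect_error(load_parameter_set(f), "utilities")

  # probability out of range, reported with its path
  broken <- raw
  broken$arms$fesoterodine$doses$`4mg`$response_w8_pct <- 120
  yaml::write_yaml(broken, f)
  expect_error(load_parameter_set(f), "arms.fesoterodine.doses.4mg.response_w8")

  # zero pad cost is valid
  degenerate <- raw
  degenerate$unit_costs$pad <- 0
  yaml::write_yaml(degenerate, f)
  p <- load_parameter_set(f)
  expect_equal(p$unit_costs$pad, 0)

  expect_error(load_parameter_set("no/such/file.yaml"), "not found")
})

test_that("validation reports broken invariants with paths instead of fixing them", {
  p <- base_params()

  p1 <- p
  p1$persistence$shared[["24"]] <- 0.95 # above week 12: increasing
  rep1 <- validate_parameter_set(p1)
  expect_true(any(grepl("persistence.shared", rep1$path)))
  expect_true(any(grepl("non-increasing", rep1$message)))

  p2 <- p
  p2$arms$tolterodine$doses$`4mg`$response_w12 <- 0.50 # breaks cond * w8
  rep2 <- validate_parameter_set(p2)
  expect_true(any(grepl("arms.tolterodine.doses.4mg.response_w12", rep2$path)))

  p3 <- p
  p3$comorbidity$controlled$uti_events_per_person <- 0.05 # below prob_any
  rep3 <- validate_parameter_set(p3)
  expect_true(any(grepl("uti_events_per_person", rep3$path)))

  p4 <- p
  p4$titration$tolterodine$frac_responders_titrate <- 0.5 # single-dose arm
  rep4 <- validate_parameter_set(p4)
  expect_true(any(grepl("titration.tolterodine", rep4$path)))
})

test_that("relative-risk scaling reproduces the printed solifenacin rows", {
  p <- base_params()
  placebo <- p$arms$placebo$doses$placebo

  s5 <- scale_efficacy_by_rr(placebo, 1.50)
  expect_equal(s5$response_w2, 0.3149)
  expect_equal(s5$response_w8, 0.5199)
  expect_equal(s5$response_w12, 0.4176)
  expect_equal(s5$cond_w12_given_w8resp, 0.8033) # copied, not scaled
  expect_equal(s5$cond_w12_given_w8nonresp, 0.2124)
  # matches the packaged fixture cell for cell
  fix5 <- p$arms$solifenacin$doses$`5mg`
  for (f in c("response_w2", "response_w8", "response_w12",
              "cond_w12_given_w8resp", "cond_w12_given_w8nonresp")) {
    expect_equal(s5[[f]], fix5[[f]], info = f)
  }

  s10 <- scale_efficacy_by_rr(placebo, 1.53)
  expect_equal(s10$response_w2, 0.3211)
  expect_equal(s10$cond_w12_given_w8nonresp, 0.2166)
  # the 10 mg W8/W12 cells drift 0.02 pp from the printed table (printed
  # 53.01/42.58); the consistency band absorbs the difference
  expect_lt(abs(s10$response_w8 - 0.5301), 0.0005)
  expect_lt(abs(s10$response_w12 - 0.4258), 0.0005)

  expect_equal(scale_efficacy_by_rr(placebo, 1), placebo)
  expect_error(scale_efficacy_by_rr(placebo, 3), "exceeds 1")
  expect_error(scale_efficacy_by_rr(placebo, -1), "positive")
})

test_that("conditional_from_marginals is the ratio of marginals with guarded edge cases", {
  expect_equal(conditional_from_marginals(0.5000, 0.4367), 0.8734)
  expect_equal(conditional_from_marginals(0.37, 0.37), 1)
  expect_equal(conditional_from_marginals(0.3466, 0.2784),
               0.2784 / 0.3466)
  expect_error(conditional_from_marginals(0, 0.1), "response_w8")
  expect_warning(conditional_from_marginals(0.2, 0.3), "exceeds")
})

test_that("events_per_affected reproduces the printed per-affected comorbidity counts", {
  expect_equal(round(events_per_affected(0.7, 0.307), 1), 2.3)
  expect_equal(round(events_per_affected(0.3, 0.19), 1), 1.6)
  expect_equal(round(events_per_affected(0.3, 0.107), 1), 2.8)
  expect_equal(round(events_per_affected(0.6, 0.093), 1), 6.5)
  expect_equal(events_per_affected(0.4, 1), 0.4)
  expect_error(events_per_affected(0.5, 0), "inconsistent")
  expect_error(events_per_affected(0, 0), "prob_any")
})

test_that("a parameter set round-trips through serialization unchanged", {
  p <- base_params()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_set(p, f)
  p2 <- load_parameter_set(f)
  expect_equal(p2, p)
})
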