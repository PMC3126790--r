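test_that("drug cost matches closed forms for degenerate and base cohorts", {
  p <- base_params()

  # perfect persistence and response: a tolterodine patient pays 364 days at
  # 1.70 euro/day
  p_full <- p
  p_full$persistence$shared[] <- 1
  p_full$persistence$week8_by_arm[] <- 1
  p_full$arms$tolterodine$doses$`4mg`$cond_w12_given_w8resp <- 1
  p_full$arms$tolterodine$doses$`4mg`$cond_w12_given_w8nonresp <- 1
  p_full$arms$tolterodine$doses$`4mg`$response_w12 <-
    p_full$arms$tolterodine$doses$`4mg`$response_w8
  traj_full <- run_cohort("tolterodine", p_full)
  expect_equal(drug_cost(traj_full, p_full), 364 * 1.70)

  # base-case fesoterodine: 28 start-dose days plus 56 mixed days weighted by
  # week-12 on-treatment occupancy; surviving responders are then
  # response-weighted across doses (higher conditional -> more 8 mg)
  mix_price <- 0.5 * 1.70 + 0.5 * 2.72
  resp_4mg <- 0.25 * (0.8734 + 0.2105)
  resp_8mg <- 0.25 * (0.9065 + 0.2420)
  oracle <- 0.9064 * (28 * 1.70 + 56 * mix_price) +
    0.7932 * 84 * (resp_4mg * 1.70 + resp_8mg * 2.72) +
    0.5927 * 196 * (resp_4mg * 1.70 + resp_8mg * 2.72)
  expect_equal(drug_cost(run_cohort("fesoterodine", p), p), oracle,
               tolerance = 1e-12)

  # zero prices cost nothing
  p0 <- p
  for (a in names(p0$unit_costs$drug_per_day)) {
    p0$unit_costs$drug_per_day[[a]] <-
      lapply(p0$unit_costs$drug_per_day[[a]], function(x) 0)
  }
  expect_equal(drug_cost(run_cohort("fesoterodine", p0), p0), 0)
})

test_that("resource costs follow the status utilization rates", {
  p <- base_params()

  # fully incontinent cohort for a model year: pads only
  inc <- make_traj(list(`12` = c(0, 1, 0), `24` = c(0, 1, 0),
                        `52` = c(0, 1, 0)))
  rc <- resource_cost(inc, p)
  expect_equal(rc$pads, 0.67 * 4.23 * 0.58 * 364)
  expect_equal(rc$visits_labs, (0.2 * 26.78 + 0.15 * 58.60 + 0.078 * 2.56) * 12)

  # fully continent cohort: no pads, the controlled visit profile
  cont <- make_traj(list(`12` = c(1, 0, 0), `24` = c(1, 0, 0),
                         `52` = c(1, 0, 0)))
  rc2 <- resource_cost(cont, p)
  expect_equal(rc2$pads, 0)
  expect_equal(rc2$visits_labs,
               (0.133 * 26.78 + 0.117 * 58.60 + 0.033 * 2.56) * 12)
  # the monthly controlled profile is the published ~10.50 euro
  expect_equal(rc2$visits_labs / 12, 10.50, tolerance = 0.005)

  # zero utilization
  p0 <- p
  for (s in c("controlled", "uncontrolled_on_rx", "untreated")) {
    p0$resource_use[[s]] <- list(frac_using_pads = 0, pads_per_day = 0,
                                 gp_visits_per_month = 0,
                                 specialist_visits_per_month = 0,
                                 lab_tests_per_month = 0)
  }
  rc0 <- resource_cost(inc, p0)
  expect_equal(rc0$pads + rc0$visits_labs, 0)
})

test_that("comorbidity costs annualize the 6-month windows and price per event", {
  p <- base_params()
  unc <- make_traj(list(`12` = c(0, 1, 0), `24` = c(0, 1, 0),
                        `52` = c(0, 1, 0)))

  cc <- comorbidity_cost(unc, p)
  expect_equal(cc$uti, 0.7 * 2 * 53.1)
  expect_equal(cc$skin, 0.6 * 2 * 53.1)
  expect_equal(cc$fracture, 0.053 * 2 * 5742.8)
  expect_equal(cc$depression, 0.1884 * 2699)
  expect_equal(cc$nursing_home, 78.3 / 1000 * 14831.4)

  # annualization off: the 6-month figures are taken as annual
  p1 <- p
  p1$conventions$annualize_six_month <- FALSE
  cc1 <- comorbidity_cost(unc, p1)
  expect_equal(cc1$uti, 0.7 * 53.1)
  expect_equal(cc1$depression, cc$depression) # already annual

  # zero rates cost nothing
  p0 <- p
  for (s in c("controlled", "uncontrolled_on_rx", "untreated")) {
    p0$comorbidity[[s]] <- list(fracture_prob_6mo = 0, skin_prob_6mo = 0,
                                skin_events_per_person = 0, uti_prob_6mo = 0,
                                uti_events_per_person = 0,
                                depression_prob_annual = 0,
                                nursing_home_admissions_per_1000py = 0)
  }
  cc0 <- comorbidity_cost(unc, p0)
  expect_equal(sum(unlist(cc0)), 0)
})

test_that("productivity is an avoided loss: negative, zero off treatment or out of work", {
  p <- base_params()

  # one fully continent person-year of the incontinence channel (nocturia
  # resolution zeroed to isolate it)
  p_iso <- p
  for (d in names(p_iso$arms$tolterodine$doses)) {
    p_iso$arms$tolterodine$doses[[d]]$nocturia_resolution_w12 <- 0
  }
  cont <- make_traj(list(`12` = c(1, 0, 0), `24` = c(1, 0, 0),
                         `52` = c(1, 0, 0)))
  expect_equal(productivity_cost(cont, p_iso),
               -(0.211 * 40 * 13.51 * 0.5983 * 52))

  # all-untreated trajectory: the comparator equals itself
  empty <- make_traj(list(`12` = c(0, 0, 1), `24` = c(0, 0, 1),
                          `52` = c(0, 0, 1)))
  expect_equal(productivity_cost(empty, p), 0)

  # nobody employed: no monetized loss
  p0 <- p
  p0$productivity$frac_employed <- 0
  expect_equal(productivity_cost(run_cohort("fesoterodine", p0), p0), 0)

  expect_lt(productivity_cost(run_cohort("fesoterodine", p), p), 0)
})

test_that("the payer/societal accounting identity holds exactly", {
  p <- base_params()
  for (arm in c("fesoterodine", "tolterodine", "solifenacin")) {
    traj <- run_cohort(arm, p)
    cb <- total_cost(traj, p, "societal")
    expect_identical(cb$total_societal, cb$total_payer + cb$productivity)
    expect_identical(cb$total, cb$total_societal)
    cb_payer <- total_cost(traj, p, "payer")
    expect_identical(cb_payer$total, cb$total_payer)
    direct <- c("drug", "pads", "visits_labs", "constipation", "fracture",
                "skin", "uti", "depression", "nursing_home")
    expect_true(all(unlist(cb[direct]) >= 0))
    expect_lte(cb$productivity, 0)
  }
})

test_that("total cost is monotone in unit costs", {
  p <- base_params()
  traj <- run_cohort("fesoterodine", p)
  base <- total_cost(traj, p, "payer")$total
  for (k in c("pad", "gp_visit", "fracture_event", "nursing_home",
              "depression_per_patient_year")) {
    p_up <- p
    p_up$unit_costs[[k]] <- p_up$unit_costs[[k]] * 1.5
    expect_gte(total_cost(traj, p_up, "payer")$total, base)
  }
})

test_that("base-case arm orderings hold for costs and QALYs", {
  p <- base_params()
  runs <- lapply(c(fesoterodine = "fesoterodine", tolterodine = "tolterodine",
                   solifenacin = "solifenacin"),
                 function(a) run_arm(a, p))
  soc <- vapply(runs, function(r) r$cost$total_societal, numeric(1))
  pay <- vapply(runs, function(r) r$cost$total_payer, numeric(1))
  q <- vapply(runs, function(r) r$qaly_gain, numeric(1))
  expect_lt(soc[["fesoterodine"]], soc[["solifenacin"]])
  expect_lt(soc[["solifenacin"]], soc[["tolterodine"]])
  expect_lt(pay[["fesoterodine"]], pay[["solifenacin"]])
  expect_lt(pay[["solifenacin"]], pay[["tolterodine"]])
  expect_gt(q[["fesoterodine"]], q[["solifenacin"]])
  expect_gt(q[["solifenacin"]], q[["tolterodine"]])
})
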