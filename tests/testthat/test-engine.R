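test_that("the titration split partitions the cohort by response and policy", {
  pol <- list(frac_responders_titrate = 0.5, frac_nonresponders_titrate = 0.5)

  s <- apply_titration(0.50, pol, "4mg", "8mg")
  expect_equal(nrow(s), 4)
  expect_equal(s$fraction, rep(0.25, 4))
  expect_equal(sum(s$fraction), 1)

  s2 <- apply_titration(0.5199, pol, "5mg", "10mg")
  expect_equal(sort(s2$fraction), sort(c(0.25995, 0.25995, 0.24005, 0.24005)))
  expect_equal(sum(s2$fraction[s2$responder_w8]), 0.5199)

  # single-dose arm: two branches on the start dose, policy irrelevant
  s3 <- apply_titration(0.4947, pol, "4mg", NA)
  expect_equal(nrow(s3), 2)
  expect_equal(s3$fraction, c(0.4947, 1 - 0.4947))
  expect_true(all(s3$dose == "4mg"))
})

test_that("week-12 response combines branch fractions with dose-specific conditionals", {
  p <- base_params()
  pol50 <- list(frac_responders_titrate = 0.5, frac_nonresponders_titrate = 0.5)

  s_fes <- apply_titration(0.50, pol50, "4mg", "8mg")
  expect_equal(response_at_w12(s_fes, p$arms$fesoterodine),
               hand_r12$fesoterodine)

  s_tol <- apply_titration(0.4947, p$titration$tolterodine, "4mg", NA)
  expect_equal(response_at_w12(s_tol, p$arms$tolterodine), hand_r12$tolterodine)

  # all conditionals zero -> zero response
  p0 <- p
  for (d in names(p0$arms$fesoterodine$doses)) {
    p0$arms$fesoterodine$doses[[d]]$cond_w12_given_w8resp <- 0
    p0$arms$fesoterodine$doses[[d]]$cond_w12_given_w8nonresp <- 0
  }
  expect_equal(response_at_w12(s_fes, p0$arms$fesoterodine), 0)

  expect_error(
    response_at_w12(data.frame(branch = "responder_stay", responder_w8 = TRUE,
                               dose = "99mg", fraction = 1),
                    p$arms$fesoterodine),
    "no efficacy data"
  )
})

test_that("the cohort engine reproduces the hand-derived checkpoint continence", {
  p <- base_params()
  pers <- p$persistence$shared
  for (arm in names(hand_r12)) {
    traj <- run_cohort(arm, p)
    r12 <- hand_r12[[arm]]
    expect_equal(traj$response_w12, r12, info = arm)
    expect_equal(continent_fraction(traj, 12), r12 * pers[["12"]], info = arm)
    expect_equal(continent_fraction(traj, 24), r12 * pers[["24"]], info = arm)
    expect_equal(continent_fraction(traj, 52), r12 * pers[["52"]], info = arm)
    # week-12 incontinent-on-treatment is the persistence remainder
    occ12 <- traj$weeks[["12"]]
    expect_equal(sum(occ12$incontinent_on_rx),
                 pers[["12"]] - r12 * pers[["12"]], info = arm)
  }
  expect_error(run_cohort("nonexistent", p), "unknown arm")
  expect_error(run_cohort("fesoterodine", p, horizon_weeks = 36), "horizon")
})

test_that("occupancy is conserved and monotone in the expected directions", {
  p <- base_params()
  for (arm in c("fesoterodine", "tolterodine", "solifenacin")) {
    traj <- run_cohort(arm, p)
    prev_untreated <- -Inf
    prev_cont <- Inf
    for (w in names(traj$weeks)) {
      occ <- traj$weeks[[w]]
      expect_equal(sum(occ$continent) + sum(occ$incontinent_on_rx) +
                     occ$untreated, 1, tolerance = 1e-12)
      expect_true(all(c(occ$continent, occ$incontinent_on_rx,
                        occ$untreated) >= 0))
      if (as.integer(w) >= 12) {
        expect_gte(occ$untreated, prev_untreated)
        expect_lte(sum(occ$continent), prev_cont + 1e-12)
        prev_untreated <- occ$untreated
        prev_cont <- sum(occ$continent)
      }
    }
  }
})

test_that("raising any response probability never lowers checkpoint continence", {
  p <- base_params()
  base <- run_cohort("fesoterodine", p)
  bump <- function(field, dose) {
    p2 <- p
    cur <- p2$arms$fesoterodine$doses[[dose]][[field]]
    p2$arms$fesoterodine$doses[[dose]][[field]] <- min(1, cur + 0.05)
    run_cohort("fesoterodine", p2)
  }
  for (field in c("cond_w12_given_w8resp", "cond_w12_given_w8nonresp")) {
    for (dose in c("4mg", "8mg")) {
      up <- bump(field, dose)
      for (w in c(12, 24, 52)) {
        expect_gte(continent_fraction(up, w), continent_fraction(base, w))
      }
    }
  }
  # week-8 response raises week-8 continence (and never lowers week 12+)
  up8 <- bump("response_w8", "4mg")
  expect_gte(continent_fraction(up8, 8), continent_fraction(base, 8))
})

test_that("single-dose arms are invariant to the titration policy", {
  p <- base_params()
  base <- run_cohort("tolterodine", p)
  p2 <- p
  p2$titration$tolterodine <- list(frac_responders_titrate = 0.8,
                                   frac_nonresponders_titrate = 0.3)
  expect_equal(run_cohort("tolterodine", p2), base)
})

test_that("dose mix tracks titration and is undefined off treatment", {
  p <- base_params()
  fes <- run_cohort("fesoterodine", p)
  expect_equal(dose_mix(fes, 12), c(`4mg` = 0.5, `8mg` = 0.5))
  expect_equal(dose_mix(fes, 52), unname(fes$weeks[["52"]]$continent) /
                 sum(fes$weeks[["52"]]$continent), ignore_attr = TRUE)

  tol <- run_cohort("tolterodine", p)
  for (w in c(8, 12, 24, 52)) {
    expect_equal(dose_mix(tol, w), c(`4mg` = 1))
  }

  empty <- make_traj(list(`12` = c(0, 0, 1), `24` = c(0, 0, 1),
                          `52` = c(0, 0, 1)))
  expect_error(dose_mix(empty, 12), "nobody on treatment")
  expect_error(dose_mix(tol, 30), "not a checkpoint")
})

test_that("trajectories export as tidy week/state/dose/fraction tables", {
  p <- base_params()
  df <- trajectory_df(run_cohort("fesoterodine", p))
  expect_named(df, c("week", "state", "dose", "fraction"))
  expect_setequal(unique(df$week), c(8L, 12L, 24L, 52L))
  sums <- tapply(df$fraction, df$week, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})
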