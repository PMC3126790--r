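# Per-patient euro cost accrual over the model horizon. All components use
# the same end-of-period convention as the QALY accrual: each period is
# valued at the occupancy of its closing checkpoint; period lengths are
# 84/84/196 days (single 84-day period at the 12-week horizon).

# Post-titration dose mix of the whole on-treatment cohort (branch split
# fractions by dose) -- the mix in force from week 4 until the week-12 gate.
split_dose_mix <- function(split) {
  doses <- unique(split$dose)
  mix <- vapply(doses, function(d) sum(split$fraction[split$dose == d]),
                numeric(1))
  mix / sum(mix)
}

# Dose-mix-weighted average of a per-dose quantity.
mix_weighted <- function(mix, per_dose) {
  sum(mix * vapply(names(mix), function(d) per_dose[[d]], numeric(1)))
}

drug_price_per_day <- function(params, arm_id) {
  prices <- params$unit_costs$drug_per_day[[arm_id]]
  if (is.null(prices)) {
    stop("no drug price for arm '", arm_id, "'", call. = FALSE)
  }
  prices
}

#' Drug acquisition cost over the horizon
#'
#' Days 0-28 are costed at the start dose, days 28 to the end of the first
#' period at the post-titration dose mix, and later periods at the surviving
#' responders' dose mix, each period weighted by its closing on-treatment
#' occupancy.
#'
#' @param traj An `oab_trajectory`.
#' @param params An `oab_parameters` object.
#' @return Euro cost per patient started.
#' @export
drug_cost <- function(traj, params) {
  arm_id <- traj$arm_id
  prices <- drug_price_per_day(params, arm_id)
  start_dose <- params$arms[[arm_id]]$start_dose
  if (is.null(prices[[start_dose]])) {
    stop("no drug price for dose '", start_dose, "'", call. = FALSE)
  }
  pw <- period_weights(traj$horizon_weeks)
  mix1 <- split_dose_mix(traj$split)
  for (d in names(mix1)) {
    if (is.null(prices[[d]])) {
      stop("no drug price for dose '", d, "'", call. = FALSE)
    }
  }
  total <- 0
  for (i in seq_len(nrow(pw))) {
    week <- pw$week_end[i]
    occ <- status_occupancy(traj, week)
    on_rx <- occ[["controlled"]] + occ[["uncontrolled_on_rx"]]
    if (on_rx <= 0) next
    if (i == 1L) {
      price_mix <- mix_weighted(mix1, prices)
      total <- total + on_rx *
        (28 * prices[[start_dose]] + (pw$days[i] - 28) * price_mix)
    } else {
      mix <- dose_mix(traj, week)
      total <- total + on_rx * pw$days[i] * mix_weighted(mix, prices)
    }
  }
  total
}

#' Pads, physician-visit and laboratory costs over the horizon
#'
#' Status-conditional utilization rates priced at unit costs: pads per day
#' (fraction using pads x pads/day x pad price) and per-month visit/lab
#' counts (a month is 1/12 of the 364-day model year).
#'
#' @inheritParams drug_cost
#' @return List with components `pads` and `visits_labs` (euros).
#' @export
resource_cost <- function(traj, params) {
  ru <- params$resource_use
  uc <- params$unit_costs
  pw <- period_weights(traj$horizon_weeks)
  pads <- 0
  visits <- 0
  daily_pads <- vapply(OAB_STATUSES, function(s) {
    ru[[s]]$frac_using_pads * ru[[s]]$pads_per_day * uc$pad
  }, numeric(1))
  monthly_visits <- vapply(OAB_STATUSES, function(s) {
    ru[[s]]$gp_visits_per_month * uc$gp_visit +
      ru[[s]]$specialist_visits_per_month * uc$specialist_visit +
      ru[[s]]$lab_tests_per_month * uc$lab_test
  }, numeric(1))
  for (i in seq_len(nrow(pw))) {
    occ <- status_occupancy(traj, pw$week_end[i])
    months <- pw$days[i] / 364 * 12
    pads <- pads + pw$days[i] * sum(occ * daily_pads)
    visits <- visits + months * sum(occ * monthly_visits)
  }
  list(pads = pads, visits_labs = visits)
}

#' Comorbidity costs over the horizon, by condition
#'
#' Occupancy-weighted annual event rates priced at unit costs and scaled by
#' period year-fractions. Fracture uses the 6-month fall-with-fracture
#' probability, skin infections and urinary tract infections their expected
#' events per person (all annualized x2 under the `annualize_six_month`
#' convention), depression its annual probability times the per-patient-year
#' cost, and nursing home the admissions per 1000 patient-years times the
#' per-admitted-patient-year cost.
#'
#' @inheritParams drug_cost
#' @return List with components `fracture`, `skin`, `uti`, `depression` and
#'   `nursing_home` (euros).
#' @export
comorbidity_cost <- function(traj, params) {
  uc <- params$unit_costs
  k <- if (isTRUE(params$conventions$annualize_six_month)) 2 else 1
  annual_rate <- function(cond) {
    vapply(OAB_STATUSES, function(s) {
      cm <- params$comorbidity[[s]]
      switch(cond,
        fracture = cm$fracture_prob_6mo * k,
        skin = cm$skin_events_per_person * k,
        uti = cm$uti_events_per_person * k,
        depression = cm$depression_prob_annual,
        nursing_home = cm$nursing_home_admissions_per_1000py / 1000
      )
    }, numeric(1))
  }
  unit <- c(
    fracture = uc$fracture_event,
    skin = uc$skin_infection_episode,
    uti = uc$uti_episode,
    depression = uc$depression_per_patient_year,
    nursing_home = uc$nursing_home
  )
  pw <- period_weights(traj$horizon_weeks)
  out <- list(fracture = 0, skin = 0, uti = 0, depression = 0,
              nursing_home = 0)
  for (i in seq_len(nrow(pw))) {
    occ <- status_occupancy(traj, pw$week_end[i])
    yf <- pw$year_fraction[i]
    for (cond in names(out)) {
      out[[cond]] <- out[[cond]] +
        yf * sum(occ * annual_rate(cond)) * unit[[cond]]
    }
  }
  out
}

#' Constipation management cost over the horizon
#'
#' Accrues the per-day constipation cost times the dose-specific constipation
#' rate over on-treatment days (start dose for days 0-28, post-titration mix
#' thereafter, survivor mix in later periods).
#'
#' @inheritParams drug_cost
#' @return Euro cost per patient started.
#' @export
constipation_cost <- function(traj, params) {
  arm <- params$arms[[traj$arm_id]]
  rate <- lapply(arm$doses, function(d) d$constipation_rate)
  cpd <- params$unit_costs$constipation_per_day
  pw <- period_weights(traj$horizon_weeks)
  mix1 <- split_dose_mix(traj$split)
  total <- 0
  for (i in seq_len(nrow(pw))) {
    occ <- status_occupancy(traj, pw$week_end[i])
    on_rx <- occ[["controlled"]] + occ[["uncontrolled_on_rx"]]
    if (on_rx <= 0) next
    if (i == 1L) {
      total <- total + on_rx * cpd *
        (28 * rate[[arm$start_dose]] +
           (pw$days[i] - 28) * mix_weighted(mix1, rate))
    } else {
      mix <- dose_mix(traj, pw$week_end[i])
      total <- total + on_rx * pw$days[i] * cpd * mix_weighted(mix, rate)
    }
  }
  total
}

#' Productivity cost relative to no treatment (a gain, so non-positive)
#'
#' Two channels, both avoided losses versus an all-untreated cohort valued at
#' the employment-adjusted wage: incontinent patients work 21.1% fewer hours
#' (avoided by continent occupancy), and patients with baseline nocturia who
#' are nocturia-free on therapy recover a 9.2% daytime work impairment
#' (accrues to on-treatment occupancy, weighted by the dose-specific
#' week-12 nocturia resolution).
#'
#' @inheritParams drug_cost
#' @return Euro amount, `<= 0` (zero for an all-untreated trajectory or when
#'   nobody is employed).
#' @export
productivity_cost <- function(traj, params) {
  pr <- params$productivity
  arm <- params$arms[[traj$arm_id]]
  wage_week <- pr$hours_per_week * pr$wage_per_hour * pr$frac_employed
  rate_incont <- pr$incontinence_hours_reduction * wage_week
  noct_res <- lapply(arm$doses, function(d) d$nocturia_resolution_w12)
  pw <- period_weights(traj$horizon_weeks)
  mix1 <- split_dose_mix(traj$split)
  gain <- 0
  for (i in seq_len(nrow(pw))) {
    occ <- status_occupancy(traj, pw$week_end[i])
    on_rx <- occ[["controlled"]] + occ[["uncontrolled_on_rx"]]
    weeks <- pw$days[i] / 7
    gain <- gain + occ[["controlled"]] * weeks * rate_incont
    if (on_rx > 0) {
      mix <- if (i == 1L) mix1 else dose_mix(traj, pw$week_end[i])
      rate_noct <- pr$baseline_nocturia_prevalence *
        mix_weighted(mix, noct_res) * pr$nocturia_impairment * wage_week
      gain <- gain + on_rx * weeks * rate_noct
    }
  }
  -gain
}

#' Full cost breakdown of a trajectory
#'
#' Assembles every component: drug, pads, visits and labs, constipation
#' management, the five comorbidities, and productivity. The payer total sums
#' the direct components; the societal total adds the (non-positive)
#' productivity component.
#'
#' @inheritParams drug_cost
#' @param perspective `"societal"` or `"payer"`; selects which total `total`
#'   reports (both totals are always present).
#' @return An `oab_cost_breakdown`: named list of euro components plus
#'   `total_payer`, `total_societal`, `total` and `perspective`.
#' @export
total_cost <- function(traj, params,
                       perspective = params$conventions$perspective) {
  perspective <- match.arg(perspective, c("societal", "payer"))
  res <- resource_cost(traj, params)
  com <- comorbidity_cost(traj, params)
  out <- list(
    drug = drug_cost(traj, params),
    pads = res$pads,
    visits_labs = res$visits_labs,
    constipation = constipation_cost(traj, params),
    fracture = com$fracture,
    skin = com$skin,
    uti = com$uti,
    depression = com$depression,
    nursing_home = com$nursing_home,
    productivity = productivity_cost(traj, params)
  )
  direct <- c("drug", "pads", "visits_labs", "constipation", "fracture",
              "skin", "uti", "depression", "nursing_home")
  out$total_payer <- sum(unlist(out[direct]))
  out$total_societal <- out$total_payer + out$productivity
  out$total <- if (perspective == "societal") out$total_societal else out$total_payer
  out$perspective <- perspective
  class(out) <- "oab_cost_breakdown"
  out
}

#' Cost breakdown as a one-row data frame
#'
#' @param cost An `oab_cost_breakdown` from [total_cost()].
#' @return Data frame with one column per component and total.
#' @export
cost_breakdown_df <- function(cost) {
  as.data.frame(cost[setdiff(names(cost), "perspective")])
}

#' @export
print.oab_cost_breakdown <- function(x, ...) {
  cat(sprintf("<oab_cost_breakdown: %s perspective>\n", x$perspective))
  comp <- setdiff(names(x), c("total", "perspective"))
  for (k in comp) cat(sprintf("  %-15s %10.2f EUR\n", k, x[[k]]))
  invisible(x)
}
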