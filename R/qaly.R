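# QALY accrual from health-state utilities. Gains are measured against the
# all-untreated baseline utility; the untreated state therefore contributes
# zero by construction.

#' Accrual periods and their year-fraction weights
#'
#' The 52-week horizon is split into (0, 12], (12, 24] and (24, 52] weeks;
#' each period is valued at the occupancy of its closing checkpoint
#' (end-of-period convention). The 12-week horizon has a single period.
#'
#' @param horizon_weeks 12 or 52.
#' @return Data frame with columns `week_end`, `weeks`, `days` and
#'   `year_fraction` (weeks/52). Year fractions sum to the horizon in years.
#' @export
period_weights <- function(horizon_weeks) {
  if (horizon_weeks == 52L) {
    df <- data.frame(week_end = c(12L, 24L, 52L), weeks = c(12, 12, 28))
  } else if (horizon_weeks == 12L) {
    df <- data.frame(week_end = 12L, weeks = 12)
  } else {
    stop("horizon must be 12 or 52 weeks", call. = FALSE)
  }
  df$days <- df$weeks * 7
  df$year_fraction <- df$weeks / 52
  df
}

#' State utilities with optional comorbidity decrements
#'
#' Returns the utility of each model state. With decrements disabled (the
#' default convention) the published state utilities are returned unchanged.
#' With decrements enabled each state's utility is multiplied by
#' `1 - sum(annual probability x decrement)` over fracture, depression and
#' nursing-home admission, using that state's comorbidity rates (6-month
#' fracture probabilities annualized per the `annualize_six_month`
#' convention; nursing-home admissions per 1000 patient-years).
#'
#' @param params An `oab_parameters` object.
#' @param decrements_enabled Override of the parameter set's convention.
#' @return Named numeric vector with elements `continent`,
#'   `incontinent_on_rx` and `untreated`.
#' @export
effective_state_utilities <- function(params,
                                      decrements_enabled =
                                        params$conventions$decrements_enabled) {
  u <- c(
    continent = params$utilities$u_continent,
    incontinent_on_rx = params$utilities$u_incontinent_on_rx,
    untreated = params$utilities$u_untreated
  )
  if (!isTRUE(decrements_enabled)) {
    return(u)
  }
  k <- if (isTRUE(params$conventions$annualize_six_month)) 2 else 1
  dec <- params$comorbidity$utility_decrements
  status_of <- c(continent = "controlled",
                 incontinent_on_rx = "uncontrolled_on_rx",
                 untreated = "untreated")
  out <- u
  for (state in names(u)) {
    cm <- params$comorbidity[[status_of[[state]]]]
    burden <- cm$fracture_prob_6mo * k * dec$fracture +
      cm$depression_prob_annual * dec$depression +
      cm$nursing_home_admissions_per_1000py / 1000 * dec$nursing_home
    out[state] <- u[state] * (1 - burden)
    if (out[state] < 0 || out[state] > 1) {
      stop(sprintf("decremented utility for state %s outside [0, 1]", state),
           call. = FALSE)
    }
  }
  out
}

#' QALY gain of a trajectory versus the untreated baseline
#'
#' Accrues `occupancy x (u_state - u_untreated)` over the horizon's periods,
#' each valued at its closing checkpoint's occupancy (during the first
#' period week-12 non-responders are still on therapy in the
#' incontinent-on-treatment state). QALYs are undiscounted.
#'
#' @param traj An `oab_trajectory`.
#' @param params An `oab_parameters` object.
#' @param decrements_enabled Override of the decrement convention.
#' @return QALY gain in years (0 for an all-untreated trajectory).
#' @export
qaly_gain <- function(traj, params,
                      decrements_enabled =
                        params$conventions$decrements_enabled) {
  eu <- effective_state_utilities(params, decrements_enabled)
  pw <- period_weights(traj$horizon_weeks)
  gain <- 0
  for (i in seq_len(nrow(pw))) {
    occ <- status_occupancy(traj, pw$week_end[i])
    gain <- gain + pw$year_fraction[i] * (
      occ[["controlled"]] * (eu[["continent"]] - eu[["untreated"]]) +
        occ[["uncontrolled_on_rx"]] *
          (eu[["incontinent_on_rx"]] - eu[["untreated"]])
    )
  }
  gain
}

#' Absolute QALY accrual of a trajectory
#'
#' The gain of [qaly_gain()] plus the baseline accrual
#' `horizon_years x u_untreated`.
#'
#' @inheritParams qaly_gain
#' @return QALYs accrued over the horizon.
#' @export
qaly_absolute <- function(traj, params,
                          decrements_enabled =
                            params$conventions$decrements_enabled) {
  eu <- effective_state_utilities(params, decrements_enabled)
  qaly_gain(traj, params, decrements_enabled) +
    (traj$horizon_weeks / 52) * eu[["untreated"]]
}
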