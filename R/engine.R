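# Cohort decision-tree engine: week-4 titration (week-8 trial data as proxy),
# week-12 responder gate, persistence-driven attrition to week 52 under last
# observation carried forward.

#' Split a cohort at the week-4 titration decision
#'
#' Splits a unit cohort by week-8-proxy response and the titration policy into
#' up to four branches (responder/non-responder x stay/titrate), each tagged
#' with the dose taken from week 4 onward. Single-dose arms have no higher
#' dose to titrate to; the policy is ignored and the split collapses to two
#' branches on the start dose.
#'
#' @param response_w8proxy Week-8 response probability at the start dose,
#'   used as the proxy for the week-4 assessment.
#' @param policy List with `frac_responders_titrate` and
#'   `frac_nonresponders_titrate` (fractions of each group moving to the
#'   higher dose).
#' @param start_dose,high_dose Dose labels; `high_dose` may be `NA` when the
#'   arm has a single dose.
#' @return A data frame (class `oab_branch_split`) with columns `branch`,
#'   `responder_w8` (logical), `dose` and `fraction`; fractions sum to 1.
#' @export
apply_titration <- function(response_w8proxy, policy, start_dose,
                            high_dose = NA_character_) {
  stopifnot(response_w8proxy >= 0, response_w8proxy <= 1)
  fr <- policy$frac_responders_titrate
  fn <- policy$frac_nonresponders_titrate
  stopifnot(fr >= 0, fr <= 1, fn >= 0, fn <= 1)
  if (is.na(high_dose)) {
    # no higher dose to titrate to: the policy is irrelevant
    fr <- 0
    fn <- 0
  }
  p <- response_w8proxy
  split <- data.frame(
    branch = c("responder_stay", "responder_titrate",
               "nonresponder_stay", "nonresponder_titrate"),
    responder_w8 = c(TRUE, TRUE, FALSE, FALSE),
    dose = c(start_dose, high_dose, start_dose, high_dose),
    fraction = c(p * (1 - fr), p * fr, (1 - p) * (1 - fn), (1 - p) * fn),
    stringsAsFactors = FALSE
  )
  # single-dose arms: drop the (zero-fraction) titrate branches
  split <- split[!is.na(split$dose), ]
  rownames(split) <- NULL
  class(split) <- c("oab_branch_split", class(split))
  split
}

#' Pre-attrition week-12 response probability of a branched cohort
#'
#' Sums branch fractions weighted by the dose-specific week-12 response
#' conditionals: responder branches use the week-12-given-week-8-response
#' conditional, non-responder branches the week-12-given-week-8-non-response
#' conditional, each at the branch's dose.
#'
#' @param split A branch split from [apply_titration()].
#' @param eff An arm efficacy entry (`params$arms[[arm]]`), whose `doses`
#'   must cover every dose present in the split.
#' @return Probability of being a responder at week 12 (before attrition).
#' @export
response_at_w12 <- function(split, eff) {
  conds <- mapply(function(dose, resp) {
    dd <- eff$doses[[dose]]
    if (is.null(dd)) {
      stop("no efficacy data for dose '", dose, "' in arm '", eff$arm_id, "'",
           call. = FALSE)
    }
    if (resp) dd$cond_w12_given_w8resp else dd$cond_w12_given_w8nonresp
  }, split$dose, split$responder_w8)
  sum(split$fraction * conds)
}

#' Run the cohort decision tree for one arm
#'
#' Propagates a unit cohort through the decision tree: week-4 titration using
#' week-8 data as proxy, week-12 responder assessment via the conditional
#' response columns, discontinuation of week-12 non-responders, and
#' proportional persistence-driven attrition of responders to weeks 24 and 52
#' with response carried forward. Checkpoint occupancies (continent on
#' therapy by dose, incontinent on therapy by dose, untreated) sum to 1.
#'
#' @param arm_id Arm name (must exist in `params$arms`).
#' @param params An `oab_parameters` object.
#' @param horizon_weeks 12 or 52; defaults to the parameter set's convention.
#' @return An `oab_trajectory` object: list with `arm_id`, `horizon_weeks`,
#'   `split` (the branch split), `response_w12` (pre-attrition week-12
#'   response), and `weeks`, a list keyed by checkpoint week, each element
#'   holding `continent` and `incontinent_on_rx` (named by dose) and
#'   `untreated`.
#' @export
run_cohort <- function(arm_id, params,
                       horizon_weeks = params$conventions$horizon_weeks) {
  arm <- params$arms[[arm_id]]
  if (is.null(arm)) stop("unknown arm: ", arm_id, call. = FALSE)
  if (!horizon_weeks %in% c(12L, 52L)) {
    stop("horizon must be 12 or 52 weeks", call. = FALSE)
  }
  pers <- params$persistence$shared
  needed <- as.character(c(12L, if (horizon_weeks == 52L) c(24L, 52L)))
  if (!all(needed %in% names(pers))) {
    stop("persistence curve lacks checkpoint(s): ",
         paste(setdiff(needed, names(pers)), collapse = ", "), call. = FALSE)
  }

  p8 <- arm$doses[[arm$start_dose]]$response_w8
  split <- apply_titration(p8, params$titration[[arm_id]],
                           arm$start_dose, arm$high_dose)
  r12 <- response_at_w12(split, arm)

  doses <- unique(split$dose)
  # per-dose pre-attrition responder fractions at week 12
  resp12_by_dose <- vapply(doses, function(d) {
    rows <- split[split$dose == d, , drop = FALSE]
    conds <- ifelse(rows$responder_w8,
                    vapply(rows$dose, function(x) arm$doses[[x]]$cond_w12_given_w8resp, numeric(1)),
                    vapply(rows$dose, function(x) arm$doses[[x]]$cond_w12_given_w8nonresp, numeric(1)))
    sum(rows$fraction * conds)
  }, numeric(1))
  dose_frac <- vapply(doses, function(d) {
    sum(split$fraction[split$dose == d])
  }, numeric(1))
  # optional week-12 response scaling (sensitivity analysis); per-dose
  # responder fractions are capped at the dose occupancy
  s12 <- params$conventions$w12_response_scale
  if (!is.null(s12) && s12 != 1) {
    scaled <- resp12_by_dose * s12
    if (any(scaled > dose_frac + 1e-12)) {
      warning("scaled week-12 response capped at dose occupancy for arm ",
              arm_id)
      scaled <- pmin(scaled, dose_frac)
    }
    resp12_by_dose <- scaled
    r12 <- sum(resp12_by_dose)
  }
  nonresp12_by_dose <- dose_frac - resp12_by_dose

  pers8 <- params$persistence$week8_by_arm[[arm_id]]
  if (is.null(pers8) || is.na(pers8)) pers8 <- pers[["8"]]

  weeks <- list()
  # Week 8: cohort is post-titration (titration happens at week 4); status is
  # the week-8 response at the (proxy-assessed) start dose.
  resp8_by_dose <- vapply(doses, function(d) {
    sum(split$fraction[split$dose == d & split$responder_w8])
  }, numeric(1))
  nonresp8_by_dose <- vapply(doses, function(d) {
    sum(split$fraction[split$dose == d & !split$responder_w8])
  }, numeric(1))
  weeks[["8"]] <- list(
    continent = resp8_by_dose * pers8,
    incontinent_on_rx = nonresp8_by_dose * pers8,
    untreated = 1 - pers8
  )
  # Week 12: responder gate applied; non-responders still on therapy during
  # the first accrual period, so incontinent-on-rx = persistence - continent.
  p12 <- pers[["12"]]
  weeks[["12"]] <- list(
    continent = resp12_by_dose * p12,
    incontinent_on_rx = nonresp12_by_dose * p12,
    untreated = 1 - p12
  )
  if (horizon_weeks == 52L) {
    # Weeks 24/52: only week-12 responders remain on therapy; attrition is
    # proportional across doses; leavers become untreated.
    for (w in c("24", "52")) {
      cont <- resp12_by_dose * pers[[w]]
      weeks[[w]] <- list(
        continent = cont,
        incontinent_on_rx = setNames(rep(0, length(doses)), doses),
        untreated = 1 - sum(cont)
      )
    }
  }

  structure(
    list(
      arm_id = arm_id,
      horizon_weeks = as.integer(horizon_weeks),
      split = split,
      response_w12 = r12,
      persistence_week8 = pers8,
      weeks = weeks
    ),
    class = "oab_trajectory"
  )
}

#' Continent fraction at a checkpoint
#'
#' @param traj An `oab_trajectory`.
#' @param week A checkpoint week present in the trajectory (8, 12, 24 or 52).
#' @return Total fraction of the cohort continent on therapy at that week.
#' @export
continent_fraction <- function(traj, week) {
  w <- as.character(week)
  if (!w %in% names(traj$weeks)) {
    stop("week ", week, " is not a checkpoint of this trajectory",
         call. = FALSE)
  }
  sum(traj$weeks[[w]]$continent)
}

#' Dose mix among on-treatment patients at a checkpoint
#'
#' @param traj An `oab_trajectory`.
#' @param week A checkpoint week.
#' @return Named vector of dose fractions among patients on therapy (sums
#'   to 1). Errors when nobody is on therapy at that week.
#' @export
dose_mix <- function(traj, week) {
  w <- as.character(week)
  if (!w %in% names(traj$weeks)) {
    stop("week ", week, " is not a checkpoint of this trajectory",
         call. = FALSE)
  }
  on_rx <- traj$weeks[[w]]$continent + traj$weeks[[w]]$incontinent_on_rx
  total <- sum(on_rx)
  if (total <= 0) {
    stop("dose mix undefined: nobody on treatment at week ", week,
         call. = FALSE)
  }
  on_rx / total
}

#' Trajectory as a tidy data frame
#'
#' @param traj An `oab_trajectory`.
#' @return Data frame with columns `week`, `state`, `dose` and `fraction`
#'   (dose is `NA` for the untreated state).
#' @export
trajectory_df <- function(traj) {
  rows <- lapply(names(traj$weeks), function(w) {
    occ <- traj$weeks[[w]]
    doses <- names(occ$continent)
    rbind(
      data.frame(week = as.integer(w), state = "continent_on_rx",
                 dose = doses, fraction = unname(occ$continent),
                 stringsAsFactors = FALSE),
      data.frame(week = as.integer(w), state = "incontinent_on_rx",
                 dose = doses, fraction = unname(occ$incontinent_on_rx),
                 stringsAsFactors = FALSE),
      data.frame(week = as.integer(w), state = "untreated",
                 dose = NA_character_, fraction = occ$untreated,
                 stringsAsFactors = FALSE)
    )
  })
  do.call(rbind, rows)
}

# Occupancy by model status (controlled / uncontrolled_on_rx / untreated) at
# a checkpoint week.
status_occupancy <- function(traj, week) {
  occ <- traj$weeks[[as.character(week)]]
  c(
    controlled = sum(occ$continent),
    uncontrolled_on_rx = sum(occ$incontinent_on_rx),
    untreated = occ$untreated
  )
}

#' @export
print.oab_trajectory <- function(x, ...) {
  cat(sprintf("<oab_trajectory: %s, %d weeks>\n", x$arm_id, x$horizon_weeks))
  cat(sprintf("  week-12 response (pre-attrition): %.4f\n", x$response_w12))
  for (w in names(x$weeks)) {
    occ <- x$weeks[[w]]
    cat(sprintf("  week %2s: continent %.4f, incontinent-on-rx %.4f, untreated %.4f\n",
                w, sum(occ$continent), sum(occ$incontinent_on_rx),
                occ$untreated))
  }
  invisible(x)
}
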