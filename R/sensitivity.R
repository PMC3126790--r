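# One-way (tornado) sensitivity analysis: +/-25% perturbations of named
# parameter groups, horizon switch (52 -> 12 weeks) and perspective switch
# (societal -> payer), re-running the full pipeline per scenario.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define a sensitivity scenario
#'
#' @param name Scenario label (base case first in the default grid).
#' @param kind One of `"base"`, `"structural"` (horizon/perspective switch),
#'   `"multiplier"` (multiply the values at `paths`), `"nontitrate"`
#'   (multiply the *not*-titrating non-responder fraction), `"continence_w12"`
#'   (scale the week-12 response conditionals of every arm),
#'   `"continence_w52"` (scale week-52 persistence) or `"utility_gain"`
#'   (scale the baseline-anchored state-utility increments).
#' @param paths Character vector of dot-separated parameter paths (for
#'   `"multiplier"`), e.g. `"unit_costs.fracture_event"`.
#' @param factor Multiplicative factor (0.75 or 1.25 in the published grid).
#' @param clamp Clamp perturbed probabilities to \[0, 1\] (with a warning)
#'   rather than rejecting them.
#' @param horizon,perspective Structural overrides (`NULL` keeps the
#'   parameter set's conventions).
#' @return An `oab_scenario` list.
#' @export
scenario <- function(name, kind = "multiplier", paths = character(),
                     factor = 1, clamp = FALSE, horizon = NULL,
                     perspective = NULL) {
  structure(
    list(name = name, kind = kind, paths = paths, factor = factor,
         clamp = clamp, horizon = horizon, perspective = perspective),
    class = "oab_scenario"
  )
}

# Multiply the numeric leaf at a dot path, optionally clamping to [0, 1].
perturb_path <- function(params, path, factor, clamp) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    if (is.null(node[[k]])) {
      stop("unresolvable parameter path: ", path, call. = FALSE)
    }
    node <- node[[k]]
  }
  x <- node * factor
  # clamp applies to probability-like leaves only (counts and rates above 1,
  # e.g. admissions per 1000 patient-years, are never clamped)
  if (clamp && node <= 1 && (x > 1 || x < 0)) {
    warning(sprintf("perturbed value at %s clamped to [0, 1] (was %.4f)",
                    path, x))
    x <- min(1, max(0, x))
  }
  params[[keys]] <- x
  params
}

clamp01 <- function(x, what) {
  if (x > 1 || x < 0) {
    warning(sprintf("perturbed %s clamped to [0, 1] (was %.4f)", what, x))
    x <- min(1, max(0, x))
  }
  x
}

#' Apply a scenario's perturbation to a parameter set
#'
#' Pure: the input parameter set is never modified. Structural switches are
#' recorded in the returned set's conventions.
#'
#' @param params An `oab_parameters` object.
#' @param sc An `oab_scenario`.
#' @return The perturbed `oab_parameters`.
#' @export
apply_scenario <- function(params, sc) {
  out <- params
  if (!is.null(sc$horizon)) out$conventions$horizon_weeks <- sc$horizon
  if (!is.null(sc$perspective)) out$conventions$perspective <- sc$perspective
  f <- sc$factor
  switch(sc$kind,
    base = ,
    structural = out,
    multiplier = {
      for (p in sc$paths) out <- perturb_path(out, p, f, sc$clamp)
      out
    },
    nontitrate = {
      # "+/-25% in % of non-responders that do NOT titrate": perturb the
      # complement of the titrating fraction.
      for (arm_id in sc$paths) {
        cur <- out$titration[[arm_id]]$frac_nonresponders_titrate
        stay <- clamp01((1 - cur) * f,
                        paste0("titration.", arm_id, ".non-titrating fraction"))
        out$titration[[arm_id]]$frac_nonresponders_titrate <- 1 - stay
      }
      out
    },
    continence_w12 = scale_week12_response(out, f),
    continence_w52 = {
      p52 <- out$persistence$shared[["52"]]
      x <- clamp01(p52 * f, "persistence.shared.52")
      # keep the curve non-increasing
      out$persistence$shared[["52"]] <- min(x, out$persistence$shared[["24"]])
      out
    },
    utility_gain = {
      u <- out$utilities
      out$utilities$u_continent <-
        clamp01(u$u_untreated + f * (u$u_continent - u$u_untreated),
                "utilities.u_continent")
      out$utilities$u_incontinent_on_rx <-
        clamp01(u$u_untreated + f * (u$u_incontinent_on_rx - u$u_untreated),
                "utilities.u_incontinent_on_rx")
      out
    },
    stop("unknown scenario kind: ", sc$kind, call. = FALSE)
  )
}

#' Scale the week-12 response of every arm
#'
#' Records a multiplicative scale on the pre-attrition week-12 responder
#' fraction of every arm, applied by the cohort engine (and the
#' microsimulation oracle) at the responder gate: each dose's responder
#' fraction is multiplied by `factor` and capped at that dose's occupancy
#' (equivalently, the per-dose response *rate* is capped at 1, with a
#' warning when the cap binds). All arms are perturbed together, so below
#' the cap each arm's week-12 continence scales by exactly `factor` and the
#' between-arm comparison is not distorted by arm-specific clamping.
#'
#' @param params An `oab_parameters` object.
#' @param factor Positive multiplicative factor.
#' @return The perturbed `oab_parameters` (scale recorded in
#'   `conventions$w12_response_scale`).
#' @export
scale_week12_response <- function(params, factor) {
  stopifnot(factor > 0)
  out <- params
  out$conventions$w12_response_scale <-
    (out$conventions$w12_response_scale %||% 1) * factor
  out
}

#' The published univariate scenario grid
#'
#' Base case first, then the structural rows (payer perspective, 12-week
#' horizon) and every +/-25% perturbation row of the published grid, with
#' each +/- pair expanded into its two directions.
#'
#' @param factors The two multiplicative factors of each pair.
#' @return List of `oab_scenario` objects.
#' @export
default_scenarios <- function(factors = c(0.75, 1.25)) {
  titration_arms <- c("fesoterodine", "solifenacin")
  pair <- function(name, ...) {
    lapply(factors, function(f) {
      sc <- scenario(sprintf("%s (x%.2f)", name, f), factor = f, ...)
      sc
    })
  }
  statuses_inc <- c("uncontrolled_on_rx", "untreated")
  comorb_fields <- c("fracture_prob_6mo", "skin_prob_6mo",
                     "skin_events_per_person", "uti_prob_6mo",
                     "uti_events_per_person", "depression_prob_annual",
                     "nursing_home_admissions_per_1000py")
  sc <- c(
    list(
      scenario("Base case (52 weeks, societal)", kind = "base"),
      scenario("52 weeks, payer perspective", kind = "structural",
               perspective = "payer"),
      scenario("12 weeks, payer perspective", kind = "structural",
               horizon = 12L, perspective = "payer"),
      scenario("12 weeks, societal perspective", kind = "structural",
               horizon = 12L)
    ),
    pair("Comorbidity costs",
         paths = paste0("unit_costs.",
                        c("fracture_event", "skin_infection_episode",
                          "uti_episode", "depression_per_patient_year",
                          "nursing_home"))),
    pair("Comorbidity rates, continent patients", clamp = TRUE,
         paths = paste0("comorbidity.controlled.", comorb_fields)),
    pair("Comorbidity rates, incontinent patients", clamp = TRUE,
         paths = as.vector(outer(paste0("comorbidity.", statuses_inc, "."),
                                 comorb_fields, paste0))),
    pair("Utility estimates", kind = "utility_gain"),
    pair("% responders titrating at week 4", clamp = TRUE,
         paths = paste0("titration.", titration_arms,
                        ".frac_responders_titrate")),
    pair("% non-responders not titrating at week 4", kind = "nontitrate",
         paths = titration_arms),
    pair("% continent at week 12", kind = "continence_w12"),
    pair("% continent at week 52", kind = "continence_w52"),
    pair("Medical services costs",
         paths = paste0("unit_costs.",
                        c("pad", "gp_visit", "specialist_visit", "lab_test",
                          "constipation_per_day"))),
    pair("% incontinent patients using pads", clamp = TRUE,
         paths = paste0("resource_use.", statuses_inc, ".frac_using_pads")),
    pair("Pads per day, incontinent patients",
         paths = paste0("resource_use.", statuses_inc, ".pads_per_day")),
    pair("GP visits per month",
         paths = paste0("resource_use.", OAB_STATUSES, ".gp_visits_per_month")),
    pair("Specialist visits per month",
         paths = paste0("resource_use.", OAB_STATUSES,
                        ".specialist_visits_per_month")),
    pair("Lab tests per month",
         paths = paste0("resource_use.", OAB_STATUSES, ".lab_tests_per_month")),
    pair("Decrease in hours worked due to incontinence", clamp = TRUE,
         paths = "productivity.incontinence_hours_reduction"),
    pair("Reduced daytime productivity due to nocturia", clamp = TRUE,
         paths = "productivity.nocturia_impairment"),
    pair("% employed", clamp = TRUE, paths = "productivity.frac_employed"),
    pair("Average hourly wage", paths = "productivity.wage_per_hour")
  )
  sc
}

#' Run one sensitivity scenario
#'
#' Re-runs the full pipeline (trajectories, QALYs, costs, pairwise CEA of
#' fesoterodine against both comparators) on the perturbed parameter set.
#' The base parameter set is left unmodified.
#'
#' @param params An `oab_parameters` object (the base case).
#' @param sc An `oab_scenario`.
#' @param reference_arm,comparator_arms Arms compared (reference vs each
#'   comparator).
#' @return List with the scenario `name`, effective `horizon_weeks` and
#'   `perspective`, per-arm `outcomes` (cost/QALY data frame) and `results`,
#'   a named list of `oab_cea_result` (one per comparator).
#' @export
run_scenario <- function(params, sc,
                         reference_arm = "fesoterodine",
                         comparator_arms = c("tolterodine", "solifenacin")) {
  p <- apply_scenario(params, sc)
  horizon <- p$conventions$horizon_weeks
  persp <- p$conventions$perspective
  arms <- c(reference_arm, comparator_arms)
  outcomes <- lapply(arms, function(a) {
    traj <- run_cohort(a, p, horizon)
    cost <- total_cost(traj, p, persp)
    list(arm = a, cost = cost$total, qaly = qaly_gain(traj, p))
  })
  names(outcomes) <- arms
  wtp <- p$conventions$wtp_per_qaly
  results <- lapply(comparator_arms, function(a) {
    cea_compare(outcomes[[reference_arm]]$cost, outcomes[[reference_arm]]$qaly,
                outcomes[[a]]$cost, outcomes[[a]]$qaly,
                reference_arm, a, wtp = wtp)
  })
  names(results) <- comparator_arms
  list(
    name = sc$name,
    horizon_weeks = horizon,
    perspective = persp,
    outcomes = do.call(rbind, lapply(outcomes, function(o) {
      data.frame(arm = o$arm, cost = o$cost, qaly_gain = o$qaly,
                 stringsAsFactors = FALSE)
    })),
    results = results
  )
}

#' Tornado table over a scenario list
#'
#' @param params Base-case `oab_parameters`.
#' @param scenarios List of `oab_scenario` objects (default: the published
#'   grid via [default_scenarios()]).
#' @inheritParams run_scenario
#' @return Data frame, one row per scenario x comparator, with columns
#'   `scenario`, `horizon_weeks`, `perspective`, `comparator`, `delta_cost`,
#'   `delta_qaly`, `icer` (`NA` under dominance), `label`, `display` and
#'   `threshold_pass`, in the scenario list's order.
#' @export
tornado <- function(params, scenarios = default_scenarios(),
                    reference_arm = "fesoterodine",
                    comparator_arms = c("tolterodine", "solifenacin")) {
  rows <- lapply(scenarios, function(sc) {
    run <- run_scenario(params, sc, reference_arm, comparator_arms)
    do.call(rbind, lapply(comparator_arms, function(a) {
      r <- run$results[[a]]
      data.frame(
        scenario = run$name,
        horizon_weeks = run$horizon_weeks,
        perspective = run$perspective,
        comparator = a,
        delta_cost = r$delta_cost,
        delta_qaly = r$delta_qaly,
        icer = r$icer,
        label = r$label,
        display = icer_display(r),
        threshold_pass = r$threshold_pass,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
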