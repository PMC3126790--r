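#' @keywords internal
"_PACKAGE"

# Treatment/continence statuses used throughout the model. "controlled" is a
# continent patient on therapy; "uncontrolled_on_rx" an incontinent patient
# still on therapy; "untreated" a patient off therapy (incontinent).
OAB_STATUSES <- c("controlled", "uncontrolled_on_rx", "untreated")

# Per-dose efficacy fields (stored as fractions).
DOSE_FIELDS <- c(
  "response_w2", "response_w8", "response_w12",
  "cond_w12_given_w8resp", "cond_w12_given_w8nonresp",
  "nocturia_resolution_w12", "constipation_rate"
)

#' Load and validate a model parameter set
#'
#' Reads a YAML parameter file mirroring the published input tables
#' (efficacy/persistence, unit costs, resource use, comorbidities, utilities,
#' productivity) and returns a validated parameter set. Percentages in the
#' file (`*_pct` keys and `persistence`) are converted to fractions.
#'
#' @param path Path to a YAML parameter file. See
#'   `system.file("extdata", "oab_basecase.yaml", package = "oabcea")` for the
#'   packaged base case and the schema.
#' @return An object of class `oab_parameters`: a named list with elements
#'   `arms`, `titration`, `persistence`, `unit_costs`, `resource_use`,
#'   `comorbidity`, `utilities`, `productivity` and `conventions`.
#' @seealso [oab_basecase()], [validate_parameter_set()]
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  params <- build_parameter_set(raw)
  report <- validate_parameter_set(params)
  if (nrow(report) > 0L) {
    stop(
      "invalid parameter set (", nrow(report), " violation(s)):\n",
      paste0("  - ", report$path, ": ", report$message, collapse = "\n"),
      call. = FALSE
    )
  }
  params
}

# Assemble an oab_parameters object from the raw YAML list, converting
# percents to fractions. Structural problems (missing keys) error here;
# value problems are left to validate_parameter_set().
build_parameter_set <- function(raw) {
  required <- c(
    "arms", "titration", "persistence", "unit_costs", "resource_use",
    "comorbidity", "utilities", "productivity", "conventions"
  )
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("missing configuration section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  arms <- lapply(names(raw$arms), function(arm_id) {
    a <- raw$arms[[arm_id]]
    if (is.null(a$start_dose)) {
      stop("missing key: arms.", arm_id, ".start_dose", call. = FALSE)
    }
    doses <- lapply(names(a$doses), function(d) {
      dd <- a$doses[[d]]
      out <- list()
      for (f in DOSE_FIELDS) {
        key <- paste0(f, "_pct")
        if (is.null(dd[[key]])) {
          stop("missing key: arms.", arm_id, ".doses.", d, ".", key,
               call. = FALSE)
        }
        out[[f]] <- dd[[key]] / 100
      }
      out
    })
    names(doses) <- names(a$doses)
    list(
      arm_id = arm_id,
      start_dose = a$start_dose,
      high_dose = if (is.null(a$high_dose)) NA_character_ else a$high_dose,
      doses = doses
    )
  })
  names(arms) <- names(raw$arms)

  pers <- raw$persistence
  shared <- vapply(pers$shared_pct, function(x) x / 100, numeric(1))
  week8 <- vapply(pers$week8_by_arm_pct, function(x) x / 100, numeric(1))

  conv <- raw$conventions
  defaults <- list(
    horizon_weeks = 52L, perspective = "societal",
    annualize_six_month = TRUE, decrements_enabled = FALSE,
    wtp_per_qaly = 30000
  )
  for (k in names(defaults)) {
    if (is.null(conv[[k]])) conv[[k]] <- defaults[[k]]
  }

  structure(
    list(
      arms = arms,
      titration = raw$titration,
      persistence = list(shared = shared, week8_by_arm = week8),
      unit_costs = raw$unit_costs,
      resource_use = raw$resource_use,
      comorbidity = raw$comorbidity,
      utilities = raw$utilities,
      productivity = raw$productivity,
      conventions = conv
    ),
    class = "oab_parameters"
  )
}

#' Validate a parameter set against the model invariants
#'
#' Checks every probability is in \[0, 1\], costs are non-negative, the
#' persistence curve is non-increasing, single-dose arms have zero titration
#' fractions, expected comorbidity event counts are at least the probability
#' of any event, and the week-12 marginal response is consistent with the
#' week-8 marginal times the responder conditional (within ±0.005, the
#' rounding tolerance of two-decimal percents).
#'
#' @param params An `oab_parameters` object.
#' @return A data frame with columns `path` and `message`, one row per
#'   violation; zero rows when the set is valid.
#' @export
validate_parameter_set <- function(params) {
  v <- list()
  bad <- function(path, message) {
    v[[length(v) + 1L]] <<- data.frame(path = path, message = message,
                                       stringsAsFactors = FALSE)
  }
  check_prob <- function(x, path) {
    if (!is.numeric(x) || is.na(x)) {
      bad(path, "not a number")
    } else if (x < 0 || x > 1) {
      bad(path, sprintf("probability %.4f outside [0, 1]", x))
    }
  }
  check_nonneg <- function(x, path) {
    if (!is.numeric(x) || is.na(x)) {
      bad(path, "not a number")
    } else if (x < 0) {
      bad(path, sprintf("negative value %.4f", x))
    }
  }

  for (arm_id in names(params$arms)) {
    arm <- params$arms[[arm_id]]
    for (d in names(arm$doses)) {
      dd <- arm$doses[[d]]
      root <- paste0("arms.", arm_id, ".doses.", d, ".")
      for (f in DOSE_FIELDS) check_prob(dd[[f]], paste0(root, f))
      # marginal/conditional consistency (only when all three are valid)
      ok <- vapply(dd[c("response_w8", "response_w12",
                        "cond_w12_given_w8resp")],
                   function(x) is.numeric(x) && !is.na(x) && x >= 0 && x <= 1,
                   logical(1))
      if (all(ok)) {
        prod12 <- dd$cond_w12_given_w8resp * dd$response_w8
        if (abs(prod12 - dd$response_w12) > 0.005) {
          bad(paste0(root, "response_w12"),
              sprintf("inconsistent with cond_w12_given_w8resp * response_w8 (%.4f vs %.4f, tolerance 0.005)",
                      prod12, dd$response_w12))
        }
      }
    }
    tit <- params$titration[[arm_id]]
    if (is.null(tit)) {
      bad(paste0("titration.", arm_id), "missing titration policy")
    } else {
      check_prob(tit$frac_responders_titrate,
                 paste0("titration.", arm_id, ".frac_responders_titrate"))
      check_prob(tit$frac_nonresponders_titrate,
                 paste0("titration.", arm_id, ".frac_nonresponders_titrate"))
      if (is.na(arm$high_dose) &&
          (tit$frac_responders_titrate != 0 ||
           tit$frac_nonresponders_titrate != 0)) {
        bad(paste0("titration.", arm_id),
            "single-dose arm must have zero titration fractions")
      }
    }
  }

  shared <- params$persistence$shared
  for (w in names(shared)) {
    check_prob(shared[[w]], paste0("persistence.shared.", w))
  }
  wk <- as.numeric(names(shared))
  ord <- order(wk)
  if (any(diff(shared[ord]) > 1e-12)) {
    bad("persistence.shared", "persistence must be non-increasing over weeks")
  }
  for (a in names(params$persistence$week8_by_arm)) {
    check_prob(params$persistence$week8_by_arm[[a]],
               paste0("persistence.week8_by_arm.", a))
  }

  uc <- params$unit_costs
  for (k in setdiff(names(uc), "drug_per_day")) {
    check_nonneg(uc[[k]], paste0("unit_costs.", k))
  }
  for (arm_id in names(uc$drug_per_day)) {
    for (d in names(uc$drug_per_day[[arm_id]])) {
      check_nonneg(uc$drug_per_day[[arm_id]][[d]],
                   paste0("unit_costs.drug_per_day.", arm_id, ".", d))
    }
  }

  for (s in OAB_STATUSES) {
    ru <- params$resource_use[[s]]
    if (is.null(ru)) {
      bad(paste0("resource_use.", s), "missing status")
      next
    }
    check_prob(ru$frac_using_pads, paste0("resource_use.", s, ".frac_using_pads"))
    for (k in c("pads_per_day", "gp_visits_per_month",
                "specialist_visits_per_month", "lab_tests_per_month")) {
      check_nonneg(ru[[k]], paste0("resource_use.", s, ".", k))
    }
    cm <- params$comorbidity[[s]]
    if (is.null(cm)) {
      bad(paste0("comorbidity.", s), "missing status")
      next
    }
    root <- paste0("comorbidity.", s, ".")
    check_prob(cm$fracture_prob_6mo, paste0(root, "fracture_prob_6mo"))
    check_prob(cm$skin_prob_6mo, paste0(root, "skin_prob_6mo"))
    check_prob(cm$uti_prob_6mo, paste0(root, "uti_prob_6mo"))
    check_prob(cm$depression_prob_annual, paste0(root, "depression_prob_annual"))
    check_nonneg(cm$skin_events_per_person, paste0(root, "skin_events_per_person"))
    check_nonneg(cm$uti_events_per_person, paste0(root, "uti_events_per_person"))
    check_nonneg(cm$nursing_home_admissions_per_1000py,
                 paste0(root, "nursing_home_admissions_per_1000py"))
    for (cond in c("skin", "uti")) {
      p <- cm[[paste0(cond, "_prob_6mo")]]
      e <- cm[[paste0(cond, "_events_per_person")]]
      if (is.numeric(p) && is.numeric(e) && !is.na(p) && !is.na(e) &&
          p > 0 && e < p) {
        bad(paste0(root, cond, "_events_per_person"),
            "expected events per person below probability of any event")
      }
    }
  }
  for (k in c("fracture", "depression", "nursing_home")) {
    check_prob(params$comorbidity$utility_decrements[[k]],
               paste0("comorbidity.utility_decrements.", k))
  }

  for (k in c("u_continent", "u_incontinent_on_rx", "u_untreated")) {
    check_prob(params$utilities[[k]], paste0("utilities.", k))
  }

  pr <- params$productivity
  check_nonneg(pr$wage_per_hour, "productivity.wage_per_hour")
  check_nonneg(pr$hours_per_week, "productivity.hours_per_week")
  for (k in c("frac_employed", "incontinence_hours_reduction",
              "nocturia_impairment", "baseline_nocturia_prevalence")) {
    check_prob(pr[[k]], paste0("productivity.", k))
  }

  if (!params$conventions$horizon_weeks %in% c(12L, 52L)) {
    bad("conventions.horizon_weeks", "horizon must be 12 or 52 weeks")
  }
  if (!params$conventions$perspective %in% c("societal", "payer")) {
    bad("conventions.perspective", "perspective must be societal or payer")
  }

  if (length(v) == 0L) {
    data.frame(path = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
}

#' Serialize a parameter set back to YAML
#'
#' Writes a file that [load_parameter_set()] reads back to an identical
#' parameter set (fractions are converted back to two-or-more-decimal
#' percents without loss).
#'
#' @param params An `oab_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  arms <- lapply(params$arms, function(arm) {
    doses <- lapply(arm$doses, function(dd) {
      out <- list()
      for (f in DOSE_FIELDS) out[[paste0(f, "_pct")]] <- dd[[f]] * 100
      out
    })
    out <- list(start_dose = arm$start_dose)
    if (!is.na(arm$high_dose)) out$high_dose <- arm$high_dose
    out$doses <- doses
    out
  })
  raw <- list(
    arms = arms,
    titration = params$titration,
    persistence = list(
      shared_pct = as.list(params$persistence$shared * 100),
      week8_by_arm_pct = as.list(params$persistence$week8_by_arm * 100)
    ),
    unit_costs = params$unit_costs,
    resource_use = params$resource_use,
    comorbidity = params$comorbidity,
    utilities = params$utilities,
    productivity = params$productivity,
    conventions = params$conventions
  )
  yaml::write_yaml(raw, path, precision = 12)
  invisible(path)
}

# Round to two-decimal percent, half away from zero (the convention of the
# source tables; base round() is half-to-even). The epsilon keeps exact
# decimal halves (e.g. 20.99% x 1.5 = 31.485%) on the upper side despite
# binary representation error; inputs are two-decimal percents times
# two-decimal risk ratios, so no genuine value sits within 1e-7 of a half.
round_pct2 <- function(frac) {
  floor(frac * 1e4 + 0.5 + 1e-7) / 1e4
}

#' Derive an arm's efficacy from placebo by a relative risk
#'
#' Scales the placebo response marginals (weeks 2, 8, 12) and the
#' week-12-given-week-8-non-response conditional by a relative risk, rounding
#' to the two-decimal percent convention of the input tables. The
#' week-12-given-week-8-response conditional is copied unscaled (taken equal
#' to placebo in the source). This is how the solifenacin arm is built from
#' the placebo row (RR 1.50 for 5 mg, 1.53 for 10 mg).
#'
#' @param placebo A single-dose efficacy list with the fields
#'   `response_w2/w8/w12`, `cond_w12_given_w8resp`, `cond_w12_given_w8nonresp`
#'   (fractions), e.g. `oab_basecase()$arms$placebo$doses$placebo`.
#' @param rr Relative risk of response versus placebo (> 0).
#' @return An efficacy list of the same shape with scaled values.
#' @export
scale_efficacy_by_rr <- function(placebo, rr) {
  stopifnot(is.numeric(rr), length(rr) == 1L)
  if (rr <= 0) stop("relative risk must be positive", call. = FALSE)
  out <- placebo
  scaled_fields <- c("response_w2", "response_w8", "response_w12",
                     "cond_w12_given_w8nonresp")
  for (f in scaled_fields) {
    x <- placebo[[f]] * rr
    if (x > 1) {
      stop(sprintf("scaled probability %s = %.4f exceeds 1", f, x),
           call. = FALSE)
    }
    out[[f]] <- round_pct2(x)
  }
  out$cond_w12_given_w8resp <- placebo$cond_w12_given_w8resp
  out
}

#' Week-12 response conditional on week-8 response
#'
#' The ratio of the week-12 to the week-8 response marginal, i.e. the
#' probability of being a responder at week 12 given response at week 8 under
#' the model's carried-forward response structure.
#'
#' @param response_w8,response_w12 Response marginals (fractions);
#'   `response_w8` must be positive.
#' @return The conditional probability. Warns (rather than errors) when
#'   `response_w12 > response_w8`, which would imply a conditional above 1.
#' @export
conditional_from_marginals <- function(response_w8, response_w12) {
  if (response_w8 <= 0) {
    stop("conditional undefined: response_w8 must be > 0", call. = FALSE)
  }
  if (response_w12 > response_w8) {
    warning("response_w12 exceeds response_w8; conditional exceeds 1")
  }
  response_w12 / response_w8
}

#' Expected events among patients experiencing at least one
#'
#' Converts a per-person expected event count over some window into the
#' expected count among affected patients: `events_per_person / prob_any`.
#' Reproduces the "events per affected patient" figures of the comorbidity
#' table (e.g. 0.7 UTIs per person with a 30.7% probability of any UTI gives
#' 2.28, printed 2.3).
#'
#' @param events_per_person Expected events per person in the population.
#' @param prob_any Probability of experiencing at least one event.
#' @return Expected events per affected patient.
#' @export
events_per_affected <- function(events_per_person, prob_any) {
  if (prob_any <= 0) {
    if (events_per_person > 0) {
      stop("inconsistent inputs: positive events with zero probability",
           call. = FALSE)
    }
    stop("prob_any must be > 0", call. = FALSE)
  }
  events_per_person / prob_any
}

#' @export
print.oab_parameters <- function(x, ...) {
  cat("<oab_parameters>\n")
  cat("  arms:", paste(names(x$arms), collapse = ", "), "\n")
  cat(sprintf("  horizon: %d weeks, perspective: %s\n",
              x$conventions$horizon_weeks, x$conventions$perspective))
  cat(sprintf("  conventions: annualize_six_month=%s, decrements_enabled=%s\n",
              x$conventions$annualize_six_month,
              x$conventions$decrements_enabled))
  invisible(x)
}
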