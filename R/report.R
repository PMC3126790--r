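# Assembly of the base-case report (per-arm outcomes, pairwise CEA, the
# convention ledger in effect) and CSV/JSON emission.

#' Run one arm end to end
#'
#' Convenience wrapper: trajectory, QALY gain and cost breakdown for one arm.
#'
#' @param arm_id Arm name.
#' @param params An `oab_parameters` object.
#' @param horizon_weeks,perspective Overrides of the parameter set's
#'   conventions.
#' @return List with `trajectory`, `qaly_gain` and `cost`.
#' @export
run_arm <- function(arm_id, params,
                    horizon_weeks = params$conventions$horizon_weeks,
                    perspective = params$conventions$perspective) {
  traj <- run_cohort(arm_id, params, horizon_weeks)
  list(
    trajectory = traj,
    qaly_gain = qaly_gain(traj, params),
    cost = total_cost(traj, params, perspective)
  )
}

#' Full model report for a parameter set
#'
#' Runs every modelled arm, assembles the per-arm outcome table (continence
#' at weeks 12 and 52, QALY gain, cost components and totals), the pairwise
#' comparisons of the reference arm against each comparator, and the
#' convention ledger in effect. Regenerating the report from the same inputs
#' is bit-identical (the model is deterministic).
#'
#' @param params An `oab_parameters` object.
#' @param horizon_weeks,perspective Overrides of the parameter set's
#'   conventions.
#' @param reference_arm,comparator_arms Arms compared.
#' @return An `oab_report`: list with `arm_table` (data frame), `cea_table`
#'   (data frame), `conventions` (list) and `horizon_weeks`/`perspective`.
#' @export
run_report <- function(params,
                       horizon_weeks = params$conventions$horizon_weeks,
                       perspective = params$conventions$perspective,
                       reference_arm = "fesoterodine",
                       comparator_arms = c("tolterodine", "solifenacin")) {
  arms <- c(reference_arm, comparator_arms)
  runs <- lapply(arms, run_arm, params = params,
                 horizon_weeks = horizon_weeks, perspective = perspective)
  names(runs) <- arms

  arm_table <- do.call(rbind, lapply(arms, function(a) {
    r <- runs[[a]]
    cbind(
      data.frame(
        arm = a,
        continent_w12_pct = 100 * continent_fraction(r$trajectory, 12),
        continent_w52_pct = if (horizon_weeks == 52L) {
          100 * continent_fraction(r$trajectory, 52)
        } else NA_real_,
        qaly_gain = r$qaly_gain,
        stringsAsFactors = FALSE
      ),
      cost_breakdown_df(r$cost)
    )
  }))

  wtp <- params$conventions$wtp_per_qaly
  cea_table <- do.call(rbind, lapply(comparator_arms, function(a) {
    r <- cea_compare(runs[[reference_arm]]$cost$total,
                     runs[[reference_arm]]$qaly_gain,
                     runs[[a]]$cost$total, runs[[a]]$qaly_gain,
                     reference_arm, a, wtp = wtp)
    data.frame(
      reference = reference_arm, comparator = a,
      delta_cost = r$delta_cost, delta_qaly = r$delta_qaly,
      icer = r$icer, label = r$label, display = icer_display(r),
      threshold_pass = r$threshold_pass, stringsAsFactors = FALSE
    )
  }))

  structure(
    list(
      horizon_weeks = horizon_weeks,
      perspective = perspective,
      arm_table = arm_table,
      cea_table = cea_table,
      conventions = params$conventions
    ),
    class = "oab_report"
  )
}

#' Write a report (or any model table) to CSV and JSON
#'
#' The CSV and JSON emissions carry identical values field for field.
#'
#' @param report An `oab_report` from [run_report()].
#' @param dir Output directory (created if needed).
#' @param stem Filename stem.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, stem = "report") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arm_csv <- file.path(dir, paste0(stem, "_arms.csv"))
  cea_csv <- file.path(dir, paste0(stem, "_cea.csv"))
  json <- file.path(dir, paste0(stem, ".json"))
  utils::write.csv(report$arm_table, arm_csv, row.names = FALSE)
  utils::write.csv(report$cea_table, cea_csv, row.names = FALSE)
  jsonlite::write_json(
    list(
      horizon_weeks = report$horizon_weeks,
      perspective = report$perspective,
      arms = report$arm_table,
      cea = report$cea_table,
      conventions = report$conventions
    ),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(arms = arm_csv, cea = cea_csv, json = json))
}

#' @export
print.oab_report <- function(x, ...) {
  cat(sprintf("<oab_report: %d weeks, %s perspective>\n", x$horizon_weeks,
              x$perspective))
  df <- x$arm_table
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-13s continent w12 %5.1f%%  w52 %s  QALY gain %.5f  total %8.0f EUR\n",
                df$arm[i], df$continent_w12_pct[i],
                if (is.na(df$continent_w52_pct[i])) "   --" else
                  sprintf("%5.1f%%", df$continent_w52_pct[i]),
                df$qaly_gain[i], df$total[i]))
  }
  for (i in seq_len(nrow(x$cea_table))) {
    cat(sprintf("  %s vs %s: %s\n", x$cea_table$reference[i],
                x$cea_table$comparator[i], x$cea_table$display[i]))
  }
  invisible(x)
}
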