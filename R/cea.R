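# Incremental cost-effectiveness comparison and dominance classification.

#' Pairwise incremental cost-effectiveness comparison
#'
#' Computes incremental cost and QALYs of a reference intervention versus a
#' comparator and classifies the result: `"cost-saving"` when the reference
#' is cheaper and more effective (dominant; no ratio reported), `"dominated"`
#' when costlier and less effective, an ICER when both deltas share a sign
#' (flagged `south_west` when both are negative, i.e. cheaper and worse), and
#' `"equivalent"`/`"cheaper-equal"`/`"costlier-equal"` when the QALY delta is
#' zero.
#'
#' @param ref_cost,ref_qaly Cost (euros) and QALYs of the reference arm.
#' @param comp_cost,comp_qaly Cost and QALYs of the comparator arm.
#' @param reference_arm,comparator_arm Labels carried into the result.
#' @param wtp Willingness-to-pay threshold in euros per QALY (default 30000).
#' @return An `oab_cea_result`: list with `reference_arm`, `comparator_arm`,
#'   `delta_cost`, `delta_qaly`, `icer` (`NA` when dominance or equality
#'   applies), `label`, `south_west` and `threshold_pass`.
#' @export
cea_compare <- function(ref_cost, ref_qaly, comp_cost, comp_qaly,
                        reference_arm = "reference",
                        comparator_arm = "comparator",
                        wtp = 30000) {
  dc <- ref_cost - comp_cost
  dq <- ref_qaly - comp_qaly
  icer <- NA_real_
  south_west <- FALSE
  if (dq == 0) {
    label <- if (dc == 0) "equivalent" else if (dc < 0) "cheaper-equal" else "costlier-equal"
  } else if (dc < 0 && dq > 0) {
    label <- "cost-saving"
  } else if (dc > 0 && dq < 0) {
    label <- "dominated"
  } else {
    icer <- dc / dq
    south_west <- dc < 0 && dq < 0
    label <- "icer"
  }
  res <- list(
    reference_arm = reference_arm,
    comparator_arm = comparator_arm,
    delta_cost = dc,
    delta_qaly = dq,
    icer = icer,
    label = label,
    south_west = south_west
  )
  res$threshold_pass <- threshold_check(res, wtp)
  class(res) <- "oab_cea_result"
  res
}

#' Willingness-to-pay threshold check
#'
#' `TRUE` when the reference is cost-saving, cheaper at equal effect, or has
#' an ICER below the threshold.
#'
#' @param result An `oab_cea_result` from [cea_compare()].
#' @param wtp Willingness-to-pay in euros per QALY.
#' @return Logical.
#' @export
threshold_check <- function(result, wtp = 30000) {
  if (result$label %in% c("cost-saving", "cheaper-equal")) return(TRUE)
  if (result$label %in% c("dominated", "costlier-equal")) return(FALSE)
  if (result$label == "equivalent") return(TRUE)
  is.finite(result$icer) && result$icer < wtp
}

# Human-readable ICER cell: dominance label or whole-euro ratio.
icer_display <- function(result) {
  switch(result$label,
    "cost-saving" = "Cost-saving",
    "dominated" = "Dominated",
    "equivalent" = "Equivalent",
    "cheaper-equal" = "Cheaper (equal QALYs)",
    "costlier-equal" = "Costlier (equal QALYs)",
    sprintf("%.0f%s", result$icer, if (result$south_west) " (SW)" else "")
  )
}

#' @export
print.oab_cea_result <- function(x, ...) {
  cat(sprintf("<oab_cea_result: %s vs %s>\n", x$reference_arm,
              x$comparator_arm))
  cat(sprintf("  delta cost: %.2f EUR, delta QALY: %.5f\n",
              x$delta_cost, x$delta_qaly))
  cat(sprintf("  result: %s, threshold pass: %s\n", icer_display(x),
              x$threshold_pass))
  invisible(x)
}
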