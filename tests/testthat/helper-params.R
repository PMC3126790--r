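# Shared fixtures for the test suite. The base case is loaded once per test
# run; tests that perturb it must copy (R lists are copy-on-modify, so plain
# assignment suffices).

base_params <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- oab_basecase()
    cached
  }
})

# A handcrafted single-dose trajectory with fully specified occupancies at
# the 52-week checkpoints, for closed-form cost checks. `occ` is a list per
# checkpoint week: c(continent, incontinent_on_rx, untreated).
make_traj <- function(occ, arm_id = "tolterodine", dose = "4mg") {
  weeks <- lapply(occ, function(o) {
    list(
      continent = setNames(o[1], dose),
      incontinent_on_rx = setNames(o[2], dose),
      untreated = o[3]
    )
  })
  structure(
    list(
      arm_id = arm_id,
      horizon_weeks = if (length(occ) >= 3) 52L else 12L,
      split = data.frame(
        branch = c("responder_stay", "nonresponder_stay"),
        responder_w8 = c(TRUE, FALSE),
        dose = dose,
        fraction = c(0.5, 0.5),
        stringsAsFactors = FALSE
      ),
      response_w12 = sum(occ[["12"]][1]),
      weeks = weeks
    ),
    class = "oab_trajectory"
  )
}

# Independent arithmetic for the expected week-12 pre-attrition response of
# the packaged fesoterodine/tolterodine/solifenacin arms (hand oracle used
# by several tests; derived branch by branch from the printed efficacy
# table, not from the engine).
hand_r12 <- list(
  fesoterodine = 0.25 * (0.8734 + 0.9065 + 0.2105 + 0.2420),
  tolterodine = 0.4947 * 0.7717 + (1 - 0.4947) * 0.1304,
  solifenacin = 0.25995 * (0.8033 + 0.8033) + 0.24005 * (0.2124 + 0.2166)
)
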