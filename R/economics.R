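#' Incremental cost-utility comparison of two arms
#'
#' Computes incremental cost \eqn{\Delta C} (intervention minus usual
#' care), incremental effect \eqn{\Delta E} (QALYs) and, when
#' \eqn{\Delta E \neq 0}, the incremental cost-utility ratio
#' \eqn{\Delta C / \Delta E}. The dominance label carries the
#' interpretation: a negative ratio is sign-ambiguous, so dominant results
#' are reported as \code{cost_saving_dominant} (cheaper and more effective)
#' rather than as a bare negative ICUR.
#'
#' @param tcs \code{arm_result} for the intervention arm.
#' @param usual \code{arm_result} for the usual-care arm.
#' @param cohort Cohort label; must match both results.
#' @return A \code{ce_result}: list with \code{delta_cost},
#'   \code{delta_effect}, \code{icur} (NA when undefined or dominant in
#'   either direction), \code{label} (one of \code{cost_saving_dominant},
#'   \code{dominated}, \code{tradeoff_ne}, \code{tradeoff_sw}, or a
#'   boundary label when a difference is exactly zero), \code{cohort}, and
#'   the two arm totals.
#' @export
incremental_result <- function(tcs, usual, cohort) {
  stopifnot(inherits(tcs, "arm_result"), inherits(usual, "arm_result"))
  check_cohort(cohort)
  if (!identical(tcs$cohort, cohort) || !identical(usual$cohort, cohort)) {
    stop("arm results are not from cohort ", cohort, call. = FALSE)
  }
  dc <- tcs$cost - usual$cost
  de <- tcs$qalys - usual$qalys
  label <-
    if (dc < 0 && de > 0) "cost_saving_dominant"
    else if (dc > 0 && de < 0) "dominated"
    else if (dc > 0 && de > 0) "tradeoff_ne"
    else if (dc < 0 && de < 0) "tradeoff_sw"
    else if (de == 0 && dc == 0) "no_difference"
    else if (de == 0) { if (dc < 0) "cheaper_equal" else "costlier_equal" }
    else { if (de > 0) "more_effective_equal_cost" else
           "less_effective_equal_cost" }
  icur <- if (de != 0 && label %in% c("tradeoff_ne", "tradeoff_sw")) dc / de
          else NA_real_
  structure(list(
    delta_cost = dc, delta_effect = de, icur = icur, label = label,
    cohort = cohort,
    tcs_cost = tcs$cost, usual_cost = usual$cost,
    tcs_qalys = tcs$qalys, usual_qalys = usual$qalys
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf(
    "%s: dCost %.2f USD, dEffect %.3f QALYs -> %s\n", x$cohort,
    x$delta_cost, x$delta_effect,
    if (is.na(x$icur)) x$label else sprintf("ICUR %.0f USD/QALY", x$icur)))
  invisible(x)
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' \eqn{NMB = WTP \times \Delta E - \Delta C}; positive means the
#' intervention is cost-effective at that threshold.
#'
#' @param ce A \code{ce_result}.
#' @param wtp Willingness to pay, USD per QALY, \eqn{\ge 0}.
#' @return List with \code{wtp} and \code{nmb} (USD).
#' @export
net_monetary_benefit <- function(ce, wtp) {
  stopifnot(inherits(ce, "ce_result"))
  if (any(wtp < 0)) stop("wtp must be non-negative", call. = FALSE)
  list(wtp = wtp, nmb = wtp * ce$delta_effect - ce$delta_cost)
}

#' Baseline cost-utility analysis over age cohorts
#'
#' Runs both arms through the cohort engine for each requested cohort and
#' returns the incremental comparisons.
#'
#' @param params A validated \code{parameter_set}.
#' @param cohorts Cohort labels to run (default all three).
#' @return Named list of \code{ce_result}, one per cohort.
#' @export
baseline_analysis <- function(params, cohorts = COHORTS) {
  res <- lapply(cohorts, function(co) {
    incremental_result(run_arm(params, "TCS", co),
                       run_arm(params, "USUAL_CARE", co), co)
  })
  stats::setNames(res, cohorts)
}

#' Tabulate baseline results in the published layout
#'
#' @param results Named list of \code{ce_result} from
#'   \code{\link{baseline_analysis}}.
#' @return Data frame with one row per cohort and arm: total cost,
#'   incremental cost, total effect, incremental effect, and the ICUR or
#'   dominance label.
#' @export
ce_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      cohort = r$cohort,
      arm = c("TCS", "Usual care"),
      total_cost = round_half_up(c(r$tcs_cost, r$usual_cost), 2),
      delta_cost = c(round_half_up(r$delta_cost, 2), NA),
      total_effect = round_half_up(c(r$tcs_qalys, r$usual_qalys), 3),
      delta_effect = c(round_half_up(r$delta_effect, 3), NA),
      icur = c(if (is.na(r$icur)) r$label else
               as.character(round_half_up(r$icur, 2)), NA),
      stringsAsFactors = FALSE
    )
  }))
}
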