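#' Run the cohort trace for one arm and age cohort
#'
#' Propagates the closed cohort through the 40 quarterly cycles. Cycle-0
#' occupancy is the arm's state distribution (everyone alive); each later
#' cycle multiplies the previous occupancy by that cycle's transition
#' matrix. The cohort's age advances one year every four cycles and drives
#' the background-mortality lookup.
#'
#' @param params A validated \code{parameter_set}.
#' @param arm \code{"TCS"} or \code{"USUAL_CARE"}.
#' @param cohort Cohort label (\code{"60s"}, \code{"70s"}, \code{"80s"}).
#' @return A \code{cohort_trace}: numeric matrix of occupancy fractions,
#'   rows = cycles 0..40, columns = the six states, with \code{arm},
#'   \code{cohort} and \code{start_age} attributes.
#' @export
run_cohort <- function(params, arm, cohort) {
  stopifnot(inherits(params, "parameter_set"))
  check_arm(arm)
  check_cohort(cohort)

  dist <- apply_relative_risks(params$distributions[[cohort]],
                               rr_vector(params), arm)
  ratios <- mortality_vector(params)
  n_cycles <- params$constants$n_cycles
  cycles_per_year <- as.integer(round(1 / params$constants$cycle_length_years))
  start_age <- params$start_age[[cohort]]

  occ <- matrix(0, n_cycles + 1L, 6L,
                dimnames = list(0:n_cycles, MEDICAL_STATES))
  occ[1L, ALIVE_STATES] <- dist$prob

  # One life-table lookup per distinct age; the per-state arithmetic below
  # is cycle_death_prob() vectorised (equivalence is property-tested).
  ages <- start_age + (seq_len(n_cycles) - 1L) %/% cycles_per_year
  q_by_age <- annual_death_prob(params$life_table, unique(ages))
  names(q_by_age) <- unique(ages)

  for (k in seq_len(n_cycles)) {
    q_annual <- q_by_age[[as.character(ages[k])]]
    d <- annual_to_cycle_prob(pmin(ratios * q_annual, 1), cycles_per_year)
    names(d) <- names(ratios)
    m <- build_cycle_matrix(dist, d, arm, cycle = k, age = ages[k])
    occ[k + 1L, ] <- occ[k, ] %*% m
  }

  rs <- rowSums(occ)
  if (any(abs(rs - 1) > 1e-9)) stop("trace rows do not sum to 1",
                                    call. = FALSE)
  if (any(diff(occ[, "DEAD"]) < -1e-12)) {
    stop("DEAD occupancy must be non-decreasing", call. = FALSE)
  }
  structure(occ, class = c("cohort_trace", "matrix"),
            arm = arm, cohort = cohort, start_age = start_age)
}

#' Discount factor for a (possibly fractional) cycle index
#'
#' \eqn{(1 + r)^{-k / c}} with annual rate \eqn{r} and \eqn{c} cycles per
#' year. Fractional \code{cycle} supports mid-cycle discounting for the
#' half-cycle correction.
#'
#' @param cycle Cycle index, \eqn{\ge 0}; may be fractional.
#' @param annual_rate Annual discount rate, \eqn{\ge 0}.
#' @param cycles_per_year Cycles per year (default 4).
#' @return Dimensionless discount factor in \code{(0, 1]}.
#' @export
discount_factor <- function(cycle, annual_rate, cycles_per_year = 4) {
  if (annual_rate < 0) stop("annual_rate must be non-negative", call. = FALSE)
  if (any(cycle < 0)) stop("cycle must be non-negative", call. = FALSE)
  (1 + annual_rate)^(-cycle / cycles_per_year)
}

#' Accumulate discounted, half-cycle-corrected costs and QALYs
#'
#' Per-cycle expected rewards are \eqn{v(k) = \sum_s occ(k, s)\,w(s)} with
#' cost weight = per-cycle state cost (USD) and QALY weight = annual utility
#' times the cycle length in years. The half-cycle correction uses the
#' trapezoid (life-table) form: the horizon contributes
#' \eqn{\sum_{k=1}^{40} \delta(k - \tfrac12)\,\tfrac12 (v(k-1) + v(k))}
#' with \eqn{\delta} the \code{\link{discount_factor}}; there is no separate
#' full cycle-0 reward. The intervention arm adds the one-time per-patient
#' service cost at model entry, undiscounted.
#'
#' @param trace A \code{cohort_trace}.
#' @param params The \code{parameter_set} the trace was run from.
#' @param arm Arm label; must match the trace's arm.
#' @return An \code{arm_result}: list with \code{cost}, \code{qalys}
#'   (discounted), \code{cost_undiscounted}, \code{qalys_undiscounted},
#'   per-cycle streams, \code{arm} and \code{cohort}.
#' @export
accumulate_outcomes <- function(trace, params, arm) {
  stopifnot(inherits(trace, "cohort_trace"))
  check_arm(arm)
  if (!identical(attr(trace, "arm"), arm)) {
    stop("trace was run for arm ", attr(trace, "arm"), ", not ", arm,
         call. = FALSE)
  }
  cohort <- attr(trace, "cohort")
  cyl <- params$constants$cycle_length_years
  cycles_per_year <- as.integer(round(1 / cyl))
  n_cycles <- nrow(trace) - 1L

  cost_w <- cost_vector(params, cohort)
  qaly_w <- utility_vector(params) * cyl
  v_cost <- as.vector(trace %*% cost_w)   # index 1 = cycle 0
  v_qaly <- as.vector(trace %*% qaly_w)

  k <- seq_len(n_cycles)
  trap_cost <- (v_cost[k] + v_cost[k + 1L]) / 2
  trap_qaly <- (v_qaly[k] + v_qaly[k + 1L]) / 2
  df <- discount_factor(k - 0.5, params$constants$discount_rate,
                        cycles_per_year)

  tcs_cost <- if (arm == "TCS") tcs_total_cost(params$tcs_schedule) else 0

  structure(list(
    cost = sum(df * trap_cost) + tcs_cost,
    qalys = sum(df * trap_qaly),
    cost_undiscounted = sum(trap_cost) + tcs_cost,
    qalys_undiscounted = sum(trap_qaly),
    cycle_cost = v_cost,
    cycle_qalys = v_qaly,
    arm = arm, cohort = cohort
  ), class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("%s / %s: cost %.2f USD, effect %.3f QALYs (discounted)\n",
              x$arm, x$cohort, x$cost, x$qalys))
  invisible(x)
}

#' Run one arm end to end
#'
#' Convenience wrapper: \code{\link{run_cohort}} followed by
#' \code{\link{accumulate_outcomes}}.
#'
#' @inheritParams run_cohort
#' @return An \code{arm_result}.
#' @export
run_arm <- function(params, arm, cohort) {
  accumulate_outcomes(run_cohort(params, arm, cohort), params, arm)
}

#' Export a cohort trace in long format
#'
#' @param trace A \code{cohort_trace}.
#' @return Data frame with columns \code{cycle}, \code{state},
#'   \code{occupancy}, \code{arm}, \code{cohort}.
#' @export
trace_to_long <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  data.frame(
    cycle = rep(as.integer(rownames(trace)), times = ncol(trace)),
    state = rep(colnames(trace), each = nrow(trace)),
    occupancy = as.vector(trace),
    arm = attr(trace, "arm"),
    cohort = attr(trace, "cohort"),
    stringsAsFactors = FALSE
  )
}
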