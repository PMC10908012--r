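#' Convert a period risk ratio to its annual equivalent
#'
#' Additional-mortality ratios reported over a study period (e.g. 2.34 over
#' three years) are converted to a per-year equivalent by the geometric root
#' \eqn{r^{1/p}}. Full precision is returned; round to 3 decimals for
#' display.
#'
#' @param ratio Period risk ratio, positive.
#' @param period Period length in years, positive.
#' @return The annual-equivalent ratio.
#' @examples
#' round(annualize_period_ratio(2.34, 3), 3)   # 1.328
#' round(annualize_period_ratio(1.14, 1.5), 3) # 1.091
#' @export
annualize_period_ratio <- function(ratio, period) {
  if (any(ratio <= 0) || any(period <= 0)) {
    stop("ratio and period must be positive", call. = FALSE)
  }
  ratio^(1 / period)
}

#' Convert an annual probability to a per-cycle probability
#'
#' Constant-hazard conversion: \eqn{1 - (1 - q)^{1/c}} for \eqn{c} cycles
#' per year.
#'
#' @param q_annual Annual probability in \code{[0, 1]}.
#' @param cycles_per_year Integer number of cycles per year, \eqn{\ge 1}.
#' @return The per-cycle probability.
#' @export
annual_to_cycle_prob <- function(q_annual, cycles_per_year = 4) {
  if (any(q_annual < 0 | q_annual > 1)) {
    stop("q_annual must lie in [0, 1]", call. = FALSE)
  }
  if (cycles_per_year < 1) stop("cycles_per_year must be >= 1", call. = FALSE)
  1 - (1 - q_annual)^(1 / cycles_per_year)
}

#' Apply intervention relative risks to a state distribution
#'
#' For the usual-care arm the distribution is returned unchanged. For the
#' intervention arm each RR-bearing state's probability is multiplied by its
#' relative risk and the \code{STABLE} state absorbs the residual mass so
#' the five probabilities still sum to 1. With all relative risks below 1
#' this shifts occupancy from unfavourable states into stable management.
#'
#' @param dist A \code{state_distribution}.
#' @param rr Named positive numeric vector of relative risks over
#'   \code{RR_STATES}.
#' @param arm \code{"TCS"} or \code{"USUAL_CARE"}.
#' @return The (possibly adjusted) \code{state_distribution}.
#' @export
apply_relative_risks <- function(dist, rr, arm) {
  stopifnot(inherits(dist, "state_distribution"))
  check_arm(arm)
  if (arm == "USUAL_CARE") return(dist)
  if (is.null(names(rr)) || !all(RR_STATES %in% names(rr))) {
    stop("rr must be named over ", paste(RR_STATES, collapse = ", "),
         call. = FALSE)
  }
  rr <- rr[RR_STATES]
  if (any(rr <= 0)) stop("relative risks must be positive", call. = FALSE)
  p <- dist$prob
  p[RR_STATES] <- p[RR_STATES] * rr
  mass <- sum(p[RR_STATES])
  if (mass > 1 + 1e-12) {
    stop("RR-adjusted non-STABLE mass exceeds 1 (", format(mass, digits = 6),
         "); no residual left for STABLE", call. = FALSE)
  }
  p["STABLE"] <- 1 - mass
  state_distribution(p, cohort = dist$cohort)
}

#' Per-cycle death probability for a state at a given age
#'
#' The annual background death probability at the cohort's current age is
#' multiplied by the state's additional mortality ratio (capped at a
#' probability of 1) and then converted to the 3-month cycle scale. The
#' ratio is applied on the probability scale, matching how the additional
#' mortality risks are reported.
#'
#' @param age Integer current age; must lie within the life table.
#' @param state An alive medical state.
#' @param life_table A \code{life_table}.
#' @param ratios Named numeric vector of annual additional mortality ratios
#'   over \code{ALIVE_STATES} (\code{STABLE} = 1).
#' @param cycles_per_year Cycles per year (default 4).
#' @return The per-cycle death probability.
#' @export
cycle_death_prob <- function(age, state, life_table, ratios,
                             cycles_per_year = 4) {
  check_state(state)
  q_annual <- annual_death_prob(life_table, age)
  r <- ratios[[state]]
  if (is.null(r) || is.na(r)) stop("no mortality ratio for state ", state,
                                   call. = FALSE)
  annual_to_cycle_prob(min(1, r * q_annual), cycles_per_year)
}

#' Assemble one cycle's transition matrix
#'
#' Death acts first as a competing event: from alive state \eqn{s} the
#' probability of dying is \code{death_probs[s]}; survivors redistribute
#' over the alive states according to the arm's (memoryless) destination
#' distribution. \code{DEAD} is absorbing. Rows sum to 1 by construction
#' and are checked.
#'
#' @param dist The arm's \code{state_distribution} (relative risks already
#'   applied for the intervention arm).
#' @param death_probs Named per-cycle death probabilities over
#'   \code{ALIVE_STATES}, each in \code{[0, 1]}.
#' @param arm Arm label, kept as metadata.
#' @param cycle,age Optional cycle index and current age metadata.
#' @return A 6x6 row-stochastic matrix of class \code{transition_matrix}
#'   with rows/columns named by \code{MEDICAL_STATES}.
#' @export
build_cycle_matrix <- function(dist, death_probs, arm, cycle = NA_integer_,
                               age = NA_integer_) {
  stopifnot(inherits(dist, "state_distribution"))
  check_arm(arm)
  if (is.null(names(death_probs)) ||
      !all(ALIVE_STATES %in% names(death_probs))) {
    stop("death_probs must be named over the five alive states",
         call. = FALSE)
  }
  d <- death_probs[ALIVE_STATES]
  if (any(d < 0 | d > 1)) stop("death probabilities must lie in [0, 1]",
                               call. = FALSE)
  m <- matrix(0, 6, 6, dimnames = list(MEDICAL_STATES, MEDICAL_STATES))
  m[ALIVE_STATES, ALIVE_STATES] <- outer(1 - d, dist$prob)
  m[ALIVE_STATES, "DEAD"] <- d
  m["DEAD", "DEAD"] <- 1
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-9) || any(m < 0 | m > 1)) {
    stop("transition matrix is not row-stochastic", call. = FALSE)
  }
  structure(m, class = c("transition_matrix", "matrix"),
            cycle = cycle, arm = arm, age = age)
}

#' Export a transition matrix in long format
#'
#' @param m A \code{transition_matrix}.
#' @return Data frame with columns \code{from_state}, \code{to_state},
#'   \code{probability}, \code{cycle}, \code{arm} — the audit layout.
#' @export
matrix_to_long <- function(m) {
  stopifnot(inherits(m, "transition_matrix"))
  data.frame(
    from_state = rep(rownames(m), times = ncol(m)),
    to_state = rep(colnames(m), each = nrow(m)),
    probability = as.vector(m),
    cycle = attr(m, "cycle"),
    arm = attr(m, "arm"),
    stringsAsFactors = FALSE
  )
}
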