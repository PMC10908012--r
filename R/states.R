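#' Health states of the post-discharge medical-use model
#'
#' The model tracks a closed cohort of older COPD inpatients after discharge
#' through six mutually exclusive states of medical use, assessed every
#' 90-day cycle: stable outpatient management of COPD, no management (no
#' physician contact within the cycle), readmission for COPD, readmission
#' for another respiratory disease, readmission for a non-respiratory
#' disease, and death. \code{DEAD} is absorbing and carries no cost and no
#' utility.
#'
#' @format Character vector of the six state labels, in canonical order.
#' @export
MEDICAL_STATES <- c("STABLE", "NO_MGMT", "READMIT_COPD", "READMIT_RESP",
                    "READMIT_OTHER", "DEAD")

#' The five alive (non-absorbing) states
#'
#' @format Character vector; \code{MEDICAL_STATES} without \code{DEAD}.
#' @export
ALIVE_STATES <- MEDICAL_STATES[MEDICAL_STATES != "DEAD"]

#' States carrying a relative risk under the intervention
#'
#' The transitional-care intervention is modelled as a multiplicative
#' relative risk on the probability of occupying each unfavourable state;
#' \code{STABLE} is the residual state and carries no relative risk.
#'
#' @format Character vector of the four RR-bearing states.
#' @export
RR_STATES <- ALIVE_STATES[ALIVE_STATES != "STABLE"]

#' Comparator arms
#'
#' @format Character vector: \code{"TCS"} (transitional care services) and
#'   \code{"USUAL_CARE"}.
#' @export
ARMS <- c("TCS", "USUAL_CARE")

#' Age cohorts
#'
#' Cohorts enter the model at age 60, 70 and 80 respectively.
#'
#' @format Character vector of cohort labels.
#' @export
COHORTS <- c("60s", "70s", "80s")

#' @keywords internal
check_state <- function(state, allow_dead = FALSE) {
  pool <- if (allow_dead) MEDICAL_STATES else ALIVE_STATES
  if (!is.character(state) || length(state) != 1L || !(state %in% pool)) {
    stop("unknown state label: ", paste(state, collapse = ", "),
         " (expected one of ", paste(pool, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(state)
}

#' @keywords internal
check_arm <- function(arm) {
  if (!is.character(arm) || length(arm) != 1L || !(arm %in% ARMS)) {
    stop("unknown arm: must be one of ", paste(ARMS, collapse = ", "),
         call. = FALSE)
  }
  invisible(arm)
}

#' @keywords internal
check_cohort <- function(cohort) {
  if (!is.character(cohort) || length(cohort) != 1L || !(cohort %in% COHORTS)) {
    stop("unknown cohort: must be one of ", paste(COHORTS, collapse = ", "),
         call. = FALSE)
  }
  invisible(cohort)
}

# Round half away from zero, the convention used for all displayed currency.
# base::round() rounds half to even, which does not match printed tables.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
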