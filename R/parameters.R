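#' Build a state distribution over the five alive states
#'
#' A \code{state_distribution} holds the probability of occupying each of the
#' five alive medical-use states 90 days after discharge. It parameterises
#' both the cycle-0 occupancy and (through the memoryless destination
#' assumption) every subsequent cycle's destination mix.
#'
#' @param prob Named numeric vector of probabilities over
#'   \code{ALIVE_STATES}; must sum to 1 within \code{1e-9}.
#' @param counts Optional named integer vector of source patient counts.
#' @param cohort Optional cohort label (\code{"60s"}, \code{"70s"},
#'   \code{"80s"}).
#' @param ci Optional list with elements \code{low} and \code{high}, named
#'   numeric vectors of 95\% interval bounds per state.
#' @return An object of class \code{state_distribution}.
#' @export
state_distribution <- function(prob, counts = NULL, cohort = NA_character_,
                               ci = NULL) {
  if (is.null(names(prob)) || !setequal(names(prob), ALIVE_STATES)) {
    stop("prob must be named over the five alive states", call. = FALSE)
  }
  prob <- prob[ALIVE_STATES]
  if (any(prob < -1e-12 | prob > 1 + 1e-12)) {
    stop("state probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(prob) - 1) > 1e-9) {
    stop("state probabilities must sum to 1 (got ",
         format(sum(prob), digits = 12), ")", call. = FALSE)
  }
  prob <- pmin(pmax(prob, 0), 1)
  structure(
    list(prob = prob, counts = counts, cohort = cohort, ci = ci),
    class = "state_distribution"
  )
}

#' @export
print.state_distribution <- function(x, ...) {
  cat("State distribution", if (!is.na(x$cohort)) paste0("(", x$cohort, ")"),
      "\n")
  print(round(x$prob, 4))
  invisible(x)
}

#' Estimate a state distribution from patient counts
#'
#' Converts per-state patient counts (one row of the transition-probability
#' table) into occupancy probabilities \code{count / total}.
#'
#' @param counts Named non-negative numeric vector over \code{ALIVE_STATES}.
#' @param cohort Optional cohort label.
#' @return A \code{state_distribution} carrying the source counts.
#' @examples
#' d <- distribution_from_counts(
#'   c(STABLE = 548, NO_MGMT = 519, READMIT_COPD = 118,
#'     READMIT_RESP = 108, READMIT_OTHER = 285), cohort = "60s")
#' round(100 * d$prob["STABLE"], 2)  # 34.73
#' @export
distribution_from_counts <- function(counts, cohort = NA_character_) {
  if (is.null(names(counts)) || !setequal(names(counts), ALIVE_STATES)) {
    stop("counts must be named over the five alive states", call. = FALSE)
  }
  counts <- counts[ALIVE_STATES]
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  prob <- counts / total
  prob <- prob / sum(prob)  # guard against FP drift; sums to 1 exactly
  state_distribution(prob, counts = counts, cohort = cohort)
}

#' Total per-cycle medical cost of a state from its components
#'
#' Sums the reimbursed, non-reimbursed, nursing-fee and inhaler components
#' and rounds half-up to cents, matching the printed cost table.
#'
#' @param reimbursed,non_reimbursed,nursing,inhaler Non-negative component
#'   costs in USD; absent components are passed as 0.
#' @return Total cost in USD, rounded to 2 decimals.
#' @examples
#' state_total_cost(1245.09, 266.05, 883.99, 0)  # 2395.13
#' @export
state_total_cost <- function(reimbursed, non_reimbursed = 0, nursing = 0,
                             inhaler = 0) {
  comps <- c(reimbursed, non_reimbursed, nursing, inhaler)
  if (any(comps < 0)) stop("cost components must be non-negative",
                           call. = FALSE)
  round_half_up(sum(comps), 2)
}

#' Non-reimbursed cost from the reimbursed amount
#'
#' Claims data carry only reimbursed payments; the non-reimbursed share is
#' imputed as a fixed fraction (21.37\% in the bundled parameter set) of the
#' reimbursed cost.
#'
#' @param reimbursed Reimbursed cost, USD, non-negative.
#' @param share Non-reimbursement share, a fraction in \code{[0, 1)}.
#' @return Imputed non-reimbursed cost, USD, rounded to 2 decimals.
#' @export
nonreimbursed_cost <- function(reimbursed, share) {
  if (reimbursed < 0) stop("reimbursed cost must be non-negative",
                           call. = FALSE)
  if (share < 0 || share >= 1) stop("share must lie in [0, 1)", call. = FALSE)
  round_half_up(reimbursed * share, 2)
}

#' One-time per-patient cost of the transitional care service
#'
#' @param schedule Data frame with at least a numeric \code{cost} column
#'   (USD), one row per intervention item.
#' @return The summed per-patient cost, USD.
#' @export
tcs_total_cost <- function(schedule) {
  if (!is.data.frame(schedule) || nrow(schedule) == 0L) {
    stop("schedule must be a non-empty data frame", call. = FALSE)
  }
  if (is.null(schedule$cost) || any(schedule$cost < 0)) {
    stop("schedule must have a non-negative cost column", call. = FALSE)
  }
  sum(schedule$cost)
}

#' Convert Korean won to US dollars
#'
#' @param amount Amount in KRW, non-negative.
#' @param rate Exchange rate, KRW per USD, positive (1,301.50 in the bundled
#'   parameter set).
#' @param rounding \code{"cents"} rounds half-up to 2 decimals;
#'   \code{"nearest_ten"} rounds to the nearest 10 USD (used for the
#'   willingness-to-pay threshold).
#' @return Amount in USD.
#' @examples
#' krw_to_usd(111700, 1301.50)                    # 85.82
#' krw_to_usd(30e6, 1301.50, "nearest_ten")       # 23050
#' @export
krw_to_usd <- function(amount, rate, rounding = c("cents", "nearest_ten")) {
  rounding <- match.arg(rounding)
  if (any(amount < 0)) stop("amount must be non-negative", call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  usd <- amount / rate
  switch(rounding,
         cents = round_half_up(usd, 2),
         nearest_ten = round_half_up(usd / 10, 0) * 10)
}

# ---------------------------------------------------------------------------
# Parameter set assembly, validation and I/O

PARAM_SCHEMA_VERSION <- "1.0"

#' @keywords internal
param_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("tcs_validation_error",
                                             "error", "condition")))
}

#' Load a validated parameter set from a directory of parameter files
#'
#' The directory layout is one CSV per input table plus one JSON of scalar
#' constants: \code{transition_counts.csv} (cohort, state, count),
#' \code{risk_ratios.csv}, \code{costs.csv}, \code{tcs_costs.csv},
#' \code{utilities.csv}, \code{mortality_ratios.csv} and
#' \code{constants.json}. All structural invariants are checked and
#' violations reported with field paths.
#'
#' @param path Directory containing the parameter files.
#' @param schema_version Expected schema version string; mismatch is an
#'   error.
#' @param life_table Optional \code{life_table} to attach; defaults to the
#'   synthetic Gompertz–Makeham table from \code{\link{make_life_table}}.
#' @return A validated \code{parameter_set}.
#' @seealso \code{\link{paper_params}} for the bundled canonical set.
#' @export
load_parameter_set <- function(path, schema_version = PARAM_SCHEMA_VERSION,
                               life_table = NULL) {
  if (!dir.exists(path)) param_error("parameter directory not found: ", path)
  need <- c("transition_counts.csv", "risk_ratios.csv", "costs.csv",
            "tcs_costs.csv", "utilities.csv", "mortality_ratios.csv",
            "constants.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    param_error("missing parameter files: ", paste(missing, collapse = ", "))
  }
  rd <- function(f) utils::read.csv(file.path(path, f),
                                    stringsAsFactors = FALSE)
  constants <- jsonlite::read_json(file.path(path, "constants.json"),
                                   simplifyVector = TRUE)
  if (!identical(constants$schema_version, schema_version)) {
    param_error("constants.schema_version: expected ", schema_version,
                ", found ", constants$schema_version)
  }

  counts_tab <- rd("transition_counts.csv")
  distributions <- list()
  for (co in COHORTS) {
    rows <- counts_tab[counts_tab$cohort == co, ]
    absent <- setdiff(ALIVE_STATES, rows$state)
    if (length(absent)) {
      param_error("transition_counts[", co, "]: missing state ",
                  paste(absent, collapse = ", "))
    }
    extra <- setdiff(rows$state, ALIVE_STATES)
    if (length(extra)) {
      param_error("transition_counts[", co, "]: unknown state label ",
                  paste(extra, collapse = ", "))
    }
    cts <- stats::setNames(rows$count, rows$state)[ALIVE_STATES]
    if (any(cts < 0)) param_error("transition_counts[", co,
                                  "]: negative count")
    distributions[[co]] <- distribution_from_counts(cts, cohort = co)
  }

  ps <- structure(list(
    distributions = distributions,
    risk_ratios = rd("risk_ratios.csv"),
    costs = rd("costs.csv"),
    tcs_schedule = rd("tcs_costs.csv"),
    utilities = rd("utilities.csv"),
    mortality_ratios = rd("mortality_ratios.csv"),
    constants = constants[setdiff(names(constants),
                                  c("schema_version", "start_age"))],
    start_age = unlist(constants$start_age),
    life_table = if (is.null(life_table)) make_life_table(life_table_spec())
                 else life_table,
    schema_version = schema_version
  ), class = "parameter_set")
  validate_parameter_set(ps)
  ps
}

#' The bundled canonical parameter set
#'
#' Loads the parameter tables shipped with the package (transition counts,
#' relative risks, costs, intervention cost schedule, utilities, mortality
#' ratios and economic constants) and attaches a background-mortality life
#' table.
#'
#' @inheritParams load_parameter_set
#' @return A validated \code{parameter_set}.
#' @export
paper_params <- function(life_table = NULL) {
  load_parameter_set(system.file("extdata", "paper_params",
                                 package = "tcscea", mustWork = TRUE),
                     life_table = life_table)
}

#' Validate a parameter set
#'
#' Checks every structural invariant: probability rows summing to one,
#' non-negative costs with component sums matching printed totals within
#' 0.02 USD, risk-ratio and utility point estimates inside their ranges,
#' mortality ratios of at least one with period-consistent annualisation,
#' and positive economic constants with cycle length times horizon equal to
#' 10 years. Violations raise a \code{tcs_validation_error} naming the field.
#'
#' @param ps A \code{parameter_set}.
#' @return \code{ps}, invisibly, if valid.
#' @export
validate_parameter_set <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  for (co in COHORTS) {
    d <- ps$distributions[[co]]
    if (is.null(d)) param_error("distributions[", co, "]: missing cohort")
    if (abs(sum(d$prob) - 1) > 1e-9) {
      param_error("distributions[", co, "].prob: does not sum to 1 (sum = ",
                  format(sum(d$prob), digits = 12), ")")
    }
  }

  rr <- ps$risk_ratios
  absent <- setdiff(RR_STATES, rr$state)
  if (length(absent)) param_error("risk_ratios: missing state ",
                                  paste(absent, collapse = ", "))
  if ("STABLE" %in% rr$state) {
    param_error("risk_ratios: STABLE is the residual state and carries no RR")
  }
  with(rr, {
    if (any(rr <= 0)) param_error("risk_ratios.rr: must be positive")
    if (any(range_low > rr | rr > range_high)) {
      param_error("risk_ratios: point outside [range_low, range_high]")
    }
    if (any(ci_low > rr | rr > ci_high)) {
      param_error("risk_ratios: point outside [ci_low, ci_high]")
    }
  })

  ct <- ps$costs
  for (co in COHORTS) {
    rows <- ct[ct$cohort == co, ]
    absent <- setdiff(ALIVE_STATES, rows$state)
    if (length(absent)) param_error("costs[", co, "]: missing state ",
                                    paste(absent, collapse = ", "))
  }
  comp <- ct$reimbursed + ct$non_reimbursed + ct$nursing_fee + ct$inhaler
  if (any(ct$total < 0 | ct$reimbursed < 0 | ct$non_reimbursed < 0 |
          ct$nursing_fee < 0 | ct$inhaler < 0)) {
    param_error("costs: negative cost component")
  }
  bad <- which(abs(ct$total - comp) > 0.02)
  if (length(bad)) {
    param_error("costs[", ct$cohort[bad[1]], ".", ct$state[bad[1]],
                "]: total differs from component sum by more than 0.02")
  }
  if (any(ct$total[ct$state == "NO_MGMT"] != 0)) {
    param_error("costs[NO_MGMT]: must be 0 (state involves no medical use)")
  }

  if (nrow(ps$tcs_schedule) == 0L || any(ps$tcs_schedule$cost < 0)) {
    param_error("tcs_schedule: must be non-empty with non-negative costs")
  }

  ut <- ps$utilities
  absent <- setdiff(ALIVE_STATES, ut$state)
  if (length(absent)) param_error("utilities: missing state ",
                                  paste(absent, collapse = ", "))
  if (any(ut$low < 0 | ut$low > ut$utility | ut$utility > ut$high |
          ut$high > 1)) {
    param_error("utilities: require 0 <= low <= point <= high <= 1")
  }

  mr <- ps$mortality_ratios
  absent <- setdiff(ALIVE_STATES, mr$state)
  if (length(absent)) param_error("mortality_ratios: missing state ",
                                  paste(absent, collapse = ", "))
  if (any(mr$annual_ratio < 1)) {
    param_error("mortality_ratios.annual_ratio: must be >= 1")
  }
  has_period <- !is.na(mr$period_ratio)
  ann <- round_half_up(mr$period_ratio[has_period]^
                         (1 / mr$period_years[has_period]), 3)
  if (any(abs(ann - mr$annual_ratio[has_period]) > 0.001)) {
    param_error("mortality_ratios: annual_ratio inconsistent with ",
                "period_ratio^(1/period_years) beyond 0.001")
  }

  cn <- ps$constants
  for (f in c("discount_rate", "cycle_length_years", "n_cycles",
              "wtp_threshold", "krw_per_usd", "nonreimbursement_share",
              "psa_iterations")) {
    if (is.null(cn[[f]])) param_error("constants.", f, ": missing")
  }
  if (cn$discount_rate < 0) param_error("constants.discount_rate: negative")
  if (any(unlist(cn[c("cycle_length_years", "n_cycles", "wtp_threshold",
                      "krw_per_usd", "nonreimbursement_share",
                      "psa_iterations")]) <= 0)) {
    param_error("constants: all constants must be strictly positive")
  }
  if (abs(cn$cycle_length_years * cn$n_cycles - 10) > 1e-9) {
    param_error("constants: cycle_length_years * n_cycles must equal 10 years")
  }
  if (!setequal(names(ps$start_age), COHORTS)) {
    param_error("start_age: must name all three cohorts")
  }
  validate_life_table(ps$life_table)
  invisible(ps)
}

#' Write a parameter set back to the on-disk layout
#'
#' Serialises a \code{parameter_set} to the same directory layout read by
#' \code{\link{load_parameter_set}}; a load of the written directory
#' round-trips losslessly. Intended for provenance logging of validated
#' inputs.
#'
#' @param ps A validated \code{parameter_set}.
#' @param path Output directory (created if absent).
#' @return \code{path}, invisibly.
#' @export
write_parameter_set <- function(ps, path) {
  stopifnot(inherits(ps, "parameter_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(path, f),
                                         row.names = FALSE, quote = TRUE)
  counts <- do.call(rbind, lapply(COHORTS, function(co) {
    data.frame(cohort = co, state = ALIVE_STATES,
               count = as.numeric(ps$distributions[[co]]$counts[ALIVE_STATES]))
  }))
  wr(counts, "transition_counts.csv")
  wr(ps$risk_ratios, "risk_ratios.csv")
  wr(ps$costs, "costs.csv")
  wr(ps$tcs_schedule, "tcs_costs.csv")
  wr(ps$utilities, "utilities.csv")
  wr(ps$mortality_ratios, "mortality_ratios.csv")
  constants <- c(list(schema_version = ps$schema_version), ps$constants,
                 list(start_age = as.list(ps$start_age)))
  jsonlite::write_json(constants, file.path(path, "constants.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Cost-utility model parameter set (schema ", x$schema_version, ")\n",
      sep = "")
  cat("  cohorts:", paste(COHORTS, collapse = ", "), "\n")
  cat("  TCS one-time cost:", round(tcs_total_cost(x$tcs_schedule), 2),
      "USD\n")
  cat("  discount", x$constants$discount_rate, "/yr, horizon",
      x$constants$n_cycles, "cycles of", x$constants$cycle_length_years,
      "yr\n")
  invisible(x)
}

# --- internal accessors used by the engine ---------------------------------

# Per-cycle cost vector over all six states for one cohort (DEAD = 0).
#' @keywords internal
cost_vector <- function(ps, cohort) {
  rows <- ps$costs[ps$costs$cohort == cohort, ]
  v <- stats::setNames(numeric(length(MEDICAL_STATES)), MEDICAL_STATES)
  v[rows$state] <- rows$total
  v["DEAD"] <- 0
  v
}

# Annual utility weight vector over all six states (DEAD = 0).
#' @keywords internal
utility_vector <- function(ps) {
  v <- stats::setNames(numeric(length(MEDICAL_STATES)), MEDICAL_STATES)
  v[ps$utilities$state] <- ps$utilities$utility
  v["DEAD"] <- 0
  v
}

# Point relative risks as a named vector over RR_STATES.
#' @keywords internal
rr_vector <- function(ps) {
  stats::setNames(ps$risk_ratios$rr, ps$risk_ratios$state)[RR_STATES]
}

# Annual additional mortality ratios over ALIVE_STATES.
#' @keywords internal
mortality_vector <- function(ps) {
  stats::setNames(ps$mortality_ratios$annual_ratio,
                  ps$mortality_ratios$state)[ALIVE_STATES]
}
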