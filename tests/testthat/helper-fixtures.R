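# Shared fixtures. PP is the bundled parameter set with the default
# synthetic life table; loading it once keeps the suite fast.
PP <- paper_params()

# Printed transition-probability percentages, by cohort and state, frozen
# from the published table (used to check count -> percentage arithmetic).
PRINTED_PCT <- list(
  "60s" = c(STABLE = 34.73, NO_MGMT = 32.89, READMIT_COPD = 7.48,
            READMIT_RESP = 6.84, READMIT_OTHER = 18.06),
  "70s" = c(STABLE = 30.90, NO_MGMT = 30.31, READMIT_COPD = 8.31,
            READMIT_RESP = 8.49, READMIT_OTHER = 22.00),
  "80s" = c(STABLE = 24.34, NO_MGMT = 31.16, READMIT_COPD = 10.29,
            READMIT_RESP = 10.11, READMIT_OTHER = 24.10)
)

# Published per-cycle totals for the nine readmission rows (cohort, state,
# total USD), frozen from the cost table.
PRINTED_READMIT_TOTALS <- data.frame(
  cohort = rep(c("60s", "70s", "80s"), each = 3),
  state = rep(c("READMIT_COPD", "READMIT_RESP", "READMIT_OTHER"), 3),
  total = c(2395.13, 2931.74, 2976.15,
            2467.40, 3078.42, 2933.76,
            2556.49, 3147.07, 2822.57),
  stringsAsFactors = FALSE
)

# A constant-mortality life table: q at every age, 1 at the terminal age.
flat_life_table <- function(q, age_min = 60, age_max = 110) {
  ages <- age_min:age_max
  life_table(ages, c(rep(q, length(ages) - 1L), 1))
}

# Parameter set reduced to a degenerate two-state world: all mass on
# STABLE, no intervention effect, constant annual death probability q.
# Used as the analytic (geometric-series) oracle configuration.
degenerate_params <- function(q = 0.1) {
  ps <- paper_params(life_table = flat_life_table(q))
  for (co in COHORTS) {
    ps$distributions[[co]] <- state_distribution(
      c(STABLE = 1, NO_MGMT = 0, READMIT_COPD = 0, READMIT_RESP = 0,
        READMIT_OTHER = 0), cohort = co)
    ps$distributions[[co]]$counts <-
      c(STABLE = 100, NO_MGMT = 0, READMIT_COPD = 0, READMIT_RESP = 0,
        READMIT_OTHER = 0)
  }
  ps$risk_ratios$rr <- rep(1, nrow(ps$risk_ratios))
  ps$mortality_ratios$annual_ratio <- rep(1, nrow(ps$mortality_ratios))
  ps$mortality_ratios$period_ratio <- NA_real_
  ps$mortality_ratios$period_years <- NA_real_
  ps
}

# Random valid state distribution (Dirichlet via gammas).
random_distribution <- function(cohort = "60s") {
  p <- stats::rgamma(5, shape = 1)
  p <- p / sum(p)
  names(p) <- ALIVE_STATES
  state_distribution(p, cohort = cohort)
}
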