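test_that("annualize_period_ratio reproduces the published conversions", {
  expect_equal(round(annualize_period_ratio(2.34, 3), 3), 1.328)
  expect_equal(round(annualize_period_ratio(1.14, 1.5), 3), 1.091)
  expect_equal(round(annualize_period_ratio(1.18, 1.5), 3), 1.117)
  expect_equal(annualize_period_ratio(1.0, 7), 1.0)
  expect_error(annualize_period_ratio(0, 1), "positive")
  expect_error(annualize_period_ratio(1.5, -1), "positive")
})

test_that("annual and cycle probabilities are survival-consistent", {
  expect_equal(annual_to_cycle_prob(0, 4), 0)
  expect_equal(annual_to_cycle_prob(1, 4), 1)
  qc <- annual_to_cycle_prob(0.04, 4)
  expect_equal(round(qc, 6), 0.010154)
  expect_equal((1 - qc)^4, 0.96, tolerance = 1e-12)  # compounding oracle
  expect_error(annual_to_cycle_prob(1.2, 4), "\\[0, 1\\]")

  # survival-scale identity linking the two converters: a period ratio r
  # over p years equals r^(1/p) per year compounded p times
  for (r in c(1.14, 1.66, 2.34)) {
    for (p in c(1.5, 3)) {
      ann <- annualize_period_ratio(r, p)
      expect_equal(ann^p, r, tolerance = 1e-12)
    }
  }
})

test_that("apply_relative_risks matches direct arithmetic on printed values", {
  dist <- state_distribution(c(STABLE = 0.3473, NO_MGMT = 0.3289,
                               READMIT_COPD = 0.0748, READMIT_RESP = 0.0684,
                               READMIT_OTHER = 0.1806))
  rr <- c(NO_MGMT = 0.704, READMIT_COPD = 0.599, READMIT_RESP = 0.720,
          READMIT_OTHER = 0.720)
  adj <- apply_relative_risks(dist, rr, "TCS")
  expect_lt(abs(adj$prob[["NO_MGMT"]] - 0.23155), 1e-4)
  expect_lt(abs(adj$prob[["READMIT_COPD"]] - 0.04481), 1e-4)
  expect_lt(abs(adj$prob[["STABLE"]] - 0.54436), 1e-4)
  expect_equal(sum(adj$prob), 1)

  # null intervention and usual care leave the distribution unchanged
  ones <- c(NO_MGMT = 1, READMIT_COPD = 1, READMIT_RESP = 1,
            READMIT_OTHER = 1)
  expect_equal(apply_relative_risks(dist, ones, "TCS")$prob, dist$prob)
  expect_identical(apply_relative_risks(dist, rr, "USUAL_CARE"), dist)

  # two-state residual check
  two <- state_distribution(c(STABLE = 0.2, NO_MGMT = 0.8,
                              READMIT_COPD = 0, READMIT_RESP = 0,
                              READMIT_OTHER = 0))
  half <- c(NO_MGMT = 0.5, READMIT_COPD = 1, READMIT_RESP = 1,
            READMIT_OTHER = 1)
  expect_equal(unname(apply_relative_risks(two, half, "TCS")$prob),
               c(0.6, 0.4, 0, 0, 0))

  # over-unity adjusted mass is reported, not clamped
  big <- c(NO_MGMT = 3, READMIT_COPD = 3, READMIT_RESP = 3,
           READMIT_OTHER = 3)
  expect_error(apply_relative_risks(dist, big, "TCS"), "exceeds 1")
})

test_that("apply_relative_risks conserves mass and orders probabilities", {
  set.seed(202)
  rr_pp <- tcscea:::rr_vector(PP)
  for (i in 1:200) {
    d <- random_distribution()
    rr <- stats::setNames(runif(4, 0.3, 0.99), RR_STATES)
    adj <- apply_relative_risks(d, rr, "TCS")
    expect_equal(sum(adj$prob), 1, tolerance = 1e-12)
    # RR < 1 strictly shrinks each RR-bearing state, grows STABLE
    pos <- d$prob[RR_STATES] > 0
    expect_true(all(adj$prob[RR_STATES][pos] < d$prob[RR_STATES][pos]))
    if (any(pos)) expect_gt(adj$prob["STABLE"], d$prob["STABLE"])
  }
  expect_named(rr_pp, RR_STATES)
})

test_that("cycle_death_prob multiplies the ratio then converts to cycles", {
  lt <- flat_life_table(0.05)
  ratios <- stats::setNames(c(1, 1.328, 1.66, 1.091, 1.117), ALIVE_STATES)
  # COPD readmission: 1.66 x 0.05 = 0.083 annually
  expect_equal(cycle_death_prob(65, "READMIT_COPD", lt, ratios),
               1 - (1 - 0.083)^0.25, tolerance = 1e-12)
  expect_equal(round(cycle_death_prob(65, "READMIT_COPD", lt, ratios), 6),
               0.021429)
  # STABLE uses the raw life-table probability
  expect_equal(cycle_death_prob(65, "STABLE", lt, ratios),
               annual_to_cycle_prob(0.05, 4))
  # ratio x q capped at 1 -> certain death in the cycle
  lt9 <- flat_life_table(0.9)
  expect_equal(cycle_death_prob(65, "READMIT_COPD", lt9, ratios), 1)
  expect_error(cycle_death_prob(200, "STABLE", lt, ratios), "outside")
  expect_error(cycle_death_prob(65, "DEAD", lt, ratios), "unknown state")
})

test_that("run_cohort's vectorised mortality equals cycle_death_prob", {
  ratios <- tcscea:::mortality_vector(PP)
  lt <- PP$life_table
  for (age in c(60, 75, 89)) {
    d <- vapply(ALIVE_STATES, function(s) cycle_death_prob(age, s, lt,
                                                           ratios),
                numeric(1))
    q <- annual_death_prob(lt, age)
    vec <- annual_to_cycle_prob(pmin(ratios * q, 1), 4)
    expect_equal(unname(vec), unname(d), tolerance = 1e-15)
  }
})

test_that("build_cycle_matrix composes death-first competing risks", {
  dist <- distribution_from_counts(c(STABLE = 548, NO_MGMT = 519,
                                     READMIT_COPD = 118,
                                     READMIT_RESP = 108,
                                     READMIT_OTHER = 285))
  zero <- stats::setNames(rep(0, 5), ALIVE_STATES)
  m0 <- build_cycle_matrix(dist, zero, "USUAL_CARE")
  for (s in ALIVE_STATES) {
    expect_equal(unname(m0[s, ALIVE_STATES]), unname(dist$prob))
  }
  expect_equal(unname(m0["DEAD", ]), c(0, 0, 0, 0, 0, 1))

  one <- stats::setNames(rep(1, 5), ALIVE_STATES)
  m1 <- build_cycle_matrix(dist, one, "USUAL_CARE")
  expect_true(all(m1[, "DEAD"] == 1))
  expect_true(all(m1[, ALIVE_STATES] == 0))

  flat <- stats::setNames(rep(0.01, 5), ALIVE_STATES)
  m <- build_cycle_matrix(dist, flat, "USUAL_CARE")
  expect_equal(m[["STABLE", "STABLE"]], 0.99 * 548 / 1578,
               tolerance = 1e-12)
  expect_equal(round(m[["STABLE", "STABLE"]], 4), 0.3438)

  expect_error(build_cycle_matrix(dist, replace(flat, 1, 1.5),
                                  "USUAL_CARE"), "\\[0, 1\\]")
})

test_that("build_cycle_matrix is row-stochastic on randomized inputs", {
  set.seed(77)
  for (i in 1:100) {
    d <- random_distribution()
    dp <- stats::setNames(runif(5), ALIVE_STATES)
    m <- build_cycle_matrix(d, dp, sample(ARMS, 1))
    expect_true(all(abs(rowSums(m) - 1) <= 1e-9))
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(unname(m["DEAD", "DEAD"]), 1)
  }
})

test_that("matrix_to_long exports the audit layout", {
  dist <- PP$distributions[["60s"]]
  m <- build_cycle_matrix(dist, stats::setNames(rep(0.02, 5), ALIVE_STATES),
                          "TCS", cycle = 3L, age = 60L)
  long <- matrix_to_long(m)
  expect_equal(nrow(long), 36)
  expect_setequal(names(long), c("from_state", "to_state", "probability",
                                 "cycle", "arm"))
  expect_equal(sum(long$probability), 6, tolerance = 1e-9)
  expect_true(all(long$arm == "TCS") && all(long$cycle == 3))
})
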