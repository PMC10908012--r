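test_that("log-normal CI fits put the median at the geometric mean", {
  f <- fit_lognormal_from_ci(0.421, 0.852)
  expect_equal(round(f$median, 3), 0.599)
  expect_equal(f$median, sqrt(0.421 * 0.852), tolerance = 1e-12)
  f2 <- fit_lognormal_from_ci(0.531, 0.978)
  expect_equal(round(f2$median, 3), 0.721)
  expect_equal(round(f2$median, 2), 0.72)
  # the fitted quantiles recover the bounds
  expect_equal(stats::qlnorm(c(0.025, 0.975), f$meanlog, f$sdlog),
               c(0.421, 0.852), tolerance = 1e-9)

  deg <- fit_lognormal_from_ci(0.7, 0.7)
  expect_equal(deg$sdlog, 0)
  expect_true(all(sample_psa(deg, 5) == 0.7))
  expect_error(fit_lognormal_from_ci(0, 1), "0 < lo")
  expect_error(fit_lognormal_from_ci(0.9, 0.5), "lo <= hi")
})

test_that("beta range fits match their stated mean and stay in (0,1)", {
  f <- fit_beta_from_range(0.795, 0.716, 0.875)
  set.seed(5)
  draws <- sample_psa(f, 1e4)
  expect_lt(abs(mean(draws) - 0.795), 0.005)
  expect_true(all(draws > 0 & draws < 1))

  f2 <- fit_beta_from_range(0.61, 0.549, 0.671)
  draws2 <- sample_psa(f2, 2000)
  expect_true(all(draws2 > 0 & draws2 < 1))

  point <- fit_beta_from_range(0.5, 0.5, 0.5)
  expect_true(all(sample_psa(point, 10) == 0.5))
  expect_error(fit_beta_from_range(1.2, 0, 1), "\\(0, 1\\)")
  expect_error(tcscea:::fit_beta_moments(0.01, 0.25), "infeasible")
})

test_that("gamma fits preserve the mean exactly", {
  f <- fit_gamma(2395.13, 0.2)
  expect_equal(f$shape, 25)
  expect_equal(f$shape * f$scale, 2395.13, tolerance = 1e-12)
  expect_equal(fit_gamma(1, 1)$shape, 1)  # exponential
  set.seed(6)
  draws <- sample_psa(f, 1e4)
  se <- 2395.13 * 0.2 / sqrt(1e4)
  expect_lt(abs(mean(draws) - 2395.13), 3 * se)
  expect_error(fit_gamma(0, 0.2), "positive")
})

test_that("sampled parameter means match specification within 3 MC SEs", {
  set.seed(40)
  fits <- psa_distributions(PP, "70s")
  n <- 1e4
  for (f in c(fits$utility, fits$cost, list(fits$tcs_cost))) {
    draws <- sample_psa(f, n)
    m <- if (f$family == "gamma") f$shape * f$scale
         else f$shape1 / (f$shape1 + f$shape2)
    expect_lt(abs(mean(draws) - m), 3 * stats::sd(draws) / sqrt(n) + 1e-12)
  }
})

test_that("renormalized transition draws stay on the simplex", {
  set.seed(41)
  fits <- psa_distributions(PP, "80s")
  for (i in 1:100) {
    pr <- vapply(fits$prob, sample_psa, numeric(1))
    pr <- pr / sum(pr)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0 & pr <= 1))
  }
})

test_that("parameter paths resolve, set, and reject unknowns", {
  expect_equal(get_param(PP, "constants.discount_rate"), 0.045)
  expect_equal(get_param(PP, "tcs_cost"), 251.25)
  expect_equal(get_param(PP, "rr.READMIT_COPD"), 0.599)
  expect_equal(get_param(PP, "utility.READMIT_RESP"), 0.52)
  expect_equal(get_param(PP, "cost.70s.READMIT_COPD"), 2467.40)
  expect_equal(get_param(PP, "prob.60s.STABLE"), 548 / 1578)

  ps <- set_param(PP, "tcs_cost", 314.0625)
  expect_equal(tcs_total_cost(ps$tcs_schedule), 314.0625)
  ps <- set_param(PP, "cost.60s.READMIT_OTHER", 1000)
  i <- ps$costs$cohort == "60s" & ps$costs$state == "READMIT_OTHER"
  expect_equal(ps$costs$total[i], 1000)
  expect_equal(ps$costs$reimbursed[i] + ps$costs$non_reimbursed[i] +
                 ps$costs$nursing_fee[i] + ps$costs$inhaler[i], 1000,
               tolerance = 0.02)
  ps <- set_param(PP, "prob.80s.READMIT_OTHER", 0.3)
  expect_equal(sum(ps$distributions[["80s"]]$prob), 1, tolerance = 1e-12)
  expect_equal(unname(ps$distributions[["80s"]]$prob["READMIT_OTHER"]), 0.3)

  # a path that does not enter the model is rejected, never silently zero
  expect_error(get_param(PP, "rr.STABLE"), "unknown")
  expect_error(get_param(PP, "gadget.flux"), "unknown parameter path")
  expect_error(set_param(PP, "nothing.here", 1), "unknown")
  expect_error(set_param(PP, "utility.STABLE", 1.5), "\\[0, 1\\]")
  expect_error(set_param(PP, "rr.READMIT_RESP", -1), "positive")
})

test_that("one_way_dsa orders by swing with exact TCS-cost linearity", {
  specs <- list(
    dsa_spec("tcs_cost", 188.4375, 314.0625),
    dsa_spec("rr.READMIT_OTHER", 0.648, 0.792, "table range"),
    dsa_spec("utility.STABLE", 0.795, 0.795)  # low = high = base
  )
  t <- one_way_dsa(PP, specs, "60s", wtp = 23050)
  expect_s3_class(t, "tornado")
  expect_true(all(diff(t$swing) <= 1e-12))  # descending
  # NMB is linear in a one-time cost: swing is exactly the band width
  expect_equal(t$swing[t$parameter == "tcs_cost"], 125.625,
               tolerance = 1e-6)
  # degenerate spec contributes zero swing and sorts last
  expect_equal(t$swing[nrow(t)], 0)
  expect_identical(t$parameter[nrow(t)], "utility.STABLE")

  expect_error(one_way_dsa(PP, list(dsa_spec("rr.READMIT_COPD", 0.9, 1.1)),
                           "60s"), "outside")
})

test_that("default DSA ranks other-disease readmission parameters highly", {
  t <- one_way_dsa(PP, default_dsa_specs(PP, "60s"), "60s")
  top5 <- t$parameter[1:5]
  expect_true(any(grepl("READMIT_OTHER", top5)))
  expect_setequal(
    t$parameter,
    vapply(default_dsa_specs(PP, "60s"), function(s) s$path, character(1)))
})

test_that("PSA collapses to the baseline under degenerate distributions", {
  base <- baseline_analysis(PP, "70s")[["70s"]]
  point <- function(x) structure(list(family = "beta", point = x),
                                 class = "psa_distribution")
  d <- PP$distributions[["70s"]]$prob
  ct <- PP$costs[PP$costs$cohort == "70s" & PP$costs$total > 0, ]
  fits <- list(
    rr = lapply(stats::setNames(PP$risk_ratios$rr, PP$risk_ratios$state),
                point),
    utility = lapply(stats::setNames(PP$utilities$utility,
                                     PP$utilities$state), point),
    prob = lapply(as.list(d), point),
    cost = lapply(stats::setNames(ct$total, ct$state), point),
    tcs_cost = point(251.25))
  psa <- run_psa(PP, n_iter = 1, seed = 8, cohort = "70s", fits = fits)
  expect_equal(psa$draws$delta_cost, base$delta_cost, tolerance = 1e-9)
  expect_equal(psa$draws$delta_qaly, base$delta_effect, tolerance = 1e-9)
})

test_that("PSA is reproducible for a fixed seed", {
  p1 <- run_psa(PP, 25, seed = 123, cohort = "60s")
  p2 <- run_psa(PP, 25, seed = 123, cohort = "60s")
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(PP, 25, seed = 124, cohort = "60s")
  expect_false(identical(p1$draws, p3$draws))
  expect_error(run_psa(PP, 0, seed = 1, cohort = "60s"), ">= 1")
  expect_error(run_psa(PP, 5, cohort = "60s"), "seed")
})

test_that("ceac computes strict-NMB acceptance fractions", {
  dom <- structure(list(
    draws = data.frame(iteration = 1:4, delta_cost = c(-5, -1, -8, -2),
                       delta_qaly = c(0.1, 0.2, 0.3, 0.4)),
    n_iter = 4L, seed = 1L, cohort = "60s"), class = "psa_result")
  cv <- ceac(dom, c(0, 23050, 50000))
  expect_equal(cv$probability, c(1, 1, 1))

  mix <- structure(list(
    draws = data.frame(iteration = 1:2, delta_cost = c(-100, 100),
                       delta_qaly = c(0.1, 0.1)),
    n_iter = 2L, seed = 1L, cohort = "60s"), class = "psa_result")
  # at wtp 1000: NMB = +200 and 0; the tie counts as not cost-effective
  expect_equal(ceac(mix, c(0, 1000))$probability, c(0.5, 0.5))
  expect_equal(ceac(mix, c(0))$probability,
               mean(mix$draws$delta_cost < 0))

  # monotone non-decreasing whenever every draw has non-negative effect
  set.seed(55)
  rnd <- structure(list(
    draws = data.frame(iteration = 1:50, delta_cost = rnorm(50, 0, 300),
                       delta_qaly = runif(50, 0, 0.3)),
    n_iter = 50L, seed = 1L, cohort = "60s"), class = "psa_result")
  cv2 <- ceac(rnd, seq(0, 40000, by = 1000))
  expect_true(all(diff(cv2$probability) >= 0))
  # limit: fraction of draws with positive effect
  expect_equal(ceac(rnd, c(1e9))$probability,
               mean(rnd$draws$delta_qaly > 0), tolerance = 0.05)

  expect_error(ceac(dom, c(3, 2, 1)), "ascending")
  expect_error(ceac(dom, numeric(0)), "ascending|non-empty")
})
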