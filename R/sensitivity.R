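#' Fit a log-normal distribution from a 95\% confidence interval
#'
#' Used for relative risks: the log-normal is parameterised so that the
#' interval bounds sit at the 2.5th and 97.5th percentiles, making the
#' median the geometric mean of the bounds.
#'
#' @param lo,hi Interval bounds, \code{0 < lo <= hi}. Equal bounds give a
#'   point mass.
#' @param target Optional label of the parameter the distribution feeds.
#' @return A \code{psa_distribution} (family \code{"lognormal"}) with
#'   \code{meanlog}, \code{sdlog} and a \code{median} element.
#' @examples
#' round(fit_lognormal_from_ci(0.421, 0.852)$median, 3)  # 0.599
#' @export
fit_lognormal_from_ci <- function(lo, hi, target = NULL) {
  if (lo <= 0 || hi <= 0 || lo > hi) {
    stop("require 0 < lo <= hi", call. = FALSE)
  }
  meanlog <- (log(lo) + log(hi)) / 2
  sdlog <- (log(hi) - log(lo)) / (2 * stats::qnorm(0.975))
  structure(list(family = "lognormal", meanlog = meanlog, sdlog = sdlog,
                 median = exp(meanlog), target = target),
            class = "psa_distribution")
}

#' Fit a beta distribution from a mean and a symmetric range
#'
#' Used for utilities and transition probabilities: the range half-width is
#' read as 1.96 standard deviations and the beta shapes are moment-matched
#' to that mean and standard deviation. A zero-width range gives a point
#' mass.
#'
#' @param mean Mean in (0, 1).
#' @param lo,hi Range bounds with \code{lo <= mean <= hi}.
#' @param target Optional parameter label.
#' @return A \code{psa_distribution} (family \code{"beta"}) with
#'   \code{shape1}, \code{shape2}.
#' @export
fit_beta_from_range <- function(mean, lo, hi, target = NULL) {
  if (mean <= 0 || mean >= 1) stop("mean must lie in (0, 1)", call. = FALSE)
  if (lo > mean || mean > hi) stop("require lo <= mean <= hi", call. = FALSE)
  sd <- (hi - lo) / (2 * stats::qnorm(0.975))
  fit_beta_moments(mean, sd, target)
}

#' @keywords internal
fit_beta_moments <- function(mean, sd, target = NULL) {
  if (sd == 0) {
    return(structure(list(family = "beta", shape1 = Inf, shape2 = Inf,
                          point = mean, target = target),
                     class = "psa_distribution"))
  }
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("implied variance ", format(v, digits = 4),
         " infeasible for a beta with mean ", mean, call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  structure(list(family = "beta", shape1 = mean * nu,
                 shape2 = (1 - mean) * nu, target = target),
            class = "psa_distribution")
}

#' Fit a gamma distribution from a mean and coefficient of variation
#'
#' Used for costs: shape \eqn{1/cv^2}, scale \eqn{mean \cdot cv^2}, so the
#' fitted mean is exact.
#'
#' @param mean Mean cost, USD, positive.
#' @param cv Coefficient of variation, positive.
#' @param target Optional parameter label.
#' @return A \code{psa_distribution} (family \code{"gamma"}) with
#'   \code{shape}, \code{scale}.
#' @export
fit_gamma <- function(mean, cv, target = NULL) {
  if (mean <= 0 || cv <= 0) stop("mean and cv must be positive",
                                 call. = FALSE)
  structure(list(family = "gamma", shape = 1 / cv^2, scale = mean * cv^2,
                 target = target),
            class = "psa_distribution")
}

#' Draw from a fitted PSA distribution
#'
#' @param dist A \code{psa_distribution}.
#' @param n Number of draws.
#' @return Numeric vector of \code{n} draws; point-mass fits return the
#'   point.
#' @export
sample_psa <- function(dist, n = 1L) {
  stopifnot(inherits(dist, "psa_distribution"))
  switch(dist$family,
    lognormal = if (dist$sdlog == 0) rep(dist$median, n)
                else stats::rlnorm(n, dist$meanlog, dist$sdlog),
    beta = if (!is.null(dist$point)) rep(dist$point, n)
           else stats::rbeta(n, dist$shape1, dist$shape2),
    gamma = stats::rgamma(n, shape = dist$shape, scale = dist$scale),
    stop("unknown family ", dist$family, call. = FALSE))
}

# ---------------------------------------------------------------------------
# Parameter paths: a small addressing scheme for one-way DSA

#' Read a scalar model parameter by path
#'
#' Paths: \code{constants.discount_rate}, \code{tcs_cost},
#' \code{rr.<STATE>}, \code{utility.<STATE>},
#' \code{cost.<cohort>.<STATE>}, \code{prob.<cohort>.<STATE>}. Unknown
#' paths are rejected, never silently ignored.
#'
#' @param params A \code{parameter_set}.
#' @param path Parameter path string.
#' @return The scalar base value.
#' @export
get_param <- function(params, path) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  switch(p[1],
    constants = {
      if (length(p) != 2L || is.null(params$constants[[p[2]]])) {
        stop("unknown constants path: ", path, call. = FALSE)
      }
      params$constants[[p[2]]]
    },
    tcs_cost = tcs_total_cost(params$tcs_schedule),
    rr = {
      if (length(p) != 2L || !(p[2] %in% params$risk_ratios$state)) {
        stop("unknown rr path: ", path, call. = FALSE)
      }
      params$risk_ratios$rr[params$risk_ratios$state == p[2]]
    },
    utility = {
      if (length(p) != 2L || !(p[2] %in% params$utilities$state)) {
        stop("unknown utility path: ", path, call. = FALSE)
      }
      params$utilities$utility[params$utilities$state == p[2]]
    },
    cost = {
      if (length(p) != 3L) stop("cost path must be cost.<cohort>.<state>",
                                call. = FALSE)
      i <- which(params$costs$cohort == p[2] & params$costs$state == p[3])
      if (length(i) != 1L) stop("unknown cost path: ", path, call. = FALSE)
      params$costs$total[i]
    },
    prob = {
      if (length(p) != 3L || !(p[2] %in% COHORTS) ||
          !(p[3] %in% ALIVE_STATES)) {
        stop("unknown prob path: ", path, call. = FALSE)
      }
      unname(params$distributions[[p[2]]]$prob[p[3]])
    },
    stop("unknown parameter path: ", path, call. = FALSE))
}

#' Set a scalar model parameter by path
#'
#' Returns a modified copy; see \code{\link{get_param}} for the path
#' grammar. Setting \code{tcs_cost} rescales the item schedule so the total
#' equals the value; setting a state cost rescales its components; setting
#' a transition probability rescales the other four states to keep the
#' simplex constraint.
#'
#' @inheritParams get_param
#' @param value New scalar value; must respect the parameter's domain.
#' @return A modified \code{parameter_set}.
#' @export
set_param <- function(params, path, value) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  get_param(params, path)  # rejects unknown paths
  switch(p[1],
    constants = {
      if (p[2] == "discount_rate" && value < 0) {
        stop("discount_rate must be non-negative", call. = FALSE)
      }
      params$constants[[p[2]]] <- value
    },
    tcs_cost = {
      if (value < 0) stop("tcs_cost must be non-negative", call. = FALSE)
      base <- tcs_total_cost(params$tcs_schedule)
      params$tcs_schedule$cost <- params$tcs_schedule$cost * value / base
    },
    rr = {
      if (value <= 0) stop("relative risk must be positive", call. = FALSE)
      params$risk_ratios$rr[params$risk_ratios$state == p[2]] <- value
    },
    utility = {
      if (value < 0 || value > 1) stop("utility must lie in [0, 1]",
                                       call. = FALSE)
      params$utilities$utility[params$utilities$state == p[2]] <- value
    },
    cost = {
      if (value < 0) stop("cost must be non-negative", call. = FALSE)
      i <- which(params$costs$cohort == p[2] & params$costs$state == p[3])
      base <- params$costs$total[i]
      if (base == 0) stop("cannot scale a zero-cost state: ", path,
                          call. = FALSE)
      f <- value / base
      for (col in c("total", "reimbursed", "non_reimbursed", "nursing_fee",
                    "inhaler")) {
        params$costs[[col]][i] <- params$costs[[col]][i] * f
      }
    },
    prob = {
      if (value < 0 || value > 1) stop("probability must lie in [0, 1]",
                                       call. = FALSE)
      d <- params$distributions[[p[2]]]
      pr <- d$prob
      rest <- setdiff(ALIVE_STATES, p[3])
      old_rest <- sum(pr[rest])
      if (old_rest <= 0 && value < 1) {
        stop("cannot renormalize: no mass outside ", p[3], call. = FALSE)
      }
      pr[p[3]] <- value
      pr[rest] <- if (value < 1) pr[rest] * (1 - value) / old_rest else 0
      params$distributions[[p[2]]] <- state_distribution(pr, cohort = p[2])
    })
  params
}

#' One-way deterministic sensitivity specification
#'
#' @param path Parameter path (see \code{\link{get_param}}).
#' @param low,high Bounds to evaluate, \code{low <= high}.
#' @param source Provenance note (e.g. \code{"table range"},
#'   \code{"default band"}).
#' @return A \code{dsa_spec}.
#' @export
dsa_spec <- function(path, low, high, source = "default band") {
  if (low > high) stop("require low <= high", call. = FALSE)
  structure(list(path = path, low = low, high = high, source = source),
            class = "dsa_spec")
}

#' Default one-way sensitivity specifications for a cohort
#'
#' Builds the standard set: discount rate 0–9\% (zero to twice the base),
#' intervention and state costs \eqn{\pm 25\%}, relative risks and
#' utilities at their published ranges, and transition probabilities at
#' \eqn{\pm 1.96} binomial standard errors from the source counts.
#'
#' @param params A \code{parameter_set}.
#' @param cohort Cohort label.
#' @return List of \code{dsa_spec}.
#' @export
default_dsa_specs <- function(params, cohort) {
  check_cohort(cohort)
  specs <- list(
    dsa_spec("constants.discount_rate", 0, 0.09, "default band"))
  tc <- tcs_total_cost(params$tcs_schedule)
  specs <- c(specs, list(dsa_spec("tcs_cost", 0.75 * tc, 1.25 * tc,
                                  "default band")))
  rr <- params$risk_ratios
  specs <- c(specs, lapply(seq_len(nrow(rr)), function(i) {
    dsa_spec(paste0("rr.", rr$state[i]), rr$range_low[i], rr$range_high[i],
             "table range")
  }))
  ut <- params$utilities
  specs <- c(specs, lapply(seq_len(nrow(ut)), function(i) {
    dsa_spec(paste0("utility.", ut$state[i]), ut$low[i], ut$high[i],
             "table range")
  }))
  ct <- params$costs[params$costs$cohort == cohort &
                     params$costs$total > 0, ]
  specs <- c(specs, lapply(seq_len(nrow(ct)), function(i) {
    dsa_spec(paste0("cost.", cohort, ".", ct$state[i]),
             0.75 * ct$total[i], 1.25 * ct$total[i], "default band")
  }))
  d <- params$distributions[[cohort]]
  n <- sum(d$counts)
  z <- stats::qnorm(0.975)
  specs <- c(specs, lapply(ALIVE_STATES, function(s) {
    p <- unname(d$prob[s])
    se <- sqrt(p * (1 - p) / n)
    dsa_spec(paste0("prob.", cohort, ".", s),
             max(0, p - z * se), min(1, p + z * se), "binomial CI")
  }))
  specs
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For each specification the full baseline pipeline is re-run with the
#' parameter at its low and at its high bound, all other parameters at
#' base; the outcome is net monetary benefit at the reference
#' willingness-to-pay. Entries are sorted by swing (absolute difference of
#' the two outcomes), descending — the tornado ordering.
#'
#' @param params A \code{parameter_set}.
#' @param specs List of \code{\link{dsa_spec}} (default
#'   \code{\link{default_dsa_specs}}).
#' @param cohort Cohort label.
#' @param wtp Reference willingness-to-pay, USD/QALY (default the
#'   parameter set's threshold).
#' @return Data frame of class \code{tornado}: \code{parameter},
#'   \code{low}, \code{high}, \code{outcome_low}, \code{outcome_high},
#'   \code{swing}, plus \code{base_nmb} as an attribute.
#' @export
one_way_dsa <- function(params, specs = default_dsa_specs(params, cohort),
                        cohort, wtp = params$constants$wtp_threshold) {
  check_cohort(cohort)
  nmb_at <- function(ps) {
    ce <- incremental_result(run_arm(ps, "TCS", cohort),
                             run_arm(ps, "USUAL_CARE", cohort), cohort)
    net_monetary_benefit(ce, wtp)$nmb
  }
  base_nmb <- nmb_at(params)
  rows <- lapply(specs, function(sp) {
    stopifnot(inherits(sp, "dsa_spec"))
    base <- get_param(params, sp$path)
    if (sp$low > base + 1e-9 || base - 1e-9 > sp$high) {
      stop("dsa spec ", sp$path, ": base value ", format(base),
           " outside [low, high]", call. = FALSE)
    }
    lo <- nmb_at(set_param(params, sp$path, sp$low))
    hi <- nmb_at(set_param(params, sp$path, sp$high))
    data.frame(parameter = sp$path, low = sp$low, high = sp$high,
               outcome_low = lo, outcome_high = hi,
               swing = abs(hi - lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  structure(out, class = c("tornado", "data.frame"),
            base_nmb = base_nmb, cohort = cohort, wtp = wtp)
}

# ---------------------------------------------------------------------------
# Probabilistic sensitivity analysis

#' Register the PSA distributions for one cohort
#'
#' Costs get gamma distributions (published means, default coefficient of
#' variation 0.2); utilities get betas moment-matched to their published
#' ranges; transition probabilities get per-state betas moment-matched to
#' the estimated proportion and its binomial standard error (renormalised
#' to the simplex after sampling); relative risks get log-normals fitted to
#' their 95\% confidence intervals.
#'
#' @param params A \code{parameter_set}.
#' @param cohort Cohort label.
#' @param cost_cv Coefficient of variation for all cost gammas.
#' @return Named list of distribution groups (\code{rr}, \code{utility},
#'   \code{prob}, \code{cost}, \code{tcs_cost}).
#' @export
psa_distributions <- function(params, cohort, cost_cv = 0.2) {
  check_cohort(cohort)
  rr <- params$risk_ratios
  rr_fits <- stats::setNames(lapply(seq_len(nrow(rr)), function(i) {
    fit_lognormal_from_ci(rr$ci_low[i], rr$ci_high[i],
                          target = paste0("rr.", rr$state[i]))
  }), rr$state)

  # States citing the identical published estimate (value and range) share
  # one utility parameter and will receive a common draw; sampling them
  # independently would invent an ordering the evidence does not contain.
  ut <- params$utilities
  key <- paste(ut$utility, ut$low, ut$high)
  util_fits <- stats::setNames(lapply(seq_len(nrow(ut)), function(i) {
    members <- ut$state[key == key[i]]
    fit_beta_from_range(ut$utility[i], ut$low[i], ut$high[i],
                        target = paste0("utility.",
                                        paste(members, collapse = "+")))
  }), ut$state)

  d <- params$distributions[[cohort]]
  n <- sum(d$counts)
  prob_fits <- stats::setNames(lapply(ALIVE_STATES, function(s) {
    p <- unname(d$prob[s])
    fit_beta_moments(p, sqrt(p * (1 - p) / n),
                     target = paste0("prob.", cohort, ".", s))
  }), ALIVE_STATES)

  ct <- params$costs[params$costs$cohort == cohort &
                     params$costs$total > 0, ]
  cost_fits <- stats::setNames(lapply(seq_len(nrow(ct)), function(i) {
    fit_gamma(ct$total[i], cost_cv,
              target = paste0("cost.", cohort, ".", ct$state[i]))
  }), ct$state)

  list(rr = rr_fits, utility = util_fits, prob = prob_fits,
       cost = cost_fits,
       tcs_cost = fit_gamma(tcs_total_cost(params$tcs_schedule), cost_cv,
                            target = "tcs_cost"))
}

#' Probabilistic sensitivity analysis by Monte-Carlo propagation
#'
#' Each iteration draws every registered parameter from its fitted
#' distribution (independent draws; per-state transition-probability betas
#' renormalised to sum to 1), reruns both arms through the cohort engine
#' and records the incremental cost and effect pair. Mortality ratios and
#' the life table are held at base (no uncertainty is published for them).
#'
#' @param params A \code{parameter_set}.
#' @param n_iter Number of iterations, \eqn{\ge 1} (10,000 at full scale).
#' @param seed Integer seed; the only source of randomness.
#' @param cohort Cohort label.
#' @param cost_cv Coefficient of variation for cost gammas (default 0.2).
#' @param fits Distribution registry as returned by
#'   \code{\link{psa_distributions}}; override to substitute alternative
#'   (e.g. degenerate) distributions. Fitting failures surface here, before
#'   any iteration runs.
#' @return A \code{psa_result}: list with \code{draws} (data frame
#'   \code{iteration}, \code{delta_cost}, \code{delta_qaly}),
#'   \code{n_iter}, \code{seed}, \code{cohort}.
#' @export
run_psa <- function(params, n_iter, seed, cohort, cost_cv = 0.2,
                    fits = NULL) {
  check_cohort(cohort)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (missing(seed) || !is.numeric(seed)) {
    stop("an integer seed is required", call. = FALSE)
  }
  if (is.null(fits)) fits <- psa_distributions(params, cohort, cost_cv)
  set.seed(as.integer(seed))

  dc <- de <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    ps <- params
    pr <- vapply(fits$prob, sample_psa, numeric(1))
    pr <- pr / sum(pr)
    ps$distributions[[cohort]] <- state_distribution(pr, cohort = cohort)
    ps$risk_ratios$rr <- vapply(fits$rr[ps$risk_ratios$state], sample_psa,
                                numeric(1))
    # one draw per distinct utility parameter, shared across its states
    ut_states <- ps$utilities$state
    tg <- vapply(ut_states, function(s) {
      t <- fits$utility[[s]]$target
      if (is.null(t)) paste0("utility.", s) else t
    }, character(1))
    first <- !duplicated(tg)
    draw_map <- stats::setNames(
      vapply(ut_states[first], function(s) sample_psa(fits$utility[[s]]),
             numeric(1)), tg[first])
    ps$utilities$utility <- unname(draw_map[tg])
    rows <- which(ps$costs$cohort == cohort & ps$costs$total > 0)
    ps$costs$total[rows] <- vapply(fits$cost[ps$costs$state[rows]],
                                   sample_psa, numeric(1))
    tcs_draw <- sample_psa(fits$tcs_cost)
    ps$tcs_schedule$cost <- ps$tcs_schedule$cost * tcs_draw /
      tcs_total_cost(params$tcs_schedule)
    ce <- incremental_result(run_arm(ps, "TCS", cohort),
                             run_arm(ps, "USUAL_CARE", cohort), cohort)
    dc[i] <- ce$delta_cost
    de[i] <- ce$delta_effect
  }
  structure(list(
    draws = data.frame(iteration = seq_len(n_iter), delta_cost = dc,
                       delta_qaly = de),
    n_iter = n_iter, seed = as.integer(seed), cohort = cohort
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  q4 <- mean(x$draws$delta_cost < 0 & x$draws$delta_qaly > 0)
  cat(sprintf(
    "PSA (%s): %d draws, seed %d; %.1f%% cheaper-and-more-effective\n",
    x$cohort, x$n_iter, x$seed, 100 * q4))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value the acceptance probability is the
#' fraction of PSA draws with strictly positive net monetary benefit
#' (ties count as not cost-effective).
#'
#' @param result A \code{psa_result}.
#' @param wtp_grid Strictly ascending willingness-to-pay grid, USD/QALY
#'   (default 0 to 50,000 in steps of 500).
#' @return A \code{ceac_curve}: data frame with columns \code{wtp},
#'   \code{probability}.
#' @export
ceac <- function(result, wtp_grid = seq(0, 50000, by = 500)) {
  stopifnot(inherits(result, "psa_result"))
  if (length(wtp_grid) == 0L || any(diff(wtp_grid) <= 0)) {
    stop("wtp_grid must be non-empty and strictly ascending", call. = FALSE)
  }
  if (nrow(result$draws) == 0L) stop("empty PSA result", call. = FALSE)
  prob <- vapply(wtp_grid, function(w) {
    mean(w * result$draws$delta_qaly - result$draws$delta_cost > 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac_curve", "data.frame"),
            cohort = result$cohort)
}
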