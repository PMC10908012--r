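#' Specification of a synthetic background-mortality life table
#'
#' The national complete life table the model draws background mortality
#' from is not redistributable, so the package generates a stand-in from a
#' Gompertz–Makeham hazard
#' \deqn{h(a) = \lambda + \alpha e^{\beta (a - 60)}}{h(a) = baseline + level * exp(slope*(a-60))}
#' with age-independent baseline hazard \eqn{\lambda} (per year), level
#' \eqn{\alpha} at age 60 (per year) and log-slope \eqn{\beta} (per year of
#' age). Defaults (\code{baseline = 0.001}, \code{level = 0.005},
#' \code{slope = 0.09}) give annual death probabilities of roughly 0.6\% at
#' 60, 3.7\% at 80 and 20\% at 100 — plausible for a contemporary
#' East-Asian national table. Generation is deterministic.
#'
#' @param baseline Age-independent hazard, per year, \eqn{\ge 0}.
#' @param level Senescent hazard at age 60, per year, \eqn{> 0}.
#' @param slope Exponential age slope, per year of age, \eqn{\ge 0}.
#' @param age_min First tabulated age (default 60).
#' @param terminal_age Last tabulated age; death probability is forced to 1
#'   there (default 110).
#' @return An object of class \code{life_table_spec}.
#' @export
life_table_spec <- function(baseline = 0.001, level = 0.005, slope = 0.09,
                            age_min = 60, terminal_age = 110) {
  if (baseline < 0 || level <= 0 || slope < 0) {
    stop("require baseline >= 0, level > 0, slope >= 0", call. = FALSE)
  }
  if (terminal_age <= age_min) stop("terminal_age must exceed age_min",
                                    call. = FALSE)
  structure(list(baseline = baseline, level = level, slope = slope,
                 age_min = age_min, terminal_age = terminal_age),
            class = "life_table_spec")
}

#' Generate a synthetic annual life table
#'
#' Converts the Gompertz–Makeham hazard of a \code{\link{life_table_spec}}
#' into annual death probabilities \eqn{q(a) = 1 - e^{-h(a)}}. If the hazard
#' drives \eqn{q} to 1 before the nominal terminal age the table is
#' truncated there and that age becomes terminal.
#'
#' @param spec A \code{life_table_spec}.
#' @return A \code{life_table}: list with integer \code{ages} and numeric
#'   \code{qx} (annual death probability per age), terminal probability 1.
#' @export
make_life_table <- function(spec = life_table_spec()) {
  stopifnot(inherits(spec, "life_table_spec"))
  ages <- seq(spec$age_min, spec$terminal_age)
  h <- spec$baseline + spec$level * exp(spec$slope * (ages - 60))
  qx <- 1 - exp(-h)
  hit <- which(qx >= 1)
  if (length(hit)) {
    ages <- ages[seq_len(hit[1])]
    qx <- qx[seq_len(hit[1])]
  }
  qx[length(qx)] <- 1
  life_table(ages, qx)
}

#' Construct a life table from ages and annual death probabilities
#'
#' @param ages Contiguous integer ages, strictly increasing by 1.
#' @param qx Annual death probabilities in (0, 1]; 1 at the terminal age.
#' @return An object of class \code{life_table}.
#' @export
life_table <- function(ages, qx) {
  lt <- structure(list(ages = as.integer(ages), qx = as.numeric(qx)),
                  class = "life_table")
  validate_life_table(lt)
  lt
}

#' @keywords internal
validate_life_table <- function(lt) {
  if (!inherits(lt, "life_table")) stop("not a life_table", call. = FALSE)
  if (length(lt$ages) != length(lt$qx) || length(lt$ages) < 2L) {
    stop("life_table: ages and qx must align, length >= 2", call. = FALSE)
  }
  if (any(diff(lt$ages) != 1L)) {
    stop("life_table: ages must be contiguous and increasing by 1",
         call. = FALSE)
  }
  if (any(lt$qx <= 0 | lt$qx > 1)) {
    stop("life_table: probabilities must lie in (0, 1]", call. = FALSE)
  }
  if (lt$qx[length(lt$qx)] != 1) {
    stop("life_table: terminal age must have probability 1", call. = FALSE)
  }
  old <- lt$ages >= 60
  if (is.unsorted(lt$qx[old])) {
    stop("life_table: probabilities must be non-decreasing from age 60",
         call. = FALSE)
  }
  invisible(lt)
}

#' Annual death probability at an integer age
#'
#' @param lt A \code{life_table}.
#' @param age Integer age; must lie within the table.
#' @return The annual all-cause death probability \eqn{q(age)}.
#' @export
annual_death_prob <- function(lt, age) {
  validate_life_table(lt)
  i <- match(as.integer(age), lt$ages)
  if (anyNA(i)) {
    stop("age ", paste(age[is.na(i)], collapse = ", "),
         " outside life table range [", lt$ages[1], ", ",
         lt$ages[length(lt$ages)], "]", call. = FALSE)
  }
  lt$qx[i]
}

#' @export
print.life_table <- function(x, ...) {
  cat("Life table, ages", x$ages[1], "-", x$ages[length(x$ages)],
      sprintf("; q(%d) = %.4f, q(%d) = %.4f\n", x$ages[1], x$qx[1],
              x$ages[length(x$ages)] - 10,
              x$qx[length(x$qx) - 10]))
  invisible(x)
}

#' Read/write a life table as two-column CSV
#'
#' @param lt A \code{life_table}.
#' @param path CSV file path with columns \code{age},
#'   \code{annual_death_probability}.
#' @return \code{write_life_table} returns \code{path} invisibly;
#'   \code{read_life_table} returns a \code{life_table}.
#' @export
write_life_table <- function(lt, path) {
  validate_life_table(lt)
  utils::write.csv(data.frame(age = lt$ages,
                              annual_death_probability = lt$qx),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  life_table(df$age, df$annual_death_probability)
}

# ---------------------------------------------------------------------------
# Claims-like outcome records

#' Simulate patient-level 90-day post-discharge outcome records
#'
#' Emulates the claims substrate the transition probabilities were estimated
#' from: each patient contributes one categorical 90-day outcome drawn
#' independently from the cohort's state distribution. This is outcome-level
#' emulation only — no longitudinal claims structure — because a
#' cross-sectional outcome distribution is all the cohort model consumes.
#'
#' @param dist A \code{state_distribution} over the five alive states.
#' @param n Number of patients, positive integer.
#' @param seed Integer seed; required, the only source of randomness.
#' @return Data frame with columns \code{patient_id}, \code{cohort},
#'   \code{outcome}.
#' @export
simulate_claims_cohort <- function(dist, n, seed) {
  stopifnot(inherits(dist, "state_distribution"))
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed)) {
    stop("an integer seed is required", call. = FALSE)
  }
  set.seed(as.integer(seed))
  outcomes <- sample(ALIVE_STATES, size = n, replace = TRUE,
                     prob = dist$prob)
  data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    cohort = if (is.na(dist$cohort)) NA_character_ else dist$cohort,
    outcome = outcomes,
    stringsAsFactors = FALSE
  )
}

#' Re-estimate a state distribution from outcome records
#'
#' Point estimates are state counts over the total; 95\% intervals use the
#' normal approximation \eqn{p \pm 1.96\sqrt{p(1-p)/n}} truncated to
#' \code{[0, 1]}.
#'
#' @param records Data frame as returned by
#'   \code{\link{simulate_claims_cohort}} (needs an \code{outcome} column).
#' @return A \code{state_distribution} with counts and a \code{ci} element
#'   (\code{low}, \code{high} named vectors).
#' @export
estimate_distribution <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  bad <- setdiff(unique(records$outcome), ALIVE_STATES)
  if (length(bad)) stop("unknown outcome state: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  n <- nrow(records)
  counts <- table(factor(records$outcome, levels = ALIVE_STATES))
  counts <- stats::setNames(as.numeric(counts), ALIVE_STATES)
  p <- counts / n
  se <- sqrt(p * (1 - p) / n)
  z <- stats::qnorm(0.975)
  cohort <- if ("cohort" %in% names(records)) records$cohort[1]
            else NA_character_
  d <- distribution_from_counts(counts, cohort = cohort)
  d$ci <- list(low = pmax(p - z * se, 0), high = pmin(p + z * se, 1))
  d
}
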