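#' Plot the incremental cost-effectiveness plane
#'
#' Scatter of PSA draws on the (incremental QALYs, incremental cost) plane
#' with the origin axes and, optionally, the willingness-to-pay line.
#'
#' @param result A \code{psa_result}.
#' @param wtp Optional willingness-to-pay to draw as a threshold line.
#' @param ... Further arguments to \code{plot}.
#' @return Invisibly, \code{result}.
#' @export
plot_ce_plane <- function(result, wtp = NULL, ...) {
  stopifnot(inherits(result, "psa_result"))
  d <- result$draws
  graphics::plot(d$delta_qaly, d$delta_cost, pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("steelblue", 0.4),
                 xlab = "Incremental effect (QALYs)",
                 ylab = "Incremental cost (USD)",
                 main = paste("CE plane,", result$cohort), ...)
  graphics::abline(h = 0, v = 0, col = "grey40")
  if (!is.null(wtp)) graphics::abline(0, wtp, lty = 2, col = "firebrick")
  invisible(result)
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param ... One or more \code{ceac_curve} objects.
#' @param wtp_ref Optional reference threshold to mark (vertical line).
#' @return Invisibly, \code{NULL}.
#' @export
plot_ceac <- function(..., wtp_ref = NULL) {
  curves <- list(...)
  stopifnot(length(curves) > 0L,
            all(vapply(curves, inherits, logical(1), "ceac_curve")))
  cols <- grDevices::hcl.colors(max(3L, length(curves)), "Dark 3")
  graphics::plot(curves[[1]]$wtp, curves[[1]]$probability, type = "n",
                 ylim = c(0, 1), xlab = "Willingness to pay (USD/QALY)",
                 ylab = "Probability cost-effective",
                 main = "Cost-effectiveness acceptability")
  for (i in seq_along(curves)) {
    graphics::lines(curves[[i]]$wtp, curves[[i]]$probability,
                    col = cols[i], lwd = 2)
  }
  if (!is.null(wtp_ref)) graphics::abline(v = wtp_ref, lty = 2)
  labs <- vapply(curves, function(x) {
    co <- attr(x, "cohort")
    if (is.null(co)) "curve" else co
  }, character(1))
  graphics::legend("bottomright", legend = labs,
                   col = cols[seq_along(curves)], lwd = 2, bty = "n")
  invisible(NULL)
}

#' Plot a tornado diagram
#'
#' Horizontal bars of net-monetary-benefit outcomes at each parameter's low
#' and high bound, widest swing on top.
#'
#' @param tornado A \code{tornado} data frame from \code{\link{one_way_dsa}}.
#' @param top Number of entries to show (default 10).
#' @return Invisibly, \code{tornado}.
#' @export
plot_tornado <- function(tornado, top = 10L) {
  stopifnot(inherits(tornado, "tornado"))
  t <- utils::head(tornado, top)
  t <- t[rev(seq_len(nrow(t))), ]
  base <- attr(tornado, "base_nmb")
  rng <- range(c(t$outcome_low, t$outcome_high, base))
  old <- graphics::par(mar = c(4, 12, 3, 1))
  on.exit(graphics::par(old))
  graphics::plot(NULL, xlim = rng, ylim = c(0.5, nrow(t) + 0.5),
                 yaxt = "n", xlab = "Net monetary benefit (USD)", ylab = "",
                 main = paste("Tornado,", attr(tornado, "cohort")))
  for (i in seq_len(nrow(t))) {
    graphics::rect(min(t$outcome_low[i], t$outcome_high[i]), i - 0.35,
                   max(t$outcome_low[i], t$outcome_high[i]), i + 0.35,
                   col = "steelblue", border = NA)
  }
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(t)), labels = t$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(tornado)
}
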