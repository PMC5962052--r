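# S3 methods for simulated trajectories.

#' @export
print.mt_trajectory <- function(x, ...) {
  ns <- length(x$stage_ends)
  cat(sprintf("Microtubule array trajectory: %d stage%s, %g s, dt = %g s\n",
              ns, if (ns > 1) "s" else "", max(x$time), x$dt))
  n <- length(x$time)
  cat(sprintf("  final: %d MTs (of %d sites), mean length %.2f um, free tubulin %.2f uM\n",
              x$n_mt[n], x$n_sites,
              x$mean_length[n], x$free_conc[n]))
  if (!is.na(x$tracked_site))
    cat(sprintf("  tracked site %d (%d successive MT%s)\n", x$tracked_site,
                x$tracked_n_mts, if (x$tracked_n_mts > 1) "s" else ""))
  invisible(x)
}

#' @export
as.data.frame.mt_trajectory <- function(x, ...) {
  data.frame(t_s = x$time, n_mt = x$n_mt, mean_length_um = x$mean_length,
             free_tubulin_uM = x$free_conc,
             tracked_length_um = x$tracked_length)
}

#' Summarize the steady-state window of a trajectory
#'
#' Time-averages MT count, mean length and free tubulin over the last
#' `window_frac` of the run (default the final 20 percent).
#'
#' @param object an `mt_trajectory`.
#' @param window_frac fraction of the run to average over (from the end).
#' @param ... ignored.
#' @return an `mt_steady_state` object (see [steady_state_summary()]).
#' @export
summary.mt_trajectory <- function(object, window_frac = 0.2, ...) {
  tmax <- max(object$time)
  steady_state_summary(object, window = c((1 - window_frac) * tmax, tmax))
}

#' Plot a simulated trajectory
#'
#' Four panels: tracked single-MT life history, mean MT length, MT count,
#' and free tubulin concentration over time. Stage boundaries are marked
#' with dashed vertical lines.
#'
#' @param x an `mt_trajectory`.
#' @param ... passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.mt_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 0.5))
  on.exit(graphics::par(op))
  panels <- list(
    list(y = x$tracked_length, ylab = "tracked MT length (um)"),
    list(y = x$mean_length, ylab = "mean MT length (um)"),
    list(y = x$n_mt, ylab = "MT count"),
    list(y = x$free_conc, ylab = "free tubulin (uM)"))
  for (p in panels) {
    graphics::plot(x$time, p$y, type = "l", xlab = "time (s)",
                   ylab = p$ylab, ...)
    if (length(x$stage_ends) > 1)
      graphics::abline(v = head(x$stage_ends, -1), lty = 2,
                       col = "grey50")
  }
  invisible(x)
}
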