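# Steady-state summaries, decay half-times, plateau diagnostics, length
# distributions, and the closed-form constant-tubulin oracle.

#' Steady-state summary over a time window
#'
#' Time-averages MT count, mean length and free tubulin within `window`
#' for each replicate trajectory, then reports mean and sd across
#' replicates.
#'
#' @param trajectories an `mt_trajectory` or a list of replicate
#'   trajectories.
#' @param window numeric length-2, `c(t_start, t_end)` in seconds; must lie
#'   within the simulated span.
#' @return an object of class `mt_steady_state`: a data frame of
#'   quantity/mean/sd rows with attributes `window` and `n_replicates`.
#' @examples
#' trajs <- lapply(1:2, function(s)
#'   simulate_mt_array(stage_spec(2000, di_preset("setB")), seed = s))
#' steady_state_summary(trajs, window = c(1500, 2000))
#' @export
steady_state_summary <- function(trajectories, window) {
  if (inherits(trajectories, "mt_trajectory"))
    trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1,
            all(vapply(trajectories, inherits, logical(1), "mt_trajectory")),
            length(window) == 2, window[1] < window[2])
  per_rep <- vapply(trajectories, function(tr) {
    if (window[1] < min(tr$time) || window[2] > max(tr$time))
      stop("'window' outside the simulated span")
    sel <- tr$time >= window[1] & tr$time <= window[2]
    if (!any(sel)) stop("empty window")
    c(n_mt = mean(tr$n_mt[sel]),
      mean_length = mean(tr$mean_length[sel], na.rm = TRUE),
      free_conc = mean(tr$free_conc[sel]))
  }, numeric(3))
  out <- data.frame(
    quantity = c("n_mt", "mean_length_um", "free_tubulin_uM"),
    mean = apply(per_rep, 1, mean),
    sd = if (ncol(per_rep) > 1) apply(per_rep, 1, sd) else rep(0, 3),
    row.names = NULL)
  structure(out, class = c("mt_steady_state", "data.frame"),
            window = window, n_replicates = length(trajectories))
}

#' @export
print.mt_steady_state <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("Steady-state summary over [%g, %g] s (%d replicate%s):\n",
              w[1], w[2], attr(x, "n_replicates"),
              if (attr(x, "n_replicates") > 1) "s" else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' Has a stochastic series reached its plateau?
#'
#' Compares the mean and the standard deviation of the last two
#' non-overlapping windows of the series; the plateau is declared when both
#' change by less than `rel_tol` (relative). The sd criterion matters: for
#' assembling polymer systems the fluctuation amplitude relaxes more slowly
#' than the mean, so a flat mean alone can be premature.
#'
#' @param series numeric vector (one sample per step).
#' @param window window width in samples; the series must be longer than
#'   `2 * window`.
#' @param rel_tol relative tolerance (default 0.05).
#' @return `TRUE` or `FALSE`.
#' @export
plateau_reached <- function(series, window, rel_tol = 0.05) {
  stopifnot(window >= 2, rel_tol > 0)
  n <- length(series)
  if (n <= 2 * window) stop("series must be longer than 2 * window")
  w2 <- series[(n - window + 1):n]
  w1 <- series[(n - 2 * window + 1):(n - window)]
  eps <- .Machine$double.eps
  mean_ok <- abs(mean(w2) - mean(w1)) <= rel_tol * max(abs(mean(w1)), eps)
  sd_ok <- abs(sd(w2) - sd(w1)) <= rel_tol * max(sd(w1), eps)
  mean_ok && sd_ok
}

#' Midpoint-crossing half-time of a decaying (or rising) series
#'
#' The half-time is the first time the series crosses the midpoint between
#' its pre-transition baseline (`series[1]`) and its post-transition
#' asymptote (mean of the last 10 percent of samples), with linear
#' interpolation between samples.
#'
#' @param series numeric vector; `series[1]` is the baseline.
#' @param t times, same length as `series`.
#' @return half-time in the units of `t`, or `NA_real_` if the midpoint is
#'   never crossed (including constant series).
#' @export
half_time <- function(series, t = seq_along(series) - 1) {
  stopifnot(length(series) == length(t), length(series) >= 2)
  keep <- !is.na(series)
  series <- series[keep]
  t <- t[keep]
  if (length(series) < 2) return(NA_real_)
  baseline <- series[1]
  final <- mean(tail(series, max(1L, ceiling(0.1 * length(series)))))
  mid <- (baseline + final) / 2
  if (baseline == final) return(NA_real_)
  dir <- sign(final - baseline)
  crossed <- if (dir < 0) series <= mid else series >= mid
  i <- which(crossed)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t[1])
  # linear interpolation between the bracketing samples
  t[i - 1] + (mid - series[i - 1]) / (series[i] - series[i - 1]) *
    (t[i] - t[i - 1])
}

#' Histogram of microtubule lengths
#'
#' Right-closed bins over `[0, max_radius]`; a length exactly at
#' `max_radius` falls in the last bin. Counts sum to the number of MTs.
#'
#' @param lengths MT lengths, um; must lie in `[0, max_radius]`.
#' @param bin_width bin width, um (default 1).
#' @param max_radius upper edge, um (typically the cell radius).
#' @return named integer vector of per-bin counts.
#' @export
length_histogram <- function(lengths, bin_width = 1, max_radius = 25) {
  stopifnot(bin_width > 0, max_radius > 0)
  if (length(lengths) &&
      (any(lengths < 0) || any(lengths > max_radius)))
    stop("lengths outside [0, max_radius]")
  breaks <- seq(0, max_radius, by = bin_width)
  if (tail(breaks, 1) < max_radius) breaks <- c(breaks, max_radius)
  counts <- integer(length(breaks) - 1)
  if (length(lengths)) {
    idx <- findInterval(lengths, breaks, left.open = TRUE,
                        rightmost.closed = FALSE)
    idx[idx == 0L] <- 1L  # lengths of exactly 0 go in the first bin
    tab <- tabulate(idx, nbins = length(counts))
    counts <- tab
  }
  names(counts) <- sprintf("(%g,%g]", head(breaks, -1), breaks[-1])
  counts
}

#' Five-bin radial fraction histogram
#'
#' Bins `length / radius` into the five equal fractions `[0, 0.2)`,
#' `[0.2, 0.4)`, ..., `[0.8, 1.0]` and returns the fraction of MTs per bin
#' (summing to 1). This is the convention used for comparing simulated tip
#' positions against tip positions measured in cells of different radii.
#'
#' @param lengths MT lengths, um; must lie in `[0, radius]`.
#' @param radius cell radius, um.
#' @return numeric vector of 5 fractions.
#' @export
radial_fraction_histogram <- function(lengths, radius) {
  stopifnot(radius > 0)
  if (!length(lengths)) stop("no lengths supplied")
  if (any(lengths < 0) || any(lengths > radius))
    stop("lengths outside [0, radius]")
  frac <- lengths / radius
  idx <- pmin(floor(frac / 0.2) + 1L, 5L)
  out <- tabulate(idx, nbins = 5L) / length(lengths)
  names(out) <- c("[0,0.2)", "[0.2,0.4)", "[0.4,0.6)", "[0.6,0.8)",
                  "[0.8,1]")
  out
}

#' Mean length in the bounded constant-tubulin regime
#'
#' For a filament with constant growth/shortening velocities and
#' catastrophe/rescue frequencies, unconfined, at fixed free tubulin, the
#' steady-state length distribution is exponential with mean
#' `v_g * v_s / (v_s * k_c - v_g * k_r)` provided the drift is toward
#' shortening (`v_s * k_c > v_g * k_r`, the bounded regime). Used as a
#' closed-form oracle to validate the stochastic engine in that limit.
#'
#' @param v_g,v_s growth and shortening velocities, um/s.
#' @param k_c,k_r catastrophe and rescue frequencies, s^-1.
#' @return mean length, um, or `NA_real_` in the unbounded regime (net
#'   growth; no stationary length distribution exists).
#' @examples
#' dogterom_leibler_mean(0.1169, 0.205, 0.075, 0.023)  # ~1.89 um
#' @export
dogterom_leibler_mean <- function(v_g, v_s, k_c, k_r) {
  stopifnot(v_g >= 0, v_s >= 0, k_c >= 0, k_r >= 0)
  denom <- v_s * k_c - v_g * k_r
  if (denom <= 0) return(NA_real_)
  v_g * v_s / denom
}

#' Read microtubule tip lengths from a plain-text file
#'
#' One length (um) per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return numeric vector of lengths.
#' @export
read_tip_lengths <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("tip lengths must be finite and non-negative")
  x
}
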