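#' Per-pair transition times from smoothed derivatives
#'
#' The transition time of an element pair is the frame where its smoothed
#' derivative of Q is largest (earliest frame on ties), expressed as a
#' fraction of the trajectory, `(frame - 1) / (n_frames - 1)`. Pairs whose Q
#' range over the whole trajectory is below `activity_threshold` carry no
#' folding signal (e.g. pairs formed throughout) and are flagged as excluded.
#'
#' @param qs An `fq_qseries` with derivative columns (see
#'   [add_derivatives()]).
#' @param activity_threshold Minimum `max(q) - min(q)` for inclusion.
#' @return A tibble of class `fq_transitions` with columns `elem_i`,
#'   `elem_j`, `t_star`, `q_range`, `included`.
#' @export
transition_times <- function(qs, activity_threshold = 0.2) {
  stopifnot(inherits(qs, "fq_qseries"))
  if (!"dq_smooth" %in% names(qs)) {
    abort("Q series lacks smoothed derivatives; call add_derivatives() first.",
          class = "foldq_error")
  }
  nf <- attr(qs, "n_frames")
  out <- qs |>
    group_by(.data$elem_i, .data$elem_j) |>
    summarise(t_star = (which.max(.data$dq_smooth) - 1) / (nf - 1),
              q_range = max(.data$q) - min(.data$q),
              .groups = "drop") |>
    mutate(included = .data$q_range >= activity_threshold)
  if (!any(out$included)) {
    abort("No folding signal: every pair excluded by the activity filter.",
          class = "foldq_error")
  }
  attr(out, "n_frames") <- nf
  class(out) <- c("fq_transitions", class(out))
  out
}

# Local maxima of a density trace with a scipy-style prominence filter.
# Endpoints may host peaks. Prominence of a peak is its height minus the
# higher of the two minima separating it from higher terrain (or the signal
# edge) on either side.
find_peaks <- function(dens, min_prominence_rel) {
  n <- length(dens)
  left <- c(-Inf, dens[-n])
  right <- c(dens[-1], -Inf)
  cand <- which(dens > left & dens >= right)
  if (length(cand) == 0) cand <- which.max(dens)
  prom <- vapply(cand, function(i) {
    lmin <- dens[i]
    j <- i
    while (j > 1 && dens[j - 1] <= dens[i]) {
      j <- j - 1
      lmin <- min(lmin, dens[j])
    }
    # no higher terrain before the grid edge: the density keeps decaying
    # outside the domain, so the base on that side is zero
    if (j == 1 && dens[1] <= dens[i]) lmin <- 0
    rmin <- dens[i]
    j <- i
    while (j < n && dens[j + 1] <= dens[i]) {
      j <- j + 1
      rmin <- min(rmin, dens[j])
    }
    if (j == n && dens[n] <= dens[i]) rmin <- 0
    dens[i] - max(lmin, rmin)
  }, numeric(1))
  # the global maximum always counts as a peak
  prom[which.max(dens[cand])] <- dens[which.max(dens)]
  keep <- prom >= min_prominence_rel * max(dens)
  cand[keep]
}

#' Cluster transition times by kernel density estimation
#'
#' Fits a Gaussian KDE to the included transition times with bandwidth from
#' Scott's rule, `h = sd(t) * m^(-1/5)` (floored at one grid spacing so a
#' degenerate sample still yields a density). Peaks are local maxima of the
#' density on a uniform grid over \[0, 1\] with relative prominence at least
#' `min_prominence`; pairs are assigned to peaks by the density minima
#' between consecutive peaks. A single peak means two-state kinetics; two or
#' more peaks mean multistate, and each inter-peak boundary defines a binary
#' intermediate contact vector (pairs already folded at that boundary).
#'
#' @param times An `fq_transitions` table.
#' @param grid_points Number of grid points on \[0, 1\].
#' @param min_prominence Relative prominence threshold for peak calling.
#' @param onset_method `"min_t"` (earliest included transition) or
#'   `"first_peak"` (first mode minus one bandwidth, floored at 0).
#' @return An object of class `fq_kinetics_call`; see [tidy.fq_kinetics_call()]
#'   and [glance.fq_kinetics_call()].
#' @export
kde_phases <- function(times, grid_points = 512L, min_prominence = 0.15,
                       onset_method = c("min_t", "first_peak")) {
  stopifnot(inherits(times, "fq_transitions"))
  onset_method <- match.arg(onset_method)
  incl <- times[times$included, , drop = FALSE]
  if (nrow(incl) == 0) {
    abort("No included transition times.", class = "foldq_error")
  }
  t_star <- incl$t_star
  m <- length(t_star)
  sigma <- if (m > 1) sd(t_star) else 0
  h <- max(sigma * m^(-1 / 5), 1 / grid_points)
  grid <- seq(0, 1, length.out = grid_points)
  dens <- rowMeans(outer(grid, t_star, function(g, t) dnorm(g, t, h)))
  peak_idx <- find_peaks(dens, min_prominence)
  peaks <- grid[peak_idx]
  k <- length(peaks)
  boundaries <- numeric(0)
  if (k > 1) {
    boundaries <- vapply(seq_len(k - 1), function(b) {
      seg <- seq(peak_idx[b], peak_idx[b + 1])
      grid[seg[which.min(dens[seg])]]
    }, numeric(1))
  }
  assignment <- findInterval(t_star, boundaries) + 1L
  label <- if (k == 1) "two_state" else "multistate"
  pair_names <- paste(times$elem_i, times$elem_j, sep = "|")
  intermediate_vectors <- lapply(seq_len(max(k - 1, 0)), function(b) {
    formed <- rep(0L, nrow(times))
    formed[which(times$included)[assignment <= b]] <- 1L
    setNames(formed, pair_names)
  })
  onset <- if (onset_method == "min_t") min(t_star) else max(peaks[1] - h, 0)
  structure(list(
    peaks = peaks,
    peak_heights = dens[peak_idx],
    boundaries = boundaries,
    assignment = mutate(incl, peak = assignment),
    label = label,
    onset = onset,
    intermediate_vectors = intermediate_vectors,
    bandwidth = h,
    n_included = m,
    excluded_pairs = pair_names[!times$included],
    density = tibble(t = grid, density = dens)
  ), class = "fq_kinetics_call")
}

#' @export
print.fq_kinetics_call <- function(x, ...) {
  cat(sprintf("<fq_kinetics_call> %s: %d peak(s) at %s; onset %.3f; h = %.4f\n",
              x$label, length(x$peaks),
              paste(sprintf("%.3f", x$peaks), collapse = ", "),
              x$onset, x$bandwidth))
  invisible(x)
}

#' Fraction of two-state trajectories
#'
#' The probability that a protein exhibits two-state kinetics, estimated as
#' the share of its decoy trajectories called two-state.
#'
#' @param calls A list of `fq_kinetics_call` objects, or a data frame with a
#'   `label` column.
#' @return A number in \[0, 1\].
#' @export
fraction_two_state <- function(calls) {
  labels <- if (is.data.frame(calls)) {
    calls$label
  } else {
    vapply(calls, function(c) c$label, "")
  }
  if (length(labels) == 0) abort("No kinetics calls given.", class = "foldq_error")
  mean(labels == "two_state")
}

#' Run the full per-trajectory kinetics analysis
#'
#' Convenience wrapper: Q time series, finite-difference derivative,
#' supersmoothing, transition times and KDE phase clustering in one call.
#'
#' @param traj An `fq_trajectory`.
#' @param contacts An `fq_contacts` table for the same protein.
#' @param config An [fq_config()].
#' @return An `fq_kinetics_call`.
#' @export
analyze_trajectory <- function(traj, contacts, config = fq_config()) {
  qs <- q_timeseries(traj, contacts, xi = config$xi)
  qs <- add_derivatives(qs, bass = config$bass)
  tt <- transition_times(qs, activity_threshold = config$activity_threshold)
  kde_phases(tt, grid_points = config$grid_points,
             min_prominence = config$min_prominence,
             onset_method = config$onset_method)
}
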