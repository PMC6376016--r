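#' Area under the curve of one species
#'
#' Trapezoidal integral of a species trajectory over the full time grid,
#' the model's yield measure for gene expression (e.g. PhoA AUC).
#'
#' @param tc A `pho_timecourse`.
#' @param species Species name.
#' @return AUC in uM*s (concentration domain) or molecules*s (count
#'   domain).
#' @export
auc <- function(tc, species) {
  y <- tc_values(tc, species)
  t <- tc$times
  n <- length(t)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

#' Quasi-steady-state level of one species
#'
#' Mean over the final fraction of the time grid, the operational
#' steady-state readout used by the promoter-design scans. The relative
#' drift within the window, `(max - min) / |mean|`, is attached; drift
#' above 5% triggers a warning and marks the value as not at steady
#' state.
#'
#' @param tc A `pho_timecourse`.
#' @param species Species name.
#' @param window_fraction Final fraction of the grid to average over
#'   (default 0.1).
#' @return The window mean, with attributes `drift` (relative) and
#'   `stationary` (logical).
#' @export
steady_state_value <- function(tc, species, window_fraction = 0.1) {
  stopifnot(window_fraction > 0, window_fraction <= 1)
  y <- tc_values(tc, species)
  n <- length(y)
  i0 <- max(1L, n - ceiling(window_fraction * n) + 1L)
  w <- y[i0:n]
  m <- mean(w)
  drift <- if (m == 0) 0 else (max(w) - min(w)) / abs(m)
  stationary <- drift <= 0.05
  if (!stationary) {
    warning(species, " not at steady state: relative drift ",
            signif(drift, 3), " in final window")
  }
  structure(m, drift = drift, stationary = stationary)
}

#' Time of the trajectory peak
#'
#' Time at which the species attains its global maximum on the output
#' grid; ties are broken by the earliest time (a constant trajectory
#' peaks at 0).
#'
#' @param tc A `pho_timecourse`.
#' @param species Species name.
#' @return Time in seconds.
#' @export
time_to_peak <- function(tc, species) {
  y <- tc_values(tc, species)
  tc$times[which.max(y)]
}

#' Steady-state noise ratio of one species over an ensemble
#'
#' Pools the grid samples of a species across a window of every
#' trajectory in an ensemble and computes the ratio of the standard
#' deviation over the mean (coefficient of variation), the measure used
#' to compare promoter unbinding regimes. By default the window is the
#' final 25% of the simulated span.
#'
#' @param trajectories A single `pho_timecourse` or a list of them
#'   (e.g. from [run_ensemble()]).
#' @param species Species name.
#' @param window Numeric `c(t_start, t_end)` in seconds; `NULL` for the
#'   final 25% of the span.
#' @return List of class `pho_noise`: `species`, `mean`, `sd`, `ratio`
#'   (sd/mean; `NA` and `defined = FALSE` when the mean is zero),
#'   `window`, `n_samples`.
#' @export
noise_ratio <- function(trajectories, species, window = NULL) {
  if (inherits(trajectories, "pho_timecourse")) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1)
  tmax <- max(trajectories[[1]]$times)
  if (is.null(window)) window <- c(0.75 * tmax, tmax)
  stopifnot(length(window) == 2, window[1] < window[2],
            window[1] >= 0, window[2] <= tmax)
  samples <- unlist(lapply(trajectories, function(tc) {
    keep <- tc$times >= window[1] & tc$times <= window[2]
    tc_values(tc, species)[keep]
  }))
  m <- mean(samples)
  s <- stats::sd(samples)
  defined <- m != 0
  structure(list(species = species, mean = m, sd = s,
                 ratio = if (defined) s / m else NA_real_,
                 defined = defined, window = window,
                 n_samples = length(samples)),
            class = "pho_noise")
}

#' @export
print.pho_noise <- function(x, ...) {
  cat("<pho_noise> ", x$species, ": mean ", signif(x$mean, 4), ", sd ",
      signif(x$sd, 4), ", sd/mean ", signif(x$ratio, 4), " (",
      x$n_samples, " samples in [", x$window[1], ", ", x$window[2],
      "] s)\n", sep = "")
  invisible(x)
}
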