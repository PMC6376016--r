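#' Observed reporter dataset
#'
#' Container for (relative) PhoA and optional PhoB expression time
#' courses, e.g. promoter-fusion fluorescence readouts on an arbitrary
#' linear scale. When `phoB` is absent, fitting uses PhoA alone — the
#' first step of the two-step calibration.
#'
#' @param times Sampling times in seconds, strictly increasing, within
#'   `[0, 16200]`.
#' @param phoA Non-negative PhoA signal.
#' @param phoB Optional non-negative PhoB signal.
#' @param normalisation `"raw"` or `"max-normalised"` bookkeeping tag.
#' @return A `pho_dataset` data frame with columns `time_s`, `phoA`
#'   and optionally `phoB`.
#' @export
observed_dataset <- function(times, phoA, phoB = NULL,
                             normalisation = c("raw", "max-normalised")) {
  normalisation <- match.arg(normalisation)
  stopifnot(length(times) == length(phoA),
            !is.unsorted(times, strictly = TRUE),
            all(times >= 0), all(times <= 16200),
            all(phoA >= 0))
  df <- data.frame(time_s = times, phoA = phoA)
  if (!is.null(phoB)) {
    stopifnot(length(phoB) == length(times), all(phoB >= 0))
    df$phoB <- phoB
  }
  structure(df, normalisation = normalisation,
            class = c("pho_dataset", "data.frame"))
}

has_phoB <- function(dataset) "phoB" %in% names(dataset)

#' Default free-parameter tie groups for calibration
#'
#' The rates fitted by default are those without a fixed literature
#' point value: the autophosphorylation pair r1/r2 and its reverse
#' r1r/r2r, the complex dissociation rates r3r/r5r/r7r/r8r, the
#' phosphotransfer pair r4/r6, the phosphatase rate r9, and the
#' expression/degradation rates r12-r19. Symbols within a group share
#' one optimisation variable (their fitted control values coincide);
#' binding rates r3/r5/r7/r8 and r10/r11, unbinding r10r/r11r and mRNA
#' decay r20/r21 stay fixed.
#'
#' @return List of character vectors (tie groups).
#' @export
default_free_groups <- function() {
  list(c("r1", "r2"), c("r1r", "r2r"), c("r3r", "r5r", "r7r", "r8r"),
       c("r4", "r6"), "r9",
       "r12", "r13", "r14", "r15", "r16", "r17", "r18", "r19")
}

#' Calibration specification
#'
#' @param free Free parameters: a list of tie groups (character
#'   vectors sharing one optimisation variable) or a plain character
#'   vector (each symbol its own group). Default:
#'   [default_free_groups()].
#' @param n_starts Number of multi-start points (log-uniform within
#'   bounds).
#' @param seed Integer seed for start sampling.
#' @param scale_mode `"fixed"` (signals are on the model scale, times
#'   `scale_factors`) or `"fit"` (a linear scale factor per observable
#'   is profiled analytically at every residual evaluation — for
#'   relative fluorescence with unknown gain).
#' @param scale_factors Named fixed scale factors (used when
#'   `scale_mode = "fixed"`).
#' @param rtol,atol ODE tolerances used during fitting. Tight defaults
#'   on purpose: weakly identified parameter combinations (e.g. the
#'   split of a transcription/translation rate product) produce
#'   residual signals of order `1e-4` and below, which solver noise at
#'   looser tolerances would drown.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param epsfcn Relative step for the optimiser's forward-difference
#'   Jacobian (the step is `sqrt(epsfcn) * |par|` on the log10 scale).
#'   The default takes steps of about `1e-3` log10 units — large
#'   enough that derivatives along weakly identified directions rise
#'   above solver noise, small enough to stay locally accurate.
#' @return List of class `pho_fitspec`.
#' @export
fit_spec <- function(free = default_free_groups(), n_starts = 20, seed = 1,
                     scale_mode = c("fixed", "fit"),
                     scale_factors = c(phoA = 1, phoB = 1),
                     rtol = 1e-9, atol = 1e-12, maxiter = 100,
                     epsfcn = 1e-6) {
  scale_mode <- match.arg(scale_mode)
  if (is.character(free)) free <- as.list(free)
  stopifnot(n_starts >= 1, length(free) >= 1)
  structure(list(free = free, n_starts = n_starts, seed = seed,
                 scale_mode = scale_mode, scale_factors = scale_factors,
                 rtol = rtol, atol = atol, maxiter = maxiter,
                 epsfcn = epsfcn),
            class = "pho_fitspec")
}

# Bounds per tie group, on the optimisation (log10) scale. Ranged rates
# use their literature range; upper-limit-only rates use
# [value/100, upper]; unconstrained rates get the default span
# [value/100, value*100].
group_bounds <- function(groups, rates) {
  t(vapply(groups, function(g) {
    i <- match(g, rates$symbol)
    if (anyNA(i)) stop("unknown rate symbol(s): ",
                       paste(g[is.na(i)], collapse = ", "))
    v <- rates$value[i][1]
    lo <- rates$lo[i][1]; hi <- rates$hi[i][1]
    if (is.na(hi)) hi <- v * 100
    if (is.na(lo)) lo <- v / 100
    c(lo = lo, hi = hi)
  }, c(lo = 0, hi = 0)))
}

expand_groups <- function(groups, theta) {
  stats::setNames(
    unlist(lapply(seq_along(groups), function(i) {
      rep(theta[i], length(groups[[i]]))
    })),
    unlist(groups)
  )
}

# Integrate the ODEs and return the model observables at the requested
# times (uM, unscaled).
ode_observables <- function(network, rates, init, times, rtol, atol) {
  tt <- sort(unique(c(0, times)))
  p <- mass_action_parms(network, rates)
  out <- deSolve::ode(y = unname(init[network$species]), times = tt,
                      func = rhs_fn, parms = p, method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 50000)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    stop("ODE integration failed at t = ", max(out[, 1]), " s")
  }
  vals <- out[match(times, tt), -1, drop = FALSE]
  colnames(vals) <- network$species
  vals
}

#' Model-predicted reporter signals
#'
#' PhoA and PhoB concentrations at the requested times, each multiplied
#' by its linear scale factor (the model's stand-in for the arbitrary
#' fluorescence gain).
#'
#' @param rates A `pho_rates` table.
#' @param init Named initial state (uM).
#' @param times Times in seconds.
#' @param scale_factors Named vector with elements `phoA`, `phoB`.
#' @param network A `pho_network`.
#' @param rtol,atol ODE tolerances.
#' @return Data frame with `time_s`, `phoA`, `phoB`.
#' @export
predict_observables <- function(rates, init = default_initial_state(),
                                times = seq(0, 16200, by = 600),
                                scale_factors = c(phoA = 1, phoB = 1),
                                network = pho_network(),
                                rtol = 1e-8, atol = 1e-12) {
  if (!"PhoA" %in% network$species) {
    stop("network lacks the PhoA reporter species")
  }
  vals <- ode_observables(network, rates, init, times, rtol, atol)
  out <- data.frame(time_s = times,
                    phoA = vals[, "PhoA"] * scale_factors[["phoA"]])
  if ("PhoB" %in% network$species) {
    out$phoB <- vals[, "PhoB"] * scale_factors[["phoB"]]
  }
  out
}

# Residuals for one parameter vector (log10 group values). Each
# observable contributes (scale * model - observed) / max(observed);
# the max-normalisation puts PhoA and PhoB on comparable scales and
# makes the fit exactly invariant to rescaling an observable when the
# scale factor is profiled.
calibration_residuals <- function(theta_log10, dataset, fitspec, rates, init,
                                  network) {
  vals <- set_rates(rates, 10^expand_groups(fitspec$free, theta_log10))
  obs_species <- c(phoA = "PhoA", phoB = "PhoB")
  use <- c("phoA", if (has_phoB(dataset)) "phoB")
  model <- ode_observables(network, vals, init, dataset$time_s,
                           fitspec$rtol, fitspec$atol)
  unlist(lapply(use, function(o) {
    y <- dataset[[o]]
    m <- model[, obs_species[[o]]]
    s <- if (fitspec$scale_mode == "fit") {
      if (sum(m^2) > 0) sum(m * y) / sum(m^2) else 1
    } else {
      fitspec$scale_factors[[o]]
    }
    (s * m - y) / max(max(y), .Machine$double.eps)
  }), use.names = FALSE)
}

profiled_scales <- function(theta_log10, dataset, fitspec, rates, init,
                            network) {
  vals <- set_rates(rates, 10^expand_groups(fitspec$free, theta_log10))
  model <- ode_observables(network, vals, init, dataset$time_s,
                           fitspec$rtol, fitspec$atol)
  obs_species <- c(phoA = "PhoA", phoB = "PhoB")
  use <- c("phoA", if (has_phoB(dataset)) "phoB")
  vapply(use, function(o) {
    if (fitspec$scale_mode != "fit") return(fitspec$scale_factors[[o]])
    m <- model[, obs_species[[o]]]
    if (sum(m^2) > 0) sum(m * dataset[[o]]) / sum(m^2) else 1
  }, 0)
}

#' Bounded multi-start least-squares calibration
#'
#' Estimates the free rate constants by trust-region
#' Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()]) in
#' log10-parameter space — the rates span eight decades — under box
#' constraints from the physiological literature ranges. Starts are
#' sampled log-uniformly within the bounds (seeded), and the best
#' converged start is returned. PhoB residuals are included only when
#' the dataset carries a `phoB` column.
#'
#' @param dataset A [observed_dataset()].
#' @param fitspec A [fit_spec()].
#' @param rates Baseline rates; fixed symbols keep these values.
#' @param init Named initial state (uM).
#' @param network A `pho_network`.
#' @param start Optional named start vector (natural scale) for the
#'   group representatives; when given it replaces the sampled starts
#'   (used by [two_step_fit()] to warm-start step two).
#' @return A `pho_fit`: `best_rates`, `best_par` (natural scale, one
#'   entry per group representative), `residual_norm` (root of the sum
#'   of squared residuals), `scale_factors`, `starts` (per-start
#'   record: start, converged values, residual norm, convergence
#'   flag), `fitspec`.
#' @export
fit_rates <- function(dataset, fitspec = fit_spec(), rates = default_rates(),
                      init = default_initial_state(),
                      network = pho_network(), start = NULL) {
  stopifnot(inherits(dataset, "pho_dataset"), inherits(fitspec, "pho_fitspec"))
  groups <- fitspec$free
  gnames <- vapply(groups, `[[`, "", 1)
  b <- group_bounds(groups, rates)
  llo <- log10(b[, "lo"]); lhi <- log10(b[, "hi"])
  if (is.null(start)) {
    set.seed(fitspec$seed)
    starts <- matrix(stats::runif(fitspec$n_starts * length(groups)),
                     nrow = fitspec$n_starts)
    starts <- sweep(sweep(starts, 2, lhi - llo, `*`), 2, llo, `+`)
  } else {
    starts <- matrix(pmin(pmax(log10(start[gnames]), llo), lhi), nrow = 1)
  }
  nres <- nrow(dataset) * (1 + has_phoB(dataset))
  fn <- function(theta) {
    tryCatch(
      calibration_residuals(theta, dataset, fitspec, rates, init, network),
      error = function(e) rep(1e6, nres)
    )
  }
  records <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = llo, upper = lhi, fn = fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = fitspec$maxiter, ftol = 1e-13,
                           ptol = 1e-11, gtol = 0,
                           epsfcn = fitspec$epsfcn %||% 1e-6)),
      error = function(e) NULL
    )
    records[[i]] <- if (is.null(res)) {
      list(start = starts[i, ], par = rep(NA_real_, length(groups)),
           rss = Inf, converged = FALSE)
    } else {
      list(start = starts[i, ], par = res$par, rss = res$deviance,
           converged = res$info %in% 1:4)
    }
  }
  rss <- vapply(records, `[[`, 0, "rss")
  if (all(!is.finite(rss))) {
    stop("all ", nrow(starts), " starts failed; last error in ODE integration",
         " or optimiser — inspect bounds and dataset")
  }
  best <- which.min(rss)
  theta <- records[[best]]$par
  best_values <- 10^expand_groups(groups, theta)
  structure(
    list(best_rates = set_rates(rates, best_values),
         best_par = stats::setNames(10^theta, gnames),
         residual_norm = sqrt(rss[best]),
         scale_factors = profiled_scales(theta, dataset, fitspec, rates,
                                         init, network),
         starts = data.frame(
           start_index = seq_along(records),
           rss = rss,
           converged = vapply(records, `[[`, TRUE, "converged")),
         start_pars = t(vapply(records, function(r) 10^r$par,
                               numeric(length(groups)))),
         fitspec = fitspec),
    class = "pho_fit"
  )
}

#' @export
print.pho_fit <- function(x, ...) {
  cat("<pho_fit> residual norm ", signif(x$residual_norm, 5), "; ",
      sum(x$starts$converged), "/", nrow(x$starts),
      " starts converged\n", sep = "")
  print(signif(x$best_par, 5))
  invisible(x)
}

#' Two-step calibration: PhoA alone, then PhoA and PhoB
#'
#' Step one fits the free parameters to the PhoA time course only;
#' step two restarts the optimiser from step one's optimum with the
#' PhoB observations included, quantifying what the PhoB/PhoR
#' expression feedback adds to the response. The difference in the
#' fitted models' PhoA time-to-peak is reported as the response-speed
#' shift attributable to the feedback.
#'
#' @inheritParams fit_rates
#' @return List of class `pho_two_step`: `step1`, `step2` (both
#'   `pho_fit`), and `time_to_peak_shift_s` (step2 minus step1, on the
#'   full output grid).
#' @export
two_step_fit <- function(dataset, fitspec = fit_spec(),
                         rates = default_rates(),
                         init = default_initial_state(),
                         network = pho_network()) {
  if (!has_phoB(dataset)) {
    stop("two_step_fit requires both phoA and phoB observations")
  }
  step1_data <- observed_dataset(dataset$time_s, dataset$phoA,
                                 normalisation = attr(dataset, "normalisation"))
  step1 <- fit_rates(step1_data, fitspec, rates, init, network)
  step2 <- fit_rates(dataset, fitspec, rates, init, network,
                     start = step1$best_par)
  cfg <- sim_config()
  ttp <- vapply(list(step1, step2), function(f) {
    time_to_peak(simulate_ode(network, f$best_rates, init, cfg), "PhoA")
  }, 0)
  structure(list(step1 = step1, step2 = step2,
                 time_to_peak_shift_s = ttp[2] - ttp[1]),
            class = "pho_two_step")
}

#' @export
print.pho_two_step <- function(x, ...) {
  cat("<pho_two_step>\n step 1 (PhoA only):      residual norm ",
      signif(x$step1$residual_norm, 5), "\n step 2 (PhoA + PhoB):    residual norm ",
      signif(x$step2$residual_norm, 5), "\n PhoA time-to-peak shift: ",
      x$time_to_peak_shift_s, " s\n", sep = "")
  invisible(x)
}
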