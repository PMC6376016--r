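#' Ground-truth specification for synthetic reporter data
#'
#' Defines the generating model for synthetic PhoA/PhoB expression time
#' courses: rates, initial state, plate-reader-like sampling cadence
#' (default every 600 s over the 4.5 h starvation window, 28 samples),
#' a relative measurement-noise level, and per-observable linear scale
#' factors mimicking the arbitrary fluorescence gain. The noise model
#' is multiplicative Gaussian — fluorescence error scales with signal.
#'
#' @param rates Generating `pho_rates` (default: control model).
#' @param init Generating initial state (uM).
#' @param seed Integer seed.
#' @param noise_sigma Relative noise standard deviation (default 0.05).
#' @param sampling_interval Seconds between samples (default 600).
#' @param t_end End of the sampling window (default 16200 s).
#' @param scale_factors Named vector `c(phoA=, phoB=)`.
#' @param network Generating network (default: full control network).
#' @return List of class `pho_truth`.
#' @export
ground_truth <- function(rates = default_rates(),
                         init = default_initial_state(), seed = 1,
                         noise_sigma = 0.05, sampling_interval = 600,
                         t_end = 16200,
                         scale_factors = c(phoA = 1, phoB = 1),
                         network = pho_network()) {
  stopifnot(noise_sigma >= 0, sampling_interval > 0, t_end > 0)
  structure(list(rates = rates, init = init, seed = seed,
                 noise_sigma = noise_sigma,
                 times = seq(0, t_end, by = sampling_interval),
                 scale_factors = scale_factors, network = network),
            class = "pho_truth")
}

#' Generate a synthetic reporter dataset from a known model
#'
#' ODE-predicted PhoA and PhoB signals at the sampling times, each
#' multiplied by its scale factor and perturbed by independent
#' multiplicative Gaussian noise, `signal * (1 + sigma * z)`, clipped
#' at zero. Seeded and reproducible; the generating truth is returned
#' alongside for recovery scoring (and is never an input to the
#' fitter).
#'
#' @param truth A [ground_truth()].
#' @return List with `dataset` (a `pho_dataset`) and `truth`.
#' @export
generate_dataset <- function(truth) {
  stopifnot(inherits(truth, "pho_truth"))
  pred <- predict_observables(truth$rates, truth$init, truth$times,
                              truth$scale_factors, truth$network)
  set.seed(truth$seed)
  noisy <- function(y) {
    pmax(0, y * (1 + truth$noise_sigma * stats::rnorm(length(y))))
  }
  list(dataset = observed_dataset(truth$times, noisy(pred$phoA),
                                  if (!is.null(pred$phoB))
                                    noisy(pred$phoB)),
       truth = truth)
}

#' Generate a population-averaged stochastic dataset
#'
#' Mean PhoA count over `n_cells` independent stochastic trajectories,
#' converted back to concentration and scaled — a synthetic stand-in
#' for bulk fluorescence whose only noise source is intrinsic
#' (molecule-number) fluctuation. Converges to the ODE prediction as
#' `n_cells` grows.
#'
#' @param truth A [ground_truth()]; its network may be a reduced
#'   [subnetwork()] for cheap sampling.
#' @param n_cells Number of cells averaged (>= 1).
#' @param ctx A [volume_context()].
#' @return A `pho_dataset` with the `phoA` column only.
#' @export
generate_ssa_dataset <- function(truth, n_cells, ctx = volume_context()) {
  stopifnot(inherits(truth, "pho_truth"), n_cells >= 1)
  net <- truth$network
  if (!"PhoA" %in% net$species) stop("network lacks the PhoA reporter species")
  init_counts <- concentration_to_count(truth$init[net$species], ctx)
  step <- diff(truth$times[1:2])
  t_end <- max(truth$times)
  reps <- run_ensemble(net, truth$rates, init = init_counts, t_end = t_end,
                       n_reps = n_cells, base_seed = truth$seed,
                       output_step = step, ctx = ctx)
  keep <- match(truth$times, reps[[1]]$times)
  phoA_counts <- rowMeans(vapply(reps, function(tc) tc$values[keep, "PhoA"],
                                 numeric(length(keep))))
  observed_dataset(truth$times,
                   count_to_concentration(phoA_counts, ctx) *
                     truth$scale_factors[["phoA"]])
}

#' Parameter-recovery experiment
#'
#' The calibration pipeline's acceptance surface: for each replicate a
#' synthetic dataset is generated from the control-model truth (with
#' the requested noise level), the two-step calibration is run with the
#' requested symbols free (all other rates held at truth), and the
#' per-parameter relative error of the final (step-two) estimate is
#' recorded. Scale factors are held fixed at their true values so that
#' the expression rates remain identifiable from the reporter signals.
#'
#' @param free_symbols Character vector of rate symbols to recover.
#' @param noise_sigma Relative measurement noise of the generator.
#' @param n_replicates Number of replicate datasets.
#' @param seed Base seed; replicate `i` uses `seed + i`.
#' @param n_starts Multi-start count per step-one fit.
#' @return List of class `pho_recovery`: `per_replicate` (data frame
#'   with replicate, symbol, true, estimated, rel_error) and
#'   `median_rel_error` (named, per symbol, median over replicates).
#' @export
recovery_experiment <- function(free_symbols, noise_sigma = 0.05,
                                n_replicates = 10, seed = 1, n_starts = 8) {
  if (length(free_symbols) == 0) {
    return(structure(list(per_replicate = data.frame(
      replicate = integer(), symbol = character(), true = numeric(),
      estimated = numeric(), rel_error = numeric()),
      median_rel_error = stats::setNames(numeric(0), character(0))),
      class = "pho_recovery"))
  }
  allowed <- unlist(default_free_groups())
  if (!all(free_symbols %in% allowed)) {
    stop("free_symbols must come from the default calibration set: ",
         paste(setdiff(free_symbols, allowed), collapse = ", "))
  }
  true_values <- rate_values(default_rates())[free_symbols]
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    truth <- ground_truth(seed = seed + i, noise_sigma = noise_sigma)
    gen <- generate_dataset(truth)
    spec <- fit_spec(free = as.list(free_symbols), n_starts = n_starts,
                     seed = seed + i, scale_mode = "fixed")
    ts <- two_step_fit(gen$dataset, spec)
    est <- rate_values(ts$step2$best_rates)[free_symbols]
    rows[[i]] <- data.frame(replicate = i, symbol = free_symbols,
                            true = unname(true_values),
                            estimated = unname(est),
                            rel_error = unname(abs(est - true_values) /
                                                 true_values))
  }
  per <- do.call(rbind, rows)
  med <- vapply(split(per$rel_error, per$symbol), stats::median, 0)
  structure(list(per_replicate = per,
                 median_rel_error = med[free_symbols]),
            class = "pho_recovery")
}

#' @export
print.pho_recovery <- function(x, ...) {
  cat("<pho_recovery> median relative error over ",
      length(unique(x$per_replicate$replicate)), " replicate(s):\n", sep = "")
  print(signif(x$median_rel_error, 3))
  invisible(x)
}
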