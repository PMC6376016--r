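# Stochastic rate constants from deterministic ones: unimolecular k,
# heterobimolecular k/omega, homodimerisation 2k/omega (with the
# combinatorial factor n(n-1)/2 applied in the propensity), so the SSA
# matches the deterministic k[X]^2 law in the large-volume limit.
stochastic_rate_constants <- function(network, rates, ctx = volume_context()) {
  k <- unname(rate_values(rates)[network$rate_symbols])
  cj <- k
  cj[is_heterobimolecular(network)] <- k[is_heterobimolecular(network)] / ctx$omega
  cj[is_homodimerisation(network)] <- 2 * k[is_homodimerisation(network)] / ctx$omega
  cj
}

#' Reaction propensity in molecule-count space
#'
#' Events per second for one reaction at the given counts:
#' `k n` for unimolecular reactions, `(k/omega) nX nY` for
#' heterobimolecular ones, and `(2k/omega) n(n-1)/2` for the PhoBp
#' homodimerisation. Zero whenever a required reactant is absent.
#'
#' @param reaction_id Reaction id (e.g. `"R10f"`).
#' @param counts Named molecule counts over the network species.
#' @param rates A `pho_rates` table.
#' @param network A `pho_network`.
#' @param ctx A [volume_context()].
#' @return Propensity in events/s.
#' @export
propensity <- function(reaction_id, counts, rates, network = pho_network(),
                       ctx = volume_context()) {
  ids <- vapply(network$reactions, `[[`, "", "id")
  j <- match(reaction_id, ids)
  if (is.na(j)) stop("unknown reaction id: ", reaction_id)
  if (any(counts < 0)) stop("counts must be non-negative")
  x <- counts[network$species]
  cj <- stochastic_rate_constants(network, rates, ctx)[j]
  n1 <- x[network$reactant1[j]]
  if (network$order[j] == 1L) return(unname(cj * n1))
  if (network$reactant1[j] == network$reactant2[j]) {
    return(unname(cj * n1 * (n1 - 1) / 2))
  }
  unname(cj * n1 * x[network$reactant2[j]])
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates the network in molecule-count space with the direct method
#' and samples the trajectory onto a uniform output grid
#' (last-event-carried-forward). If all propensities vanish before
#' `t_end` the state is absorbing and is held to the end. Identical
#' seed and inputs give an identical trajectory.
#'
#' @param network A `pho_network`.
#' @param rates A `pho_rates` table (deterministic units; converted
#'   internally).
#' @param init_counts Named non-negative integer counts; defaults to
#'   the discretised [default_initial_state()].
#' @param t_end End time, seconds.
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @param output_step Output grid spacing, seconds.
#' @param ctx A [volume_context()].
#' @return A `pho_timecourse` in the count domain, with attributes
#'   `n_events` and `seed`.
#' @export
simulate_ssa <- function(network = pho_network(), rates = default_rates(),
                         init_counts = NULL, t_end = 16200, seed = NULL,
                         output_step = 10, ctx = volume_context()) {
  stopifnot(inherits(network, "pho_network"), t_end > 0)
  if (is.null(init_counts)) {
    init_counts <- concentration_to_count(default_initial_state(ctx), ctx)
  }
  init_counts <- init_counts[network$species]
  if (anyNA(init_counts)) stop("init_counts does not cover all network species")
  if (any(init_counts < 0) || any(init_counts != round(init_counts))) {
    stop("init_counts must be non-negative integers")
  }
  if (!is.null(seed)) set.seed(seed)
  # 64-bit stream seed drawn from R's RNG, so set.seed() governs the run
  seed64 <- floor(stats::runif(2) * 2^32)
  cj <- stochastic_rate_constants(network, rates, ctx)
  times <- seq(0, t_end, by = output_step)
  res <- ssa_direct_cpp(network$S, network$reactant1, network$reactant2,
                        cj, as.numeric(init_counts), times, seed64)
  values <- res$counts
  colnames(values) <- network$species
  tc <- new_timecourse(times, values, domain = "count",
                       volume_um3 = ctx$volume_um3)
  attr(tc, "n_events") <- res$n_events
  attr(tc, "seed") <- seed
  tc
}

#' Ensemble of independent stochastic trajectories
#'
#' Runs `n_reps` independent simulations with per-replicate seeds
#' `base_seed + 1, ..., base_seed + n_reps`, so the ensemble is
#' reproducible and independent of execution order.
#'
#' @inheritParams simulate_ssa
#' @param init Named integer counts (see [simulate_ssa()]).
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Integer base seed.
#' @return List of `pho_timecourse` objects (count domain).
#' @export
run_ensemble <- function(network = pho_network(), rates = default_rates(),
                         init = NULL, t_end = 16200, n_reps = 100,
                         base_seed = 1, output_step = 10,
                         ctx = volume_context()) {
  stopifnot(n_reps >= 1)
  lapply(seq_len(n_reps), function(i) {
    simulate_ssa(network, rates, init_counts = init, t_end = t_end,
                 seed = base_seed + i, output_step = output_step, ctx = ctx)
  })
}
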