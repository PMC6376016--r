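#' External-phosphate regime scan
#'
#' External inorganic phosphate enters the model only through the PhoR
#' autophosphorylation propensity: a fold factor applied to r1 and r2
#' (1 = starvation at 0 uM external Pi; smaller factors emulate
#' increasing external Pi, which suppresses PhoR activation via the
#' Pst/PhoU pathway abstracted out of the explicit species).
#'
#' @param factors Positive fold factors (default the four study
#'   regimes 1, 0.5, 0.2, 0.1).
#' @param network,rates,init,config Model inputs as in
#'   [simulate_ode()].
#' @return List of class `pho_regime_scan`: `trajectories` (one
#'   `pho_timecourse` per factor) and `summary` (data frame with
#'   `factor`, `ss_DiPhoBpp`, `ss_pPhoAa` (uM), `auc_PhoA` (uM*s)).
#' @export
pi_regime_scan <- function(factors = c(1, 0.5, 0.2, 0.1),
                           network = pho_network(), rates = default_rates(),
                           init = default_initial_state(),
                           config = sim_config()) {
  stopifnot(all(factors > 0))
  tcs <- lapply(factors, function(f) {
    simulate_ode(network, apply_fold_changes(rates, c(r1 = f, r2 = f)),
                 init, config)
  })
  names(tcs) <- paste0("factor_", factors)
  summary <- data.frame(
    factor = factors,
    ss_DiPhoBpp = vapply(tcs, function(tc)
      as.numeric(steady_state_value(tc, "DiPhoBpp")), 0),
    ss_pPhoAa = vapply(tcs, function(tc)
      as.numeric(steady_state_value(tc, "pPhoAa")), 0),
    auc_PhoA = vapply(tcs, auc, 0, species = "PhoA"),
    row.names = NULL
  )
  structure(list(trajectories = tcs, summary = summary),
            class = "pho_regime_scan")
}

#' Promoter-design fold-change scan
#'
#' Scans synthetic promoter designs as fold factors on the
#' transcription-factor binding rates (r10/r11) and unbinding rates
#' (r10r/r11r) under a given external-Pi regime. The default 10 x 10
#' grid (0.25 to 2.5 in steps of 0.25) gives 100 simulations per
#' regime; each cell records the steady-state active-promoter level
#' `ss_pPhoAa` and the PhoA yield `auc_PhoA`. The control model's
#' PhoA AUC (all factors 1, starvation regime) is attached as the
#' normalisation reference.
#'
#' @param binding_folds,unbinding_folds Non-negative fold grids.
#' @param regime_factor External-Pi fold factor on r1/r2.
#' @param network,rates,init,config Model inputs.
#' @param keep_trajectories Keep full trajectories per cell (memory
#'   heavy; off by default).
#' @return A `pho_scan` data frame (one row per cell:
#'   `regime_factor`, `binding_fold`, `unbinding_fold`, `ss_pPhoAa`,
#'   `auc_PhoA`) with attributes `control_auc` and, optionally,
#'   `trajectories`.
#' @export
promoter_design_scan <- function(binding_folds = seq(0.25, 2.5, by = 0.25),
                                 unbinding_folds = seq(0.25, 2.5, by = 0.25),
                                 regime_factor = 1,
                                 network = pho_network(),
                                 rates = default_rates(),
                                 init = default_initial_state(),
                                 config = sim_config(),
                                 keep_trajectories = FALSE) {
  stopifnot(all(binding_folds >= 0), all(unbinding_folds >= 0),
            regime_factor > 0)
  control <- simulate_ode(network, rates, init, config)
  control_auc <- auc(control, "PhoA")
  grid <- expand.grid(binding_fold = binding_folds,
                      unbinding_fold = unbinding_folds)
  tcs <- if (keep_trajectories) vector("list", nrow(grid)) else NULL
  ss <- numeric(nrow(grid)); au <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fc <- c(r1 = regime_factor, r2 = regime_factor,
            r10 = grid$binding_fold[i], r11 = grid$binding_fold[i],
            r10r = grid$unbinding_fold[i], r11r = grid$unbinding_fold[i])
    tc <- simulate_ode(network, apply_fold_changes(rates, fc), init, config)
    ss[i] <- as.numeric(steady_state_value(tc, "pPhoAa"))
    au[i] <- auc(tc, "PhoA")
    if (keep_trajectories) tcs[[i]] <- tc
  }
  out <- data.frame(regime_factor = regime_factor,
                    binding_fold = grid$binding_fold,
                    unbinding_fold = grid$unbinding_fold,
                    ss_pPhoAa = ss, auc_PhoA = au)
  attr(out, "control_auc") <- control_auc
  if (keep_trajectories) attr(out, "trajectories") <- tcs
  class(out) <- c("pho_scan", "data.frame")
  out
}

#' Promoter designs reproducing the starvation response
#'
#' Cells of a promoter-design scan whose PhoA yield matches the
#' control (starvation, unmodified promoter) yield within a relative
#' tolerance — the designs predicted to restore the starvation-level
#' response under higher external Pi. If no cell falls within the
#' tolerance the single nearest cell is returned, flagged with
#' `nearest = TRUE`.
#'
#' @param scan A `pho_scan` from [promoter_design_scan()].
#' @param reference Reference PhoA AUC (default: the scan's attached
#'   control AUC).
#' @param tolerance Relative tolerance (default 0.01 = 1%).
#' @return Subset of `scan` rows with an added `rel_deviation`
#'   column; attribute `nearest` marks the fallback case.
#' @export
find_starvation_equivalent_designs <- function(scan,
                                               reference =
                                                 attr(scan, "control_auc"),
                                               tolerance = 0.01) {
  stopifnot(inherits(scan, "pho_scan"), is.numeric(reference),
            reference > 0, tolerance >= 0)
  dev <- abs(scan$auc_PhoA - reference) / reference
  hit <- dev <= tolerance
  nearest <- FALSE
  if (!any(hit)) {
    hit <- seq_along(dev) == which.min(dev)
    nearest <- TRUE
  }
  out <- as.data.frame(scan)[hit, , drop = FALSE]
  out$rel_deviation <- dev[hit]
  attr(out, "nearest") <- nearest
  out
}

# Discretise a concentration state to counts, keeping each promoter
# total at exactly 10 copies (independent rounding could break the
# integer conservation the SSA relies on).
discretise_state <- function(state, ctx) {
  counts <- concentration_to_count(state, ctx)
  for (pair in list(c("pPhoAa", "pPhoA"), c("pPhoBa", "pPhoB"))) {
    if (all(pair %in% names(state))) {
      total <- concentration_to_count(sum(state[pair]), ctx)
      counts[pair[1]] <- min(counts[pair[1]], total)
      counts[pair[2]] <- total - counts[pair[1]]
    }
  }
  counts
}

#' Promoter-unbinding noise study
#'
#' Quantifies how the transcription-factor unbinding rate shapes gene
#' expression noise: for each value of r10r = r11r, stochastic
#' ensembles are sampled around the induced quasi-stationary state and
#' the noise ratio (sd/mean) of mRNA and active-promoter levels is
#' computed.
#'
#' Sampling protocol: the deterministic model (with the modified
#' unbinding rate) is integrated to `anchor_time`, a mid-induction
#' operating point where promoter occupancy is equilibrated and mRNA
#' is close to its plateau; each replicate starts from that state
#' discretised to counts, with mRNA counts drawn from a Poisson law at
#' the deterministic mean (the stationary law of the birth-death
#' motif, so the ensemble needs almost no stochastic burn-in), runs
#' for `t_end` seconds, and is sampled on the window
#' `[burn_in, t_end]`. The default window is deliberately short: the
#' fully induced network fires millions of phosphotransfer events per
#' simulated second, and promoter/mRNA fluctuation statistics
#' converge through the replicate ensemble rather than through long
#' single runs.
#'
#' @param unbinding_rates Values for r10r/r11r in 1/s (default the
#'   study's 100, 1000, 5000).
#' @param n_reps Replicates per rate (default 100).
#' @param seed Integer base seed.
#' @param species Species to summarise.
#' @param network,rates,init Model inputs.
#' @param anchor_time Deterministic induction time before stochastic
#'   sampling starts (s).
#' @param t_end Stochastic span per replicate (s).
#' @param burn_in Portion of each replicate discarded before sampling
#'   (s).
#' @param output_step Sampling grid step (s).
#' @param ctx A [volume_context()].
#' @return Data frame of class `pho_noise_study`: one row per
#'   (unbinding rate, species) with `mean`, `sd`, `ratio`,
#'   `n_samples`.
#' @export
unbinding_noise_study <- function(unbinding_rates = c(100, 1000, 5000),
                                  n_reps = 100, seed = 1,
                                  species = c("mRNAa", "mRNAb",
                                              "pPhoAa", "pPhoBa"),
                                  network = pho_network(),
                                  rates = default_rates(),
                                  init = default_initial_state(),
                                  anchor_time = 450, t_end = 40,
                                  burn_in = 10, output_step = 1,
                                  ctx = volume_context()) {
  stopifnot(all(unbinding_rates > 0), n_reps >= 1, burn_in < t_end)
  rows <- list()
  for (k in seq_along(unbinding_rates)) {
    ku <- unbinding_rates[k]
    rk <- set_rates(rates, c(r10r = ku, r11r = ku))
    anchor <- simulate_ode(network, rk, init,
                           sim_config(t_end = anchor_time, output_step = 10))
    state <- anchor$values[nrow(anchor$values), ]
    counts0 <- discretise_state(state, ctx)
    mRNA_mean <- state[c("mRNAa", "mRNAb")] * ctx$omega
    reps <- vector("list", n_reps)
    for (i in seq_len(n_reps)) {
      set.seed(seed + 100000L * k + i)
      counts <- counts0
      counts[c("mRNAa", "mRNAb")] <- stats::rpois(2, mRNA_mean)
      reps[[i]] <- simulate_ssa(network, rk, init_counts = counts,
                                t_end = t_end, seed = NULL,
                                output_step = output_step, ctx = ctx)
    }
    for (sp in species) {
      nr <- noise_ratio(reps, sp, window = c(burn_in, t_end))
      rows[[length(rows) + 1L]] <- data.frame(
        unbinding_rate = ku, species = sp, mean = nr$mean, sd = nr$sd,
        ratio = nr$ratio, n_samples = nr$n_samples)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pho_noise_study", "data.frame")
  out
}

ranged_parameters <- function(rates) {
  rates$symbol[!is.na(rates$lo) & !is.na(rates$hi)]
}

#' Range-based local sensitivity analysis
#'
#' For every rate constant with a finite literature range, the model
#' is simulated with the parameter at the range maximum and at the
#' range minimum (all other rates at control values); the entry for
#' (parameter, species) is the signed difference of the species AUCs,
#' normalised by the control-model AUC:
#' `(AUC(p = max) - AUC(p = min)) / AUC(control)`. A degenerate range
#' (min = max) yields a zero row. Species whose control AUC is zero
#' are flagged `NA`.
#'
#' @param network,rates,init,config Model inputs.
#' @return A `pho_sensitivity` matrix (parameters x species), with
#'   attributes `mode = "range"` and `control_auc`.
#' @export
range_sensitivity <- function(network = pho_network(),
                              rates = default_rates(),
                              init = default_initial_state(),
                              config = sim_config()) {
  params <- ranged_parameters(rates)
  control <- simulate_ode(network, rates, init, config)
  auc_control <- vapply(network$species, auc, 0, tc = control)
  M <- matrix(NA_real_, length(params), length(network$species),
              dimnames = list(params, network$species))
  for (p in params) {
    i <- match(p, rates$symbol)
    lo <- rates$lo[i]; hi <- rates$hi[i]
    if (lo == hi) { M[p, ] <- 0; next }
    auc_hi <- vapply(network$species, auc, 0,
                     tc = simulate_ode(network, set_rates(rates,
                       stats::setNames(hi, p)), init, config))
    auc_lo <- vapply(network$species, auc, 0,
                     tc = simulate_ode(network, set_rates(rates,
                       stats::setNames(lo, p)), init, config))
    M[p, ] <- ifelse(auc_control > 0, (auc_hi - auc_lo) / auc_control,
                     NA_real_)
  }
  structure(M, mode_tag = "range", control_auc = auc_control,
            class = c("pho_sensitivity", class(M)))
}

#' Fold-change sweep sensitivity analysis
#'
#' One-at-a-time sweep: each rate constant is multiplied by every
#' factor of a fold grid spanning six orders of magnitude (default
#' 1e-3 to 1e3), the model is re-simulated, and each species AUC is
#' normalised by the control AUC. Integration failures are recorded
#' per cell (`NA` ratios, `failed = TRUE`) without aborting the sweep.
#'
#' @param network,rates,init,config Model inputs.
#' @param fold_grid Positive fold factors (default `10^(-3:3)`).
#' @param symbols Rate symbols to sweep (default: all 29).
#' @return Long data frame of class `pho_sweep`: `rate`, `fold`,
#'   `species`, `auc_ratio`, `failed`.
#' @export
sweep_sensitivity <- function(network = pho_network(),
                              rates = default_rates(),
                              init = default_initial_state(),
                              config = sim_config(),
                              fold_grid = 10^(-3:3),
                              symbols = rates$symbol) {
  stopifnot(all(fold_grid > 0))
  control <- simulate_ode(network, rates, init, config)
  auc_control <- vapply(network$species, auc, 0, tc = control)
  rows <- list()
  for (sym in symbols) {
    for (f in fold_grid) {
      au <- tryCatch({
        tc <- simulate_ode(network,
                           apply_fold_changes(rates, stats::setNames(f, sym)),
                           init, config)
        vapply(network$species, auc, 0, tc = tc)
      }, error = function(e) NULL)
      failed <- is.null(au)
      ratio <- if (failed) rep(NA_real_, length(network$species))
               else ifelse(auc_control > 0, au / auc_control, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        rate = sym, fold = f, species = network$species,
        auc_ratio = unname(ratio), failed = failed, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pho_sweep", "data.frame")
  out
}
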