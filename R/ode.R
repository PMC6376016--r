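#' Simulation configuration
#'
#' @param t_end End time in seconds (default 16200 s = 4.5 h, the
#'   starvation window the reporter assays cover).
#' @param output_step Output grid spacing in seconds (default 10 s).
#' @param rtol,atol Relative and absolute integrator tolerances. The
#'   defaults (1e-8, 1e-12 uM) are deliberately tight: the network mixes
#'   1e4 uM^-1 s^-1 promoter binding with 1e-4 s^-1 protein degradation,
#'   eight orders of magnitude apart, so a stiff method with tight
#'   tolerances is required.
#' @return List of class `pho_sim_config`.
#' @export
sim_config <- function(t_end = 16200, output_step = 10,
                       rtol = 1e-8, atol = 1e-12) {
  stopifnot(t_end > 0, output_step > 0, output_step <= t_end)
  structure(list(t_end = t_end, output_step = output_step,
                 rtol = rtol, atol = atol),
            class = "pho_sim_config")
}

output_grid <- function(config) {
  seq(0, config$t_end, by = config$output_step)
}

mass_action_parms <- function(network, rates) {
  k <- rate_values(rates)[network$rate_symbols]
  if (anyNA(k)) {
    stop("rates table is missing symbol(s): ",
         paste(network$rate_symbols[is.na(k)], collapse = ", "))
  }
  bi <- which(network$order == 2L)
  list(k = unname(k), re1 = network$reactant1, bi = bi,
       re2bi = network$reactant2[bi], S = unname(network$S) * 1.0)
}

rhs_fn <- function(t, y, p) {
  v <- p$k * y[p$re1]
  if (length(p$bi)) v[p$bi] <- v[p$bi] * y[p$re2bi]
  list(as.vector(p$S %*% v))
}

#' Mass-action right-hand side of the network ODEs
#'
#' Derivatives are the standard stoichiometric translation of the
#' reaction network, `dy/dt = S v(y)`, with mass-action velocities:
#' `k [X]` for unimolecular, `k [X][Y]` for heterobimolecular, and
#' `k [X]^2` for the PhoBp homodimerisation.
#'
#' @param state Named species vector in uM (canonical network order).
#' @param rates A `pho_rates` table.
#' @param network A `pho_network`.
#' @return Named derivative vector in uM/s.
#' @export
ode_rhs <- function(state, rates, network = pho_network()) {
  stopifnot(length(state) == length(network$species))
  if (!is.null(names(state))) state <- state[network$species]
  p <- mass_action_parms(network, rates)
  stats::setNames(rhs_fn(0, unname(state), p)[[1]], network$species)
}

#' Deterministic time-course simulation
#'
#' Integrates the mass-action ODEs with a stiff-capable solver
#' (`deSolve::lsoda`) on a uniform output grid.
#'
#' Concentrations marginally below zero (integrator noise) are clipped
#' to zero on output; negative excursions beyond `1e-9` uM abort with
#' the offending time, as they indicate a genuinely failed integration.
#'
#' @param network A `pho_network` (default: the full control network).
#' @param rates A `pho_rates` table.
#' @param init Named initial state in uM; defaults to
#'   [default_initial_state()] for the full network.
#' @param config A [sim_config()].
#' @return A `pho_timecourse`: list with `times` (s), `values`
#'   (time x species matrix, uM), `domain = "concentration"`.
#' @examples
#' \donttest{
#' tc <- simulate_ode(config = sim_config(t_end = 600))
#' time_to_peak(tc, "DiPhoBpp")
#' }
#' @export
simulate_ode <- function(network = pho_network(), rates = default_rates(),
                         init = default_initial_state(),
                         config = sim_config()) {
  stopifnot(inherits(network, "pho_network"))
  if (is.null(names(init))) names(init) <- network$species
  init <- init[network$species]
  if (anyNA(init)) stop("initial state does not cover all network species")
  p <- mass_action_parms(network, rates)
  times <- output_grid(config)
  out <- deSolve::ode(y = unname(init), times = times, func = rhs_fn,
                      parms = p, method = "lsoda",
                      rtol = config$rtol, atol = config$atol,
                      maxsteps = 50000)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    stop("ODE integration failed at t = ", max(out[, 1]),
         " s (istate ", istate[1], ")")
  }
  values <- out[, -1, drop = FALSE]
  colnames(values) <- network$species
  neg_floor <- -1e-9
  if (any(values < neg_floor)) {
    bad <- which(values < neg_floor, arr.ind = TRUE)[1, ]
    stop("negative concentration at t = ", times[bad[1]], " s for species ",
         network$species[bad[2]])
  }
  values[values < 0] <- 0
  new_timecourse(times, values, domain = "concentration")
}

new_timecourse <- function(times, values, domain = c("concentration", "count"),
                           volume_um3 = 1) {
  domain <- match.arg(domain)
  stopifnot(nrow(values) == length(times), times[1] == 0,
            !is.unsorted(times, strictly = TRUE))
  structure(list(times = times, values = values, domain = domain,
                 volume_um3 = volume_um3),
            class = "pho_timecourse")
}

#' @export
print.pho_timecourse <- function(x, ...) {
  cat("<pho_timecourse> ", length(x$times), " time points over [0, ",
      max(x$times), "] s; ", ncol(x$values), " species (",
      x$domain, " domain)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.pho_timecourse <- function(x, ...) {
  data.frame(time_s = x$times, x$values, check.names = FALSE)
}

tc_values <- function(tc, species) {
  stopifnot(inherits(tc, "pho_timecourse"))
  if (!species %in% colnames(tc$values)) {
    stop("species '", species, "' not in trajectory")
  }
  tc$values[, species]
}
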