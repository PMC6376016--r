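#' Default rate constants of the control model
#'
#' Returns the 29 fitted rate constants of the control model, together
#' with the physiological literature ranges used as calibration bounds
#' and a provenance tag per rate:
#' \describe{
#'   \item{`literature-fixed`}{point value taken from the literature
#'     (binding rates r3/r5/r7/r8 and r10/r11, transcription-factor
#'     unbinding r10r/r11r fixed at 1000/s, mRNA decay r20/r21).}
#'   \item{`range-fitted`}{fitted within a literature range (or below a
#'     literature upper limit, in which case `lo` is `NA`).}
#'   \item{`unconstrained-fitted`}{fitted with no literature constraint
#'     (the complex dissociation rates r3r/r5r/r7r/r8r).}
#' }
#' Units are `per-second` for unimolecular reactions and
#' `per-uM-per-second` for the six bimolecular association reactions.
#'
#' @return A `pho_rates` data frame with columns `symbol`, `value`,
#'   `units`, `lo`, `hi`, `provenance`.
#' @examples
#' r <- default_rates()
#' r[r$symbol == "r4", ]  # 21.3718, bounds 17-23 /s
#' @export
default_rates <- function() {
  df <- data.frame(
    symbol = c("r1", "r1r", "r2", "r2r", "r3", "r3r", "r4",
               "r5", "r5r", "r6", "r7", "r7r", "r8", "r8r", "r9",
               "r10", "r10r", "r11", "r11r",
               "r12", "r13", "r14", "r15", "r16",
               "r17", "r18", "r19", "r20", "r21"),
    value = c(25.3658, 8.1165, 25.3658, 8.1165, 100, 4.9411, 21.3718,
              100, 4.9411, 21.3718, 100, 4.9411, 100, 4.9411, 12.95,
              10000, 1000, 10000, 1000,
              0.0540, 0.0302, 0.130, 0.035, 0.0302,
              0.0001, 0.0001, 0.0001, 0.0055, 0.0055),
    lo = c(10, NA, 10, NA, NA, NA, 17,
           NA, NA, 17, NA, NA, NA, NA, NA,
           NA, NA, NA, NA,
           0.0025, 0.0006, 0.0025, 0.0006, 0.0006,
           0.000096, 0.000096, 0.000096, NA, NA),
    hi = c(100, 10, 100, 10, NA, NA, 23,
           NA, NA, 23, NA, NA, NA, NA, 17,
           NA, NA, NA, NA,
           0.2, 0.05, 0.2, 0.05, 0.05,
           0.00079, 0.00079, 0.00079, NA, NA),
    provenance = c("range-fitted", "range-fitted", "range-fitted", "range-fitted",
                   "literature-fixed", "unconstrained-fitted", "range-fitted",
                   "literature-fixed", "unconstrained-fitted", "range-fitted",
                   "literature-fixed", "unconstrained-fitted",
                   "literature-fixed", "unconstrained-fitted", "range-fitted",
                   "literature-fixed", "literature-fixed",
                   "literature-fixed", "literature-fixed",
                   "range-fitted", "range-fitted", "range-fitted",
                   "range-fitted", "range-fitted",
                   "range-fitted", "range-fitted", "range-fitted",
                   "literature-fixed", "literature-fixed"),
    stringsAsFactors = FALSE
  )
  bimol <- df$symbol %in% c("r3", "r5", "r7", "r8", "r10", "r11")
  df$units <- ifelse(bimol, "per-uM-per-second", "per-second")
  df <- df[, c("symbol", "value", "units", "lo", "hi", "provenance")]
  class(df) <- c("pho_rates", "data.frame")
  validate_rates(df)
  df
}

validate_rates <- function(rates) {
  stopifnot(inherits(rates, "data.frame"),
            all(c("symbol", "value") %in% names(rates)))
  if (any(rates$value < 0)) stop("rate constants must be non-negative")
  bounded <- !is.na(rates$lo) & !is.na(rates$hi)
  bad <- bounded & (rates$value < rates$lo | rates$value > rates$hi)
  if (any(bad)) {
    stop("rate(s) outside literature bounds: ",
         paste(rates$symbol[bad], collapse = ", "))
  }
  invisible(rates)
}

#' Named vector of rate values
#'
#' @param rates A `pho_rates` table.
#' @return Named numeric vector (symbol -> value).
#' @export
rate_values <- function(rates) {
  stats::setNames(rates$value, rates$symbol)
}

#' Set rate values by symbol
#'
#' Replaces values (no fold change); unknown symbols are an error.
#' Literature bounds are left untouched and not re-enforced, so
#' perturbation studies may deliberately leave the physiological range.
#'
#' @param rates A `pho_rates` table.
#' @param values Named numeric vector of replacement values.
#' @return Modified `pho_rates`.
#' @export
set_rates <- function(rates, values) {
  unknown <- setdiff(names(values), rates$symbol)
  if (length(unknown)) stop("unknown rate symbol(s): ", paste(unknown, collapse = ", "))
  if (any(values < 0)) stop("rate constants must be non-negative")
  rates$value[match(names(values), rates$symbol)] <- unname(values)
  rates
}

#' Apply multiplicative fold changes to rate constants
#'
#' The model's handle for perturbation studies: external phosphate
#' regimes are emulated as fold factors on the PhoR autophosphorylation
#' rates r1/r2, promoter designs as fold factors on the
#' binding/unbinding rates r10/r11 and r10r/r11r, and sensitivity sweeps
#' as per-rate fold grids. Multipliers are applied to the current
#' values; bounds are never re-enforced (scans deliberately leave the
#' physiological ranges).
#'
#' @param rates A `pho_rates` table.
#' @param fold_changes Named numeric vector of non-negative multipliers
#'   (rate symbol -> factor). An empty or all-ones spec returns the
#'   input unchanged.
#' @return Modified `pho_rates`.
#' @examples
#' r <- apply_fold_changes(default_rates(), c(r1 = 0.5, r2 = 0.5))
#' rate_values(r)[["r1"]]  # 12.6829
#' @export
apply_fold_changes <- function(rates, fold_changes) {
  if (length(fold_changes) == 0) return(rates)
  unknown <- setdiff(names(fold_changes), rates$symbol)
  if (length(unknown)) stop("unknown rate symbol(s): ", paste(unknown, collapse = ", "))
  if (any(fold_changes < 0)) stop("fold-change multipliers must be non-negative")
  i <- match(names(fold_changes), rates$symbol)
  rates$value[i] <- rates$value[i] * unname(fold_changes)
  rates
}

#' Read a flat rate/initial-state configuration file
#'
#' Accepts JSON or YAML with flat `key: value` pairs. Keys must be rate
#' symbols (r1...r21, r1r...r11r) or species names; anything else is an
#' error. Returns the default rates and initial state with the listed
#' entries overridden.
#'
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @param ctx Volume context for the default initial state.
#' @return List with elements `rates` (`pho_rates`) and `init`
#'   (named numeric vector, uM).
#' @export
read_model_config <- function(path, ctx = volume_context()) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(cfg)) cfg <- as.list(cfg)
  rates <- default_rates()
  init <- default_initial_state(ctx)
  unknown <- setdiff(names(cfg), c(rates$symbol, names(init)))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  rate_keys <- intersect(names(cfg), rates$symbol)
  if (length(rate_keys)) {
    rates <- set_rates(rates, unlist(cfg[rate_keys]))
  }
  sp_keys <- intersect(names(cfg), names(init))
  if (length(sp_keys)) init[sp_keys] <- unlist(cfg[sp_keys])
  list(rates = rates, init = init)
}

#' Dump a network, rates and bounds as a JSON interchange document
#'
#' Canonical plain-text export of the model: species (with roles where
#' known), reactions (reactants, products, rate symbol), and the rate
#' table with bounds and provenance.
#'
#' @param network A `pho_network`.
#' @param rates A `pho_rates` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, rates, path) {
  doc <- list(
    species = lapply(network$species, function(s) {
      list(name = s,
           role = if (s %in% names(PHO_SPECIES_ROLE)) PHO_SPECIES_ROLE[[s]] else NA)
    }),
    reactions = lapply(network$reactions, function(r) {
      list(id = r$id, rate = r$rate,
           reactants = as.list(r$reactants), products = as.list(r$products))
    }),
    rates = rates
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
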