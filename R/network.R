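#' @useDynLib phoregulon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical species order used by every engine. Keep stable: stoichiometric
# matrices, initial-state vectors and C++ code all index into this order.
PHO_SPECIES <- c(
  "DiPhoR", "DiPhoRp", "DiPhoRpp",
  "PhoB", "PhoBp", "DiPhoBpp",
  "C_RppB", "C_RpB", "C_RBp",
  "pPhoA", "pPhoAa", "pPhoB", "pPhoBa",
  "mRNAa", "mRNAb", "PhoA"
)

PHO_SPECIES_ROLE <- c(
  DiPhoR = "kinase", DiPhoRp = "kinase", DiPhoRpp = "kinase",
  PhoB = "regulator", PhoBp = "regulator", DiPhoBpp = "regulator",
  C_RppB = "complex", C_RpB = "complex", C_RBp = "complex",
  pPhoA = "promoter", pPhoAa = "promoter",
  pPhoB = "promoter", pPhoBa = "promoter",
  mRNAa = "transcript", mRNAb = "transcript",
  PhoA = "product"
)

#' Construct a mass-action reaction network
#'
#' Low-level constructor used both for the full Pho regulon model
#' ([pho_network()]) and for reduced sub-networks in analytical cross-checks
#' (see [subnetwork()]). Reactions follow mass-action kinetics; reaction
#' order must be 1 or 2.
#'
#' @param species Character vector of species names.
#' @param reactions List of reactions; each a list with elements `id`
#'   (character), `rate` (rate-constant symbol, character), `reactants`
#'   and `products` (named integer vectors of stoichiometries).
#' @return An object of class `pho_network`: species, reactions, the
#'   net stoichiometric matrix `S` (species x reactions), reactant index
#'   vectors used by the simulation engines, and per-reaction order.
#' @export
reaction_network <- function(species, reactions) {
  stopifnot(is.character(species), !anyDuplicated(species), length(reactions) >= 1)
  n_sp <- length(species)
  n_rx <- length(reactions)
  S <- matrix(0L, n_sp, n_rx, dimnames = list(species, vapply(reactions, `[[`, "", "id")))
  re1 <- integer(n_rx); re2 <- integer(n_rx); ord <- integer(n_rx)
  rate_sym <- character(n_rx)
  for (j in seq_len(n_rx)) {
    rx <- reactions[[j]]
    for (side in c("reactants", "products")) {
      st <- rx[[side]]
      if (length(st) == 0) next
      if (!all(names(st) %in% species)) {
        stop("reaction ", rx$id, " references undeclared species: ",
             paste(setdiff(names(st), species), collapse = ", "))
      }
    }
    sgn_r <- rx$reactants
    ord[j] <- sum(sgn_r)
    if (!ord[j] %in% c(1L, 2L)) {
      stop("reaction ", rx$id, " has order ", ord[j], "; only 1 or 2 supported")
    }
    for (nm in names(sgn_r)) S[nm, j] <- S[nm, j] - as.integer(sgn_r[[nm]])
    for (nm in names(rx$products)) S[nm, j] <- S[nm, j] + as.integer(rx$products[[nm]])
    idx <- match(names(sgn_r), species)
    if (length(sgn_r) == 1L && sgn_r[[1]] == 2L) {        # homodimerisation
      re1[j] <- idx[1]; re2[j] <- idx[1]
    } else if (length(sgn_r) == 2L) {                      # heterobimolecular
      re1[j] <- idx[1]; re2[j] <- idx[2]
    } else {                                               # unimolecular
      re1[j] <- idx[1]; re2[j] <- 0L
    }
    rate_sym[j] <- rx$rate
  }
  structure(
    list(species = species, reactions = reactions, S = S,
         rate_symbols = rate_sym, reactant1 = re1, reactant2 = re2,
         order = ord),
    class = "pho_network"
  )
}

#' @export
print.pho_network <- function(x, ...) {
  cat("<pho_network> ", length(x$species), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

rxn <- function(id, rate, reactants, products = integer()) {
  list(id = id, rate = rate,
       reactants = vapply(reactants, as.integer, 1L),
       products = if (length(products)) vapply(products, as.integer, 1L) else integer())
}

#' The Pho regulon control network
#'
#' Builds the 16-species, 29-reaction mass-action network of the PhoR/PhoB
#' two-component phosphate starvation response: PhoR dimer
#' autophosphorylation (R1-R2), phosphotransfer to PhoB via transient
#' complexes (R3-R6), PhoBp dimerisation into the active transcription
#' factor DiPhoBpp (R7), the phosphatase branch through the
#' DiPhoR-PhoBp complex (R8-R9), transcription-factor binding to the
#' PhoA and PhoB promoters (R10-R11), transcription and translation
#' (R12-R16, catalytic) and first-order degradation/dilution (R17-R21).
#' Eight of the reactions are reversible (R1, R2, R3, R5, R7, R8, R10,
#' R11), giving 8 x 2 + 13 = 29 reactions in total.
#'
#' @return A `pho_network`; see [reaction_network()].
#' @seealso [default_rates()], [default_initial_state()]
#' @examples
#' net <- pho_network()
#' length(net$reactions)  # 29
#' @export
pho_network <- function() {
  reaction_network(PHO_SPECIES, list(
    rxn("R1f",  "r1",   c(DiPhoR = 1),                c(DiPhoRp = 1)),
    rxn("R1r",  "r1r",  c(DiPhoRp = 1),               c(DiPhoR = 1)),
    rxn("R2f",  "r2",   c(DiPhoRp = 1),               c(DiPhoRpp = 1)),
    rxn("R2r",  "r2r",  c(DiPhoRpp = 1),              c(DiPhoRp = 1)),
    rxn("R3f",  "r3",   c(DiPhoRpp = 1, PhoB = 1),    c(C_RppB = 1)),
    rxn("R3r",  "r3r",  c(C_RppB = 1),                c(DiPhoRpp = 1, PhoB = 1)),
    rxn("R4",   "r4",   c(C_RppB = 1),                c(DiPhoRp = 1, PhoBp = 1)),
    rxn("R5f",  "r5",   c(DiPhoRp = 1, PhoB = 1),     c(C_RpB = 1)),
    rxn("R5r",  "r5r",  c(C_RpB = 1),                 c(DiPhoRp = 1, PhoB = 1)),
    rxn("R6",   "r6",   c(C_RpB = 1),                 c(DiPhoR = 1, PhoBp = 1)),
    rxn("R7f",  "r7",   c(PhoBp = 2),                 c(DiPhoBpp = 1)),
    rxn("R7r",  "r7r",  c(DiPhoBpp = 1),              c(PhoBp = 2)),
    rxn("R8f",  "r8",   c(DiPhoR = 1, PhoBp = 1),     c(C_RBp = 1)),
    rxn("R8r",  "r8r",  c(C_RBp = 1),                 c(DiPhoR = 1, PhoBp = 1)),
    rxn("R9",   "r9",   c(C_RBp = 1),                 c(DiPhoR = 1, PhoB = 1)),
    rxn("R10f", "r10",  c(DiPhoBpp = 1, pPhoA = 1),   c(pPhoAa = 1)),
    rxn("R10r", "r10r", c(pPhoAa = 1),                c(DiPhoBpp = 1, pPhoA = 1)),
    rxn("R11f", "r11",  c(DiPhoBpp = 1, pPhoB = 1),   c(pPhoBa = 1)),
    rxn("R11r", "r11r", c(pPhoBa = 1),                c(DiPhoBpp = 1, pPhoB = 1)),
    rxn("R12",  "r12",  c(pPhoAa = 1),                c(pPhoAa = 1, mRNAa = 1)),
    rxn("R13",  "r13",  c(mRNAa = 1),                 c(mRNAa = 1, PhoA = 1)),
    rxn("R14",  "r14",  c(pPhoBa = 1),                c(pPhoBa = 1, mRNAb = 1)),
    rxn("R15",  "r15",  c(mRNAb = 1),                 c(mRNAb = 1, PhoB = 1)),
    rxn("R16",  "r16",  c(mRNAb = 1),                 c(mRNAb = 1, DiPhoR = 1)),
    rxn("R17",  "r17",  c(PhoA = 1)),
    rxn("R18",  "r18",  c(PhoB = 1)),
    rxn("R19",  "r19",  c(DiPhoR = 1)),
    rxn("R20",  "r20",  c(mRNAa = 1)),
    rxn("R21",  "r21",  c(mRNAb = 1))
  ))
}

#' Extract a sub-network by reaction id
#'
#' Keeps the listed reactions and the species they touch, preserving
#' canonical ordering. Useful for comparing reduced motifs (e.g. the
#' transcription/degradation pair R12/R20, or the promoter binding pair
#' R10f/R10r) against closed-form solutions.
#'
#' @param network A `pho_network`.
#' @param reaction_ids Character vector of reaction ids to retain.
#' @return A `pho_network` restricted to those reactions.
#' @export
subnetwork <- function(network, reaction_ids) {
  stopifnot(inherits(network, "pho_network"))
  ids <- vapply(network$reactions, `[[`, "", "id")
  missing <- setdiff(reaction_ids, ids)
  if (length(missing)) stop("unknown reaction id(s): ", paste(missing, collapse = ", "))
  keep <- network$reactions[match(reaction_ids, ids)]
  touched <- unique(unlist(lapply(keep, function(r) c(names(r$reactants), names(r$products)))))
  reaction_network(network$species[network$species %in% touched], keep)
}

#' Is a reaction bimolecular between two distinct species?
#' @noRd
is_heterobimolecular <- function(network) {
  network$order == 2L & network$reactant1 != network$reactant2
}

#' Is a reaction a homodimerisation (2 X -> ...)?
#' @noRd
is_homodimerisation <- function(network) {
  network$order == 2L & network$reactant1 == network$reactant2
}
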