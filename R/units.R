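AVOGADRO <- 6.02214076e23

#' Volume context for concentration/count conversion
#'
#' A cytoplasmic volume (default 1 um^3, the standard E. coli cell
#' volume) and the derived conversion factor `omega` in molecules per
#' uM: `omega = N_A * V[L] * 1e-6 mol/L`, about 602.214 at 1 um^3, so
#' one molecule corresponds to 0.00166 uM.
#'
#' @param volume_um3 Cell volume in cubic micrometres.
#' @return List with `volume_um3` and `omega` (molecules per uM),
#'   class `pho_volume`.
#' @export
volume_context <- function(volume_um3 = 1) {
  stopifnot(is.numeric(volume_um3), length(volume_um3) == 1, volume_um3 > 0)
  structure(
    list(volume_um3 = volume_um3,
         omega = AVOGADRO * volume_um3 * 1e-15 * 1e-6),
    class = "pho_volume"
  )
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert concentrations (uM) to molecule counts and back
#'
#' `concentration_to_count()` rounds `c * omega` half away from zero to
#' the nearest integer count; `count_to_concentration()` returns
#' `count / omega` exactly, so a round trip starting from an integer
#' count is exact for any volume.
#'
#' @param concentration Non-negative concentration(s) in uM.
#' @param count Non-negative molecule count(s).
#' @param ctx A [volume_context()].
#' @return Counts (integer-valued numeric) or concentrations (uM).
#' @examples
#' ctx <- volume_context(1)
#' concentration_to_count(0.22, ctx)   # 132
#' count_to_concentration(1, ctx)      # 0.00166 uM (3 s.f.)
#' @export
concentration_to_count <- function(concentration, ctx = volume_context()) {
  if (any(concentration < 0)) stop("concentrations must be non-negative")
  round_half_away(concentration * ctx$omega)
}

#' @rdname concentration_to_count
#' @export
count_to_concentration <- function(count, ctx = volume_context()) {
  if (any(count < 0)) stop("counts must be non-negative")
  count / ctx$omega
}

#' Default initial state of the control model
#'
#' Pre-starvation conditions: PhoR (stable as a dimer, so represented by
#' DiPhoR) and PhoB monomer both at 0.22 uM; the catalytically active
#' forms DiPhoRpp and PhoBp at the trace levels 4e-8 and 6e-8 uM; one
#' mRNA molecule of each transcript (0.00166 uM at 1 um^3); 10 copies of
#' each promoter in the inactive state; every complex, the active
#' transcription factor, the singly phosphorylated kinase, active
#' promoters and PhoA start at zero.
#'
#' @param ctx A [volume_context()]; promoter copies (10 each) are
#'   converted to concentration with its `omega`.
#' @return Named numeric vector over the 16 model species, in uM.
#' @export
default_initial_state <- function(ctx = volume_context()) {
  init <- stats::setNames(numeric(length(PHO_SPECIES)), PHO_SPECIES)
  init["DiPhoR"] <- 0.22
  init["PhoB"] <- 0.22
  init["DiPhoRpp"] <- 4e-8
  init["PhoBp"] <- 6e-8
  init["mRNAa"] <- 0.00166
  init["mRNAb"] <- 0.00166
  init["pPhoA"] <- 10 / ctx$omega
  init["pPhoB"] <- 10 / ctx$omega
  init
}
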