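# Physical constants and unit conversions used throughout.
# Gas constant in kcal mol^-1 K^-1 (thermochemistry convention).
R_KCAL <- 0.0019872

# Unit conversions.
HARTREE_TO_KCAL <- 627.5095
HARTREE_TO_EV <- 27.211386
COULOMB_KCAL <- 332.0637 # kcal A mol^-1 e^-2, fixed-point-charge convention

# Rigid water internal geometry (gas-phase experimental values).
WATER_OH <- 0.9572 # A
WATER_HOH <- 104.52 # degrees

# Atom-level site tags (what an individual solute atom is).
ATOM_SITE_TAGS <- c(
  "PHOSPHATE_O", "AMINE_N10", "PURINE_O11", "PURINE_RING_N",
  "RIBOSE_OH", "OTHER"
)

# Hydration-site taxonomy (where a water binds), in priority order for the
# primary-site call; NONE means no hydrogen bond detected.
HYDRATION_SITES <- c(
  "AMINE_N10", "PHOSPHATE", "PURINE_RING", "RIBOSE_OH", "WATER_WATER", "NONE"
)

# Atom tag -> hydration site.
SITE_OF_TAG <- c(
  PHOSPHATE_O = "PHOSPHATE",
  AMINE_N10 = "AMINE_N10",
  PURINE_O11 = "PURINE_RING",
  PURINE_RING_N = "PURINE_RING",
  RIBOSE_OH = "RIBOSE_OH",
  OTHER = "NONE"
)

#' Unit conversions for electronic-structure energies
#'
#' Convert energies between hartree, electron-volt and kcal/mol using the
#' conventional factors 1 hartree = 27.211386 eV = 627.5095 kcal/mol.
#'
#' @param x Numeric vector of energies.
#' @return Numeric vector in the target unit.
#' @examples
#' hartree_to_ev(0.05) # 1.3606 eV
#' @export
hartree_to_ev <- function(x) x * HARTREE_TO_EV

#' @rdname hartree_to_ev
#' @export
ev_to_hartree <- function(x) x / HARTREE_TO_EV

#' @rdname hartree_to_ev
#' @export
hartree_to_kcal <- function(x) x * HARTREE_TO_KCAL

#' @rdname hartree_to_ev
#' @export
kcal_to_hartree <- function(x) x / HARTREE_TO_KCAL
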