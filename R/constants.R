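## Unit system: kJ/mol, nm, ps, amu, e, K.
## In these units 1 amu nm^2 ps^-2 == 1 kJ/mol, so Newton's equations need no
## conversion factor anywhere in the integrator.

.kB <- 0.0083144621          # kJ mol^-1 K^-1
.fCoulomb <- 138.935458      # kJ mol^-1 nm e^-2

#' Physical constants of the engine's unit system
#'
#' The engine works in the standard molecular-dynamics unit system
#' (kJ/mol, nm, ps, amu, e, K). `boltzmannConstant()` returns k_B in
#' kJ/(mol K); `coulombConstant()` returns the electric conversion factor
#' f = 1/(4 pi eps0) in kJ mol^-1 nm e^-2.
#'
#' @return A single numeric value.
#' @examples
#' ## free energy of one pH unit at 300 K, kJ/mol
#' log(10) * boltzmannConstant() * 300
#' @export
boltzmannConstant <- function() .kB

#' @rdname boltzmannConstant
#' @export
coulombConstant <- function() .fCoulomb
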