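# CODATA 2018 exact values; F and R are derived from e, kB and Avogadro so the
# set is internally consistent (F = e*NA, R = kB*NA).
.const <- local({
  kB <- 1.380649e-23
  NAv <- 6.02214076e23
  e <- 1.602176634e-19
  list(
    kB = kB,                      # Boltzmann constant, J/K
    Nav = NAv,                    # Avogadro number, 1/mol
    e = e,                        # elementary charge, C
    F = e * NAv,                  # Faraday constant, C/mol
    R = kB * NAv,                 # gas constant, J/mol/K
    eps0 = 8.8541878128e-12       # vacuum permittivity, F/m
  )
})

#' Physical constants used throughout the transport model
#'
#' Returns the internally consistent constant set (SI units): Faraday constant
#' `F` (C/mol), gas constant `R` (J/mol/K), Boltzmann constant `kB` (J/K),
#' elementary charge `e` (C), Avogadro number `Nav` (1/mol) and vacuum
#' permittivity `eps0` (F/m). `F = e * Nav` and `R = kB * Nav` hold exactly.
#'
#' @return Named list of constants.
#' @examples
#' physical_constants()$F
#' @export
physical_constants <- function() .const

# default water viscosity at 25 C, Pa s (configurable in every caller)
.default_mu <- 0.89e-3
# default bulk dielectric constant of water at 25 C
.default_eps_b <- 78.4
# default temperature, K
.default_T <- 298.15
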