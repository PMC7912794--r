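#' Stokes-Einstein radius from diffusivity
#'
#' `r = kB*T / (6*pi*mu*D)`. The inverse, [diffusivity_from_radius()], allows
#' exact round-tripping.
#'
#' @param D_inf Diffusivity at infinite dilution, m^2/s.
#' @param T Temperature, K.
#' @param mu Dynamic viscosity, Pa s (default: water at 25 C).
#' @return Radius in m.
#' @examples
#' stokes_einstein_radius(6.14e-10) * 1e9  # sulfadiazine, ~0.40 nm
#' @export
stokes_einstein_radius <- function(D_inf, T = .default_T, mu = .default_mu) {
  if (any(D_inf <= 0) || T <= 0 || mu <= 0)
    stop("'D_inf', 'T' and 'mu' must all be positive", call. = FALSE)
  .const$kB * T / (6 * pi * mu * D_inf)
}

#' @rdname stokes_einstein_radius
#' @param radius Hydrodynamic radius, m.
#' @export
diffusivity_from_radius <- function(radius, T = .default_T, mu = .default_mu) {
  if (any(radius <= 0) || T <= 0 || mu <= 0)
    stop("'radius', 'T' and 'mu' must all be positive", call. = FALSE)
  .const$kB * T / (6 * pi * mu * radius)
}

#' Speciation of a diprotic amphoteric solute
#'
#' Henderson-Hasselbalch fractions of the cationic (fully protonated), neutral
#' and anionic (fully deprotonated) forms of an amphoteric solute such as
#' sulfadiazine (pKa 2.00 / 6.50). At pH 7 the mono-anion dominates (~76%),
#' which is why the transport model treats SDZ as a single z = -1 species.
#'
#' @param pH pH value(s).
#' @param pKa1,pKa2 Acid dissociation constants, `pKa1 < pKa2`.
#' @return Matrix with columns `cationic`, `neutral`, `anionic`; rows sum to 1.
#' @examples
#' charge_fractions(7, 2.00, 6.50)
#' @export
charge_fractions <- function(pH, pKa1, pKa2) {
  if (pKa1 >= pKa2) stop("'pKa1' must be smaller than 'pKa2'", call. = FALSE)
  h <- 10^(-pH)
  K1 <- 10^(-pKa1); K2 <- 10^(-pKa2)
  denom <- h^2 + h * K1 + K1 * K2
  out <- cbind(cationic = h^2 / denom,
               neutral = h * K1 / denom,
               anionic = K1 * K2 / denom)
  rownames(out) <- NULL
  out
}

#' Surface charge density from zeta potential (Gouy-Chapman)
#'
#' `|sigma| = sqrt(2*eps0*eps_b*R*T * sum_i c_i [exp(-z_i F zeta / (R T)) - 1])`
#' with `sign(sigma) = sign(zeta)`: a negatively charged surface has a negative
#' zeta potential. Charge regulation is not modelled, so the result is an
#' upper estimate of the true pore surface charge.
#'
#' @param zeta Zeta potential, V.
#' @param solution A [solution_state()] giving the electrolyte in which zeta
#'   was measured (electroneutral).
#' @return Surface charge density, C/m^2.
#' @examples
#' kcl <- solution_state(
#'   list(species("K+", 1, 1.96e-9), species("Cl-", -1, 2.03e-9)), c(1, 1))
#' gouy_chapman_sigma(-25.69e-3, kcl) * 1e3  # ~-1.93 mC/m^2
#' @export
gouy_chapman_sigma <- function(zeta, solution) {
  stopifnot(inherits(solution, "sede_solution"))
  Fc <- .const$F; R <- .const$R
  T <- solution$T
  z <- vapply(solution$species, `[[`, numeric(1), "z")
  s <- vapply(zeta, function(zv)
    sum(solution$conc * (exp(-z * Fc * zv / (R * T)) - 1)), numeric(1))
  # electroneutral input guarantees s >= 0; guard against rounding
  s <- pmax(s, 0)
  sign(zeta) * sqrt(2 * .const$eps0 * solution$eps_b * R * T * s)
}

#' Volumetric fixed charge from surface charge density
#'
#' For a cylindrical pore of radius `r_p`, the wall charge spread over the
#' pore volume gives `CLoc = 2*sigma / (F * r_p)` in mol/m^3.
#'
#' @param sigma Surface charge density, C/m^2.
#' @param r_p Pore radius, m.
#' @return Equivalent volumetric fixed charge, mol/m^3.
#' @examples
#' sigma_to_cloc(-1.93e-3, 0.35e-9)  # ~ -114 mol/m^3
#' @export
sigma_to_cloc <- function(sigma, r_p) {
  if (any(r_p <= 0)) stop("'r_p' must be positive", call. = FALSE)
  2 * sigma / (.const$F * r_p)
}

#' Born solvation energy penalty of pore entry
#'
#' Dimensionless (units of kB*T) solvation-energy change for moving an ion of
#' valence `z` and cavity radius `r_cav` from a bulk of dielectric constant
#' `eps_b` into pore solution of dielectric constant `eps_p`:
#' `DW = (z*e)^2 / (8*pi*eps0*kB*T*r_cav) * (1/eps_p - 1/eps_b)`.
#' Zero for neutral solutes; positive (exclusion) whenever `eps_p < eps_b`.
#'
#' @param sp A [species()].
#' @param eps_p Pore dielectric constant.
#' @param eps_b Bulk dielectric constant.
#' @param T Temperature, K.
#' @return Energy in units of kB*T.
#' @examples
#' born_energy(species("SDZ", -1, 6.14e-10), eps_p = 33.4)  # ~1.20 kT
#' @export
born_energy <- function(sp, eps_p, eps_b = .default_eps_b, T = .default_T) {
  stopifnot(inherits(sp, "sede_species"))
  if (eps_p <= 1 || eps_b <= 1) stop("dielectric constants must exceed 1", call. = FALSE)
  (sp$z * .const$e)^2 / (8 * pi * .const$eps0 * .const$kB * T * sp$r_cav) *
    (1 / eps_p - 1 / eps_b)
}

#' Steric partitioning coefficient
#'
#' Ferry partitioning `phi = (1 - lambda)^2` for a spherical solute on the
#' pore centerline, with `lambda = r_stokes/r_p`. Values of `lambda >= 1`
#' (solute nominally larger than the pore) must be capped with [cap_lambda()]
#' before use; Ferry's expression is strictly only valid below 1.
#'
#' @param lambda_ Solute-to-pore size ratio (>= 0, < 1).
#' @return phi in (0, 1].
#' @examples
#' steric_partition(0.5)  # 0.25
#' @export
steric_partition <- function(lambda_) {
  if (any(lambda_ < 0)) stop("'lambda_' must be non-negative", call. = FALSE)
  if (any(lambda_ >= 1))
    stop("'lambda_' >= 1: cap with cap_lambda() before computing phi", call. = FALSE)
  (1 - lambda_)^2
}

#' Cap the solute-to-pore size ratio
#'
#' The model is applied to solutes whose Stokes radius can exceed the mean
#' pore radius (SDZ in NF90/VNF2-8040 pores), where the Ferry/hindrance
#' expressions are undefined. A configurable cap `lambda_eff = min(lambda,
#' lambda_max)` keeps the steric machinery finite; a warning is emitted
#' whenever capping occurs, since rejections computed in that regime inherit
#' the approximation.
#'
#' @param lambda_ Size ratio(s), >= 0.
#' @param lambda_max Cap, default 0.95.
#' @param warn Emit a warning when capping occurs (default TRUE).
#' @return Capped ratio(s).
#' @examples
#' cap_lambda(1.18)
#' @export
cap_lambda <- function(lambda_, lambda_max = 0.95, warn = TRUE) {
  if (any(lambda_ < 0)) stop("'lambda_' must be non-negative", call. = FALSE)
  capped <- lambda_ > lambda_max
  if (any(capped) && warn)
    warning(sprintf("%d lambda value(s) capped at %.2f (solute about as large as the pore)",
                    sum(capped), lambda_max), call. = FALSE)
  pmin(lambda_, lambda_max)
}
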