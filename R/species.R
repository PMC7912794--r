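#' Define a solute species
#'
#' A species record carries everything the partitioning and transport code
#' needs: valence, diffusivity at infinite dilution, Stokes radius (steric
#' size) and Born cavity radius (dielectric size). If `r_stokes` is omitted it
#' is computed from `D_inf` by the Stokes-Einstein relation at 25 C; if
#' `r_cav` is omitted it defaults to `r_stokes`.
#'
#' @param name Label.
#' @param z Integer valence (may be 0 for neutral tracers).
#' @param D_inf Diffusivity at infinite dilution, m^2/s.
#' @param r_stokes Stokes radius, m. Default: Stokes-Einstein from `D_inf`.
#' @param r_cav Born cavity radius, m. Default: `r_stokes`.
#' @param pKa1,pKa2 Optional acid dissociation constants (pKa1 < pKa2) for
#'   amphoteric solutes; used for speciation reporting only.
#' @return Object of class `sede_species`.
#' @examples
#' sdz <- species("SDZ", z = -1, D_inf = 6.14e-10, pKa1 = 2.00, pKa2 = 6.50)
#' sdz$r_stokes  # ~0.40 nm
#' @export
species <- function(name, z, D_inf, r_stokes = NULL, r_cav = NULL,
                    pKa1 = NA_real_, pKa2 = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(z) || length(z) != 1L || z != round(z))
    stop("species valence 'z' must be a single integer", call. = FALSE)
  if (!is.numeric(D_inf) || D_inf <= 0)
    stop("'D_inf' must be a positive diffusivity (m^2/s)", call. = FALSE)
  if (is.null(r_stokes)) r_stokes <- stokes_einstein_radius(D_inf)
  if (r_stokes <= 0) stop("'r_stokes' must be positive", call. = FALSE)
  if (is.null(r_cav)) r_cav <- r_stokes
  if (r_cav <= 0) stop("'r_cav' must be positive", call. = FALSE)
  if (!is.na(pKa1) && !is.na(pKa2) && pKa1 >= pKa2)
    stop("'pKa1' must be smaller than 'pKa2'", call. = FALSE)
  structure(
    list(name = name, z = as.integer(z), D_inf = D_inf,
         r_stokes = r_stokes, r_cav = r_cav, pKa1 = pKa1, pKa2 = pKa2),
    class = "sede_species")
}

#' @export
print.sede_species <- function(x, ...) {
  cat(sprintf("<species> %s  z=%+d  D=%.3g m2/s  r_stokes=%.3f nm  r_cav=%.3f nm\n",
              x$name, x$z, x$D_inf, x$r_stokes * 1e9, x$r_cav * 1e9))
  invisible(x)
}

#' Describe the bulk solution on one side of the membrane
#'
#' Bundles the solute set with bulk concentrations, temperature and bulk
#' dielectric constant of one bulk phase. The composition must be electroneutral (the feed of a
#' filtration run always is; trace imbalances up to 1e-9 mol/m^3 of charge are
#' tolerated as rounding).
#'
#' @param species_list List of [species()] objects.
#' @param conc Numeric vector of bulk concentrations, mol/m^3, one per species
#'   (same order), all non-negative.
#' @param T Temperature, K.
#' @param eps_b Bulk dielectric constant (dimensionless, > 1).
#' @param pH Optional pH of the solution (reporting only).
#' @return Object of class `sede_solution`.
#' @examples
#' kcl <- solution_state(
#'   list(species("K+", 1, 1.96e-9), species("Cl-", -1, 2.03e-9)),
#'   conc = c(1, 1))
#' @export
solution_state <- function(species_list, conc, T = .default_T,
                           eps_b = .default_eps_b, pH = NA_real_) {
  if (!length(species_list) || !all(vapply(species_list, inherits, TRUE, "sede_species")))
    stop("'species_list' must be a non-empty list of species objects", call. = FALSE)
  if (length(conc) != length(species_list))
    stop("'conc' must have one entry per species", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (T <= 0) stop("temperature must be positive (K)", call. = FALSE)
  if (eps_b <= 1) stop("'eps_b' must exceed 1", call. = FALSE)
  z <- vapply(species_list, `[[`, numeric(1), "z")
  if (abs(sum(z * conc)) > 1e-9)
    stop("bulk composition is not electroneutral (|sum z_i c_i| > 1e-9 mol/m^3)",
         call. = FALSE)
  names(conc) <- vapply(species_list, `[[`, character(1), "name")
  structure(list(species = species_list, conc = conc, T = T,
                 eps_b = eps_b, pH = pH),
            class = "sede_solution")
}

#' @export
print.sede_solution <- function(x, ...) {
  cat(sprintf("<solution> T=%.2f K  eps_b=%.1f  %d species\n", x$T, x$eps_b,
              length(x$species)))
  print(round(x$conc, 6))
  invisible(x)
}

#' Built-in solute definitions
#'
#' Returns the solutes used in the bundled analyses: sulfadiazine (SDZ,
#' modelled as a single mono-anion at pH 7), its Na+ counterion, Cl-, and the
#' three neutral pore-sizing tracers (dioxane, erythritol, xylose) with their
#' tabulated diffusivities and Stokes radii. Tracer radii are taken as
#' authoritative inputs (they are not exactly Stokes-Einstein consistent with
#' the tabulated diffusivities).
#'
#' @return Named list of `sede_species`.
#' @examples
#' default_species()$sdz
#' @export
default_species <- function() {
  list(
    sdz = species("SDZ", z = -1, D_inf = 6.14e-10, pKa1 = 2.00, pKa2 = 6.50),
    na = species("Na+", z = 1, D_inf = 1.33e-9),
    cl = species("Cl-", z = -1, D_inf = 2.03e-9),
    dioxane = species("dioxane", z = 0, D_inf = 9.1e-10, r_stokes = 0.234e-9),
    erythritol = species("erythritol", z = 0, D_inf = 8.1e-10, r_stokes = 0.263e-9),
    xylose = species("xylose", z = 0, D_inf = 7.4e-10, r_stokes = 0.290e-9)
  )
}

#' Default sulfadiazine feed solution
#'
#' The filtration feed: SDZ- at `c_sdz_mg_L` mg/L (divided by the 250.28 g/mol
#' molar mass), Na+ to electroneutrality, and a NaCl background electrolyte.
#' The default background of 10 mol/m^3 (10 mM) represents the ionic strength
#' of the pH-adjusted feed; it is the package's study-condition choice (the
#' methods vignette discusses how the intrapore field responds to this level)
#' and is freely configurable.
#'
#' @param c_sdz_mg_L SDZ feed concentration in mg/L (default 1).
#' @param background_nacl NaCl background, mol/m^3 (default 10).
#' @param T Temperature, K.
#' @param eps_b Bulk dielectric constant.
#' @return A [solution_state()] with species SDZ, Na+, Cl-.
#' @examples
#' sdz_feed()
#' @export
sdz_feed <- function(c_sdz_mg_L = 1, background_nacl = 10,
                     T = .default_T, eps_b = .default_eps_b) {
  sp <- default_species()
  c_sdz <- c_sdz_mg_L / 250.28        # mg/L over g/mol -> mmol/L = mol/m^3
  solution_state(list(sp$sdz, sp$na, sp$cl),
                 conc = c(c_sdz, c_sdz + background_nacl, background_nacl),
                 T = T, eps_b = eps_b, pH = 7)
}
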