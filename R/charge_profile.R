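#' Bipolar axial fixed-charge profile
#'
#' Polyamide active layers carry deprotonated carboxyl groups on the outer
#' (feed) face and protonated amine groups on the inner (permeate) face, so
#' the volumetric fixed charge CLoc(x) runs from a negative entrance plateau
#' to a positive exit plateau along the normalized pore coordinate x in
#' [0, 1]. The profile family used here is a logistic smooth step rescaled so
#' the endpoint values are matched exactly:
#' `CLoc(x) = c_entrance + (c_exit - c_entrance) * S(x)` with
#' `S(x) = (L(x) - L(0))/(L(1) - L(0))`, `L(x) = 1/(1 + exp(-(x - x0)/w))`.
#' It is monotone non-decreasing with an analytic derivative; the degenerate
#' case `c_entrance == c_exit` is the homogeneous membrane.
#'
#' @param c_entrance Fixed charge at the pore entrance (x = 0), mol/m^3.
#' @param c_exit Fixed charge at the pore exit (x = 1), mol/m^3; must be
#'   >= `c_entrance`.
#' @param x0 Transition midpoint in (0, 1). Default 0.65 (transition in the
#'   back half of the pore).
#' @param w Transition width (> 0). Default 0.08.
#' @return Object of class `charge_profile`.
#' @examples
#' pr <- charge_profile(-50, 50, x0 = 0.5, w = 0.1)
#' eval_profile(pr, c(0, 0.5, 1))
#' @export
charge_profile <- function(c_entrance, c_exit, x0 = 0.65, w = 0.08) {
  if (!is.finite(c_entrance) || !is.finite(c_exit))
    stop("charge endpoints must be finite", call. = FALSE)
  if (c_exit < c_entrance)
    stop("'c_exit' must be >= 'c_entrance' (profile is non-decreasing)", call. = FALSE)
  if (x0 <= 0 || x0 >= 1) stop("'x0' must lie in (0, 1)", call. = FALSE)
  if (w <= 0) stop("'w' must be positive", call. = FALSE)
  structure(list(c_entrance = c_entrance, c_exit = c_exit, x0 = x0, w = w,
                 form = "logistic-step"),
            class = "charge_profile")
}

#' @export
print.charge_profile <- function(x, ...) {
  cat(sprintf("<charge_profile> %s: %.1f -> %.1f mol/m^3, x0=%.3f, w=%.3f (avg %.1f)\n",
              x$form, x$c_entrance, x$c_exit, x$x0, x$w, average_charge(x)))
  invisible(x)
}

# raw logistic and its endpoint normalization
.logi <- function(x, x0, w) 1 / (1 + exp(-(x - x0) / w))

#' Evaluate a fixed-charge profile
#'
#' @param profile A [charge_profile()].
#' @param x Normalized axial position(s) in `[0, 1]`.
#' @return CLoc(x), mol/m^3.
#' @export
eval_profile <- function(profile, x) {
  stopifnot(inherits(profile, "charge_profile"))
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]", call. = FALSE)
  span <- profile$c_exit - profile$c_entrance
  if (span == 0) return(rep(profile$c_entrance, length(x)))
  L0 <- .logi(0, profile$x0, profile$w)
  L1 <- .logi(1, profile$x0, profile$w)
  profile$c_entrance + span * (.logi(x, profile$x0, profile$w) - L0) / (L1 - L0)
}

#' Analytic derivative of a fixed-charge profile
#'
#' dCLoc/dx per unit normalized x; non-negative everywhere and integrating
#' to `c_exit - c_entrance` over `[0, 1]`. This is the inhomogeneous-charge
#' source term of the axial electric field.
#'
#' @inheritParams eval_profile
#' @return dCLoc/dx, mol/m^3 per unit x.
#' @export
profile_derivative <- function(profile, x) {
  stopifnot(inherits(profile, "charge_profile"))
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]", call. = FALSE)
  span <- profile$c_exit - profile$c_entrance
  if (span == 0) return(rep(0, length(x)))
  L0 <- .logi(0, profile$x0, profile$w)
  L1 <- .logi(1, profile$x0, profile$w)
  L <- .logi(x, profile$x0, profile$w)
  span * L * (1 - L) / (profile$w * (L1 - L0))
}

#' Average fixed charge of a profile
#'
#' `integral_0^1 CLoc(x) dx` by adaptive quadrature (relative tolerance
#' 1e-10). This is the quantity usually quoted as the membrane's mean
#' volumetric charge, e.g. -25.8 mmol/L for NF90.
#'
#' @inheritParams eval_profile
#' @return Average charge, mol/m^3.
#' @export
average_charge <- function(profile) {
  stopifnot(inherits(profile, "charge_profile"))
  stats::integrate(function(x) eval_profile(profile, x), 0, 1,
                   rel.tol = 1e-10, abs.tol = 1e-10,
                   subdivisions = 400L)$value
}

#' Calibrate a bipolar profile from zeta potentials
#'
#' Converts the strong-base zeta potential (deprotonated carboxyls, outer/
#' entrance face) into the negative entrance charge and the strong-acid zeta
#' potential (protonated amines, inner/exit face) into the positive exit
#' charge, via [gouy_chapman_sigma()] and [sigma_to_cloc()]. If a target
#' average charge is supplied, the transition midpoint `x0` is fitted (at
#' fixed width `w`) so [average_charge()] reproduces it; otherwise the
#' defaults `x0 = 0.65`, `w = 0.08` are used.
#'
#' @param zeta_acid Zeta potential under strong acid conditions (V, > 0).
#' @param zeta_base Zeta potential under strong base conditions (V, < 0).
#' @param rp Pore radius, m.
#' @param solution [solution_state()] of the electrolyte used for the zeta
#'   measurements.
#' @param target_average Optional target average charge, mol/m^3; must lie
#'   strictly between the entrance and exit charges.
#' @param x0,w Profile shape parameters (x0 ignored when a target is given).
#' @return A [charge_profile()].
#' @examples
#' kcl <- solution_state(
#'   list(species("K+", 1, 1.96e-9), species("Cl-", -1, 2.03e-9)), c(1, 1))
#' calibrate_profile(20e-3, -20e-3, 0.4e-9, kcl)
#' @export
calibrate_profile <- function(zeta_acid, zeta_base, rp, solution,
                              target_average = NULL, x0 = 0.65, w = 0.08) {
  if (!(zeta_base < 0 && zeta_acid > 0))
    stop("amphoteric membrane expected: 'zeta_base' < 0 < 'zeta_acid'", call. = FALSE)
  c_ent <- sigma_to_cloc(gouy_chapman_sigma(zeta_base, solution), rp)
  c_exit <- sigma_to_cloc(gouy_chapman_sigma(zeta_acid, solution), rp)
  if (is.null(target_average))
    return(charge_profile(c_ent, c_exit, x0 = x0, w = w))
  lo <- 1e-3; hi <- 1 - 1e-3
  avg_at <- function(x0v) average_charge(charge_profile(c_ent, c_exit, x0v, w))
  # average is monotone decreasing in x0 (more of the pore at entrance charge)
  a_hi <- avg_at(lo); a_lo <- avg_at(hi)
  if (target_average >= a_hi || target_average <= a_lo)
    stop(sprintf(
      "target average %.3g mol/m^3 infeasible for endpoint charges [%.3g, %.3g]",
      target_average, c_ent, c_exit), call. = FALSE)
  root <- stats::uniroot(function(x0v) avg_at(x0v) - target_average,
                         c(lo, hi), tol = 1e-12)$root
  charge_profile(c_ent, c_exit, x0 = root, w = w)
}
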