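#' Bungay-Brenner centerline series coefficients
#'
#' The two seven-coefficient sets of the Bungay-Brenner centerline
#' approximation for a sphere in a cylindrical pore: `a` enters `Kt` (the
#' resistance underlying the diffusive hindrance) and `b` enters `Ks` (the
#' convective counterpart). Exposed so an independent term-by-term summation
#' can cross-check the packaged implementation.
#'
#' @return List with numeric vectors `a` and `b` (length 7 each).
#' @examples
#' bb_coefficients()$a[1]  # -73/60
#' @export
bb_coefficients <- function() {
  list(
    a = c(-73 / 60, 77293 / 50400, -22.5083, -5.6117, -0.3363, -1.216, 1.647),
    b = c(7 / 60, -2227 / 50400, 4.0180, -3.9788, -1.9215, 4.392, 5.006)
  )
}

#' Hydrodynamic hindrance factors (Bungay-Brenner)
#'
#' Centerline hindrance factors for diffusion (`Kd`) and convection (`Kc`) of
#' a spherical solute in a cylindrical pore, valid over the whole ratio range
#' `0 <= lambda < 1`:
#' \deqn{K_t, K_s = \tfrac94 \pi^2 \sqrt2 (1-\lambda)^{-5/2}
#'   [1 + c_1 (1-\lambda) + c_2 (1-\lambda)^2] + \sum_{n=0}^{4} c_{n+3} \lambda^n}
#' with `Kd = 6*pi/Kt`, `Kc = (2 - phi)*Ks/(2*Kt)` and `phi = (1-lambda)^2`.
#'
#' @param lambda_ Solute-to-pore size ratio(s) in `[0, 1)`; callers must cap
#'   ratios >= 1 first (see [cap_lambda()]).
#' @return Data frame with columns `lambda`, `phi`, `Kd`, `Kc` (class
#'   `hindrance_factors`).
#' @examples
#' bungay_brenner(c(0, 0.5))
#' @export
bungay_brenner <- function(lambda_) {
  if (any(lambda_ < 0)) stop("'lambda_' must be non-negative", call. = FALSE)
  if (any(lambda_ >= 1))
    stop("'lambda_' must be < 1 (cap with cap_lambda() first)", call. = FALSE)
  cf <- bb_coefficients()
  u <- 1 - lambda_
  pre <- 9 / 4 * pi^2 * sqrt(2) * u^(-2.5)
  poly <- function(co) co[3] + co[4] * lambda_ + co[5] * lambda_^2 +
    co[6] * lambda_^3 + co[7] * lambda_^4
  Kt <- pre * (1 + cf$a[1] * u + cf$a[2] * u^2) + poly(cf$a)
  Ks <- pre * (1 + cf$b[1] * u + cf$b[2] * u^2) + poly(cf$b)
  phi <- u^2
  out <- data.frame(lambda = lambda_, phi = phi,
                    Kd = 6 * pi / Kt, Kc = (2 - phi) * Ks / (2 * Kt))
  class(out) <- c("hindrance_factors", class(out))
  out
}

#' Limiting rejection of a neutral solute
#'
#' The infinite-Peclet rejection plateau `R_inf = 1 - phi*Kc`, strictly
#' increasing in lambda. This is the quantity inverted during pore-size
#' characterization.
#'
#' @inheritParams bungay_brenner
#' @return `R_inf` in `[0, 1)`.
#' @examples
#' neutral_limiting_rejection(0.5)  # ~0.633
#' @export
neutral_limiting_rejection <- function(lambda_) {
  h <- bungay_brenner(lambda_)
  1 - h$phi * h$Kc
}

#' Closed-form rejection curve of a neutral solute
#'
#' Hindered-transport rejection of an uncharged solute at finite Peclet
#' number: `R = 1 - phi*Kc / (1 - (1 - phi*Kc) * exp(-Pe))` with
#' `Pe = Kc*Jv*dx_eff/(Kd*D)`. Serves both as the characterization model for
#' tracer data and as an exact oracle for the full transport solver run with
#' z = 0 and no fixed charge.
#'
#' @inheritParams bungay_brenner
#' @param peclet Peclet number(s), >= 0.
#' @return Rejection in `[0, 1)`.
#' @examples
#' neutral_rejection_curve(0.5, peclet = c(0, 1, 100))
#' @export
neutral_rejection_curve <- function(lambda_, peclet) {
  if (any(peclet < 0)) stop("'peclet' must be non-negative", call. = FALSE)
  h <- bungay_brenner(lambda_)
  pk <- h$phi * h$Kc
  1 - pk / (1 - (1 - pk) * exp(-peclet))
}

#' Peclet number inside the pore
#'
#' `Pe = Kc * Jv * dx_eff / (Kd * D_inf)`, the ratio of hindered convection to
#' hindered diffusion over the effective active-layer thickness.
#'
#' @inheritParams bungay_brenner
#' @param Jv Volume flux, m/s.
#' @param dx_eff Effective active-layer thickness Delta_w/Ak, m.
#' @param D_inf Solute diffusivity, m^2/s.
#' @return Peclet number(s).
#' @export
peclet_number <- function(lambda_, Jv, dx_eff, D_inf) {
  h <- bungay_brenner(lambda_)
  h$Kc * Jv * dx_eff / (h$Kd * D_inf)
}

#' Tabulate hindrance factors
#'
#' Convenience table of `lambda, phi, Kd, Kc, R_inf` over a lambda grid,
#' suitable for CSV export.
#'
#' @param lambda_ Grid of size ratios in `[0, 1)`; default 0 to 0.95.
#' @return Data frame.
#' @examples
#' head(hindrance_table())
#' @export
hindrance_table <- function(lambda_ = seq(0, 0.95, by = 0.05)) {
  h <- bungay_brenner(lambda_)
  h$R_inf <- 1 - h$phi * h$Kc
  as.data.frame(h)
}
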