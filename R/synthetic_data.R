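# Seeded generators for every input the pipeline consumes: neutral-tracer
# rejection curves, zeta-pH curves, and noisy rejection-vs-pressure datasets
# produced by the forward SEDE model. All generators are pure functions of
# (spec, seed): identical calls give identical tables.

#' Specification of a synthetic study
#'
#' Ground-truth parameters for the generators. Defaults emulate the bundled
#' study conditions: a membrane of pore radius 0.40 nm, effective thickness
#' 10 um, the three neutral tracers, a log-spaced flux grid spanning Peclet
#' numbers ~0.1-20 for the middle tracer, multiplicative lognormal noise of
#' sigma = 0.02 on the rejection complement, and a sigmoidal zeta-pH curve
#' crossing zero at the isoelectric point.
#'
#' @param seed Integer seed fixing all randomness.
#' @param rp_truth True pore radius, m.
#' @param dx_eff_truth True effective thickness, m.
#' @param eps_p_truth True pore dielectric constant.
#' @param profile_truth True [charge_profile()] (for rejection datasets).
#' @param tracers List of neutral [species()] (default: bundled tracers).
#' @param n_flux Number of flux-grid points.
#' @param sigma Noise sigma on the rejection complement (lognormal).
#' @param zeta_truth List with `iep`, `zeta_acid`, `zeta_base` (V), `slope`
#'   (pH units) and `sigma_zeta` (V).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, rp_truth = 0.40e-9, dx_eff_truth = 1e-5,
                           eps_p_truth = 34, profile_truth = NULL,
                           tracers = NULL, n_flux = 8L, sigma = 0.02,
                           zeta_truth = list(iep = 4.25, zeta_acid = 18e-3,
                                             zeta_base = -15e-3, slope = 0.8,
                                             sigma_zeta = 1e-3)) {
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (is.null(tracers)) {
    sp <- default_species()
    tracers <- list(sp$dioxane, sp$erythritol, sp$xylose)
  }
  if (is.null(profile_truth))
    profile_truth <- charge_profile(-50, 60, x0 = 0.7, w = 0.08)
  structure(list(seed = as.integer(seed), rp_truth = rp_truth,
                 dx_eff_truth = dx_eff_truth, eps_p_truth = eps_p_truth,
                 profile_truth = profile_truth, tracers = tracers,
                 n_flux = as.integer(n_flux), sigma = sigma,
                 zeta_truth = zeta_truth),
            class = "synthetic_spec")
}

# flux grid spanning Pe ~ 0.1..20 for the middle tracer
.flux_grid <- function(spec) {
  tr <- spec$tracers[[ceiling(length(spec$tracers) / 2)]]
  lam <- cap_lambda(tr$r_stokes / spec$rp_truth, warn = FALSE)
  h <- bungay_brenner(lam)
  per_jv <- h$Kc * spec$dx_eff_truth / (h$Kd * tr$D_inf)
  10^seq(log10(0.1 / per_jv), log10(20 / per_jv), length.out = spec$n_flux)
}

#' Generate noisy neutral-tracer rejection curves
#'
#' Forward curves follow the closed-form hindered-transport law with
#' `Pe = Kc*Jv*dx_eff/(Kd*D)`; noise multiplies the rejection complement,
#' `1 - R' = (1 - R)*exp(N(0, sigma^2))`, keeping rejections in `[0, 1)`
#' (clipped to `[0, 0.999]`).
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame: `tracer`, `rs_nm`, `flux_m_per_s`, `rejection`,
#'   `rejection_true`.
#' @examples
#' head(gen_tracer_rejections(synthetic_spec(seed = 1)))
#' @export
gen_tracer_rejections <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  Jv <- .flux_grid(spec)
  set.seed(spec$seed)
  out <- do.call(rbind, lapply(spec$tracers, function(tr) {
    lam <- tr$r_stokes / spec$rp_truth
    if (lam >= 1) stop(sprintf("tracer %s larger than the pore", tr$name),
                       call. = FALSE)
    h <- bungay_brenner(lam)
    pe <- h$Kc * Jv * spec$dx_eff_truth / (h$Kd * tr$D_inf)
    R <- neutral_rejection_curve(lam, pe)
    Rn <- 1 - (1 - R) * exp(stats::rnorm(length(R), 0, spec$sigma))
    data.frame(tracer = tr$name, rs_nm = tr$r_stokes * 1e9,
               flux_m_per_s = Jv, rejection = pmin(pmax(Rn, 0), 0.999),
               rejection_true = R)
  }))
  rownames(out) <- NULL
  out
}

#' Recover the pore radius from tracer rejection curves
#'
#' Fits each tracer's curve with [limiting_rejection_from_curve()], converts
#' the fitted lambdas to radii and averages.
#'
#' @param obs Output of [gen_tracer_rejections()] (or measured data with the
#'   same columns).
#' @return List with `rp` (m), `per_tracer_rp` (m) and `per_tracer_lambda`.
#' @export
recover_pore_radius <- function(obs) {
  keys <- unique(obs[c("tracer", "rs_nm")])
  lam <- vapply(seq_len(nrow(keys)), function(i) {
    d <- obs[obs$tracer == keys$tracer[i], ]
    limiting_rejection_from_curve(d$flux_m_per_s, d$rejection)$lambda
  }, numeric(1))
  rp_t <- keys$rs_nm * 1e-9 / lam
  list(rp = average_pore_radius(rp_t),
       per_tracer_rp = stats::setNames(rp_t, keys$tracer),
       per_tracer_lambda = stats::setNames(lam, keys$tracer))
}

#' Generate a noisy zeta-potential versus pH curve
#'
#' Logistic curve running from the strong-acid plateau to the strong-base
#' plateau, constructed to cross zero exactly at the true isoelectric point;
#' additive Gaussian noise.
#'
#' @param spec A [synthetic_spec()].
#' @param pH pH grid (default 2 to 9 in 0.5 steps).
#' @return Data frame: `pH`, `zeta_V`, `zeta_true_V`.
#' @export
gen_zeta_curve <- function(spec, pH = seq(2, 9, by = 0.5)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  zt <- spec$zeta_truth
  if (!(zt$zeta_base < 0 && zt$zeta_acid > 0))
    stop("'zeta_base' < 0 < 'zeta_acid' required", call. = FALSE)
  m <- zt$iep + zt$slope * log(-zt$zeta_base / zt$zeta_acid)
  L <- 1 / (1 + exp(-(pH - m) / zt$slope))
  z <- zt$zeta_acid + (zt$zeta_base - zt$zeta_acid) * L
  set.seed(spec$seed + 1L)
  data.frame(pH = pH, zeta_V = z + stats::rnorm(length(pH), 0, zt$sigma_zeta),
             zeta_true_V = z)
}

#' Fit the isoelectric point of a zeta-pH curve
#'
#' Four-parameter logistic fit (acid plateau, base plateau, midpoint, slope);
#' the IEP is the fitted zero crossing.
#'
#' @param curve Data frame with columns `pH`, `zeta_V`.
#' @return List with `iep` and the fitted parameters.
#' @export
fit_iep <- function(curve) {
  d <- data.frame(pH = curve$pH, z = curve$zeta_V)
  start <- list(za = max(d$z), zb = min(d$z),
                m = stats::median(d$pH), s = 1)
  fit <- minpack.lm::nlsLM(
    z ~ za + (zb - za) / (1 + exp(-(pH - m) / s)),
    data = d, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- as.list(stats::coef(fit))
  if (!(p$zb < 0 && p$za > 0))
    stop("fitted curve does not cross zero; no isoelectric point", call. = FALSE)
  # zero crossing: za + (zb - za)*L = 0  =>  L = za/(za - zb)
  iep <- p$m - p$s * log(-p$zb / p$za)
  list(iep = iep, pars = p)
}

#' Generate a noisy rejection-versus-pressure dataset
#'
#' Runs the forward SEDE solver over a pressure grid and adds multiplicative
#' lognormal noise on the rejection complement. The ground-truth membrane is
#' returned alongside so recovery studies can compare fitted parameters to
#' truth.
#'
#' @param spec A [synthetic_spec()].
#' @param pressures Pressure grid, Pa (default 9 points over 0.4-2.0 MPa).
#' @param feed Feed solution (default [sdz_feed()]).
#' @param solute Name of the reported solute (default "SDZ").
#' @return List with `data` (data frame `dP_MPa`, `Jv_m_s`, `rejection`,
#'   `rejection_true`) and `membrane_truth`.
#' @export
gen_rejection_dataset <- function(spec, pressures = seq(0.4e6, 2e6, length.out = 9),
                                  feed = sdz_feed(), solute = "SDZ") {
  stopifnot(inherits(spec, "synthetic_spec"))
  mem <- membrane(spec$rp_truth, spec$dx_eff_truth, spec$eps_p_truth,
                  spec$profile_truth, name = "synthetic-truth")
  curve <- rejection_vs_pressure(mem, pressures, feed = feed,
                                 control = sede_control(warn_cap = FALSE))
  R <- curve[[paste0("R_", solute)]]
  set.seed(spec$seed + 2L)
  Rn <- 1 - (1 - R) * exp(stats::rnorm(length(R), 0, spec$sigma))
  list(data = data.frame(dP_MPa = curve$dP_MPa, Jv_m_s = curve$Jv_m_s,
                         rejection = pmin(pmax(Rn, 0), 1),
                         rejection_true = R),
       membrane_truth = mem)
}

#' Fit the entrance-charge amplitude from a rejection curve
#'
#' One-dimensional recovery of the entrance fixed charge: the membrane's
#' entrance charge is scaled by a factor alpha (exit charge, transition
#' position and width held at their known values) and alpha is chosen to
#' minimize the squared residuals of `log(1 - R)` (the natural scale for
#' multiplicative noise on the rejection complement).
#'
#' @param data Data frame with `Jv_m_s` and `rejection`.
#' @param membrane_ref Reference [membrane()] whose entrance charge is scaled.
#' @param feed Feed solution.
#' @param interval Search interval for alpha.
#' @return List with `alpha`, `c_entrance` (fitted, mol/m^3) and `objective`.
#' @export
fit_charge_amplitude <- function(data, membrane_ref, feed = sdz_feed(),
                                 interval = c(0.3, 3)) {
  pr <- membrane_ref$profile
  ctl <- sede_control(warn_cap = FALSE, n_grid = 101L)
  sse <- function(alpha) {
    prof <- charge_profile(alpha * pr$c_entrance, pr$c_exit, pr$x0, pr$w)
    mem <- membrane(membrane_ref$rp, membrane_ref$dx_eff, membrane_ref$eps_p,
                    prof, name = membrane_ref$name)
    cp <- NULL
    rs <- vapply(data$Jv_m_s, function(jv) {
      sol <- solve_transport(mem, operating_point(feed, Jv = jv),
                             control = ctl, cp_init = cp)
      cp <<- sol$permeate
      sol$rejection[["SDZ"]]
    }, numeric(1))
    sum((log1p(-rs) - log1p(-data$rejection))^2)
  }
  opt <- stats::optimize(sse, interval = interval, tol = 1e-3)
  list(alpha = opt$minimum,
       c_entrance = opt$minimum * pr$c_entrance,
       objective = opt$objective)
}
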