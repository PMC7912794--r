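#' Estimate the limiting rejection of a neutral tracer
#'
#' Two strategies for extracting the infinite-flux rejection plateau from an
#' observed rejection-versus-flux curve:
#' \describe{
#'   \item{`"fit"` (default)}{Two-parameter least-squares fit of the closed
#'     form [neutral_rejection_curve()] with free `lambda` and a free
#'     Peclet-per-flux proportionality `beta` (`Pe = beta * Jv`); returns the
#'     fitted plateau `1 - phi*Kc`.}
#'   \item{`"plateau"`}{Mean of the rejections at the two highest fluxes.}
#' }
#'
#' @param fluxes Strictly increasing volume fluxes, m/s (>= 4 points spanning
#'   at least a 5x range for the fit).
#' @param rejections Observed rejections in `[0, 1)`, same length.
#' @param method `"fit"` or `"plateau"`.
#' @return List with `R_inf`, `lambda` (NA for plateau method) and `beta`.
#' @examples
#' Jv <- 10^seq(-6, -4.5, length.out = 8)
#' R <- neutral_rejection_curve(0.5, 5e4 * Jv)
#' limiting_rejection_from_curve(Jv, R)$R_inf  # ~0.633
#' @export
limiting_rejection_from_curve <- function(fluxes, rejections,
                                          method = c("fit", "plateau")) {
  method <- match.arg(method)
  n <- length(fluxes)
  if (length(rejections) != n) stop("length mismatch", call. = FALSE)
  if (is.unsorted(fluxes, strictly = TRUE))
    stop("'fluxes' must be strictly increasing", call. = FALSE)
  if (any(rejections < 0 | rejections >= 1))
    stop("rejections must lie in [0, 1)", call. = FALSE)
  if (method == "plateau") {
    top <- utils::tail(order(fluxes), 2)
    return(list(R_inf = mean(rejections[top]), lambda = NA_real_, beta = NA_real_))
  }
  if (n < 4 || max(fluxes) / min(fluxes) < 5)
    stop("curve fit needs >= 4 flux points spanning at least a 5x range", call. = FALSE)
  drops <- diff(rejections) < -0.05
  if (any(drops))
    warning("rejections decrease with flux beyond noise tolerance; fit may be unreliable",
            call. = FALSE)
  # work on transformed parameters so the optimizer stays in bounds:
  # lambda = 0.95 * plogis(p1), beta = exp(p2)
  rinf0 <- max(rejections)
  lam0 <- tryCatch(invert_lambda(min(rinf0, 0.93), warn = FALSE), error = function(e) 0.5)
  start <- c(stats::qlogis(max(min(lam0 / 0.95, 0.99), 0.01)),
             log(2 / stats::median(fluxes)))
  obj <- function(p) {
    lam <- 0.95 * stats::plogis(p[1]); beta <- exp(p[2])
    rejections - neutral_rejection_curve(lam, beta * fluxes)
  }
  fit <- minpack.lm::nls.lm(par = start, fn = obj,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 9))
    stop("limiting-rejection fit failed to converge", call. = FALSE)
  lam <- 0.95 * stats::plogis(fit$par[1])
  list(R_inf = neutral_limiting_rejection(lam), lambda = lam,
       beta = exp(fit$par[2]))
}

#' Invert the limiting-rejection law for lambda
#'
#' Finds the unique `lambda` in `[0, lambda_max]` with
#' `neutral_limiting_rejection(lambda) == R_inf` by bracketed root search
#' (the law is strictly increasing). Plateaus above the attainable range are
#' capped at `lambda_max` with a warning.
#'
#' @param R_inf Limiting rejection in `[0, 1)`.
#' @param lambda_max Upper bound of the search, default 0.95.
#' @param warn Warn when capping occurs.
#' @return lambda.
#' @examples
#' invert_lambda(neutral_limiting_rejection(0.691))  # 0.691
#' @export
invert_lambda <- function(R_inf, lambda_max = 0.95, warn = TRUE) {
  if (R_inf < 0 || R_inf >= 1) stop("'R_inf' must lie in [0, 1)", call. = FALSE)
  if (R_inf == 0) return(0)
  top <- neutral_limiting_rejection(lambda_max)
  if (R_inf >= top) {
    if (warn)
      warning(sprintf("R_inf = %.4f exceeds the plateau attainable at lambda = %.2f; capped",
                      R_inf, lambda_max), call. = FALSE)
    return(lambda_max)
  }
  stats::uniroot(function(l) neutral_limiting_rejection(l) - R_inf,
                 c(0, lambda_max), tol = 1e-12)$root
}

#' Pore radius from a fitted size ratio
#'
#' `rp = r_stokes / lambda`.
#'
#' @param lambda_ Size ratio (> 0).
#' @param r_stokes Tracer Stokes radius, m.
#' @return Pore radius, m.
#' @examples
#' pore_radius_from_lambda(0.691, 0.234e-9) * 1e9  # 0.34 nm
#' @export
pore_radius_from_lambda <- function(lambda_, r_stokes) {
  if (any(lambda_ <= 0)) stop("'lambda_' must be positive (finite pore)", call. = FALSE)
  r_stokes / lambda_
}

#' Average pore radius over tracers
#'
#' Arithmetic mean of per-tracer pore radii. Radii are carried at full
#' precision; rounding to 2 decimals happens only in table output.
#'
#' @param radii Non-empty numeric vector of radii (any single unit).
#' @return Mean radius.
#' @export
average_pore_radius <- function(radii) {
  if (!length(radii)) stop("empty radius list", call. = FALSE)
  mean(radii)
}

#' Pore dielectric constants of the bundled membranes
#'
#' The per-membrane pore dielectric constants used by the transport model.
#' These are treated as tabulated membrane properties (the confined-water
#' dielectric constant cannot be measured directly and any printed
#' correlation with pore radius is unreliable); a user-supplied correlation
#' `eps_p(rp)` can replace the table.
#'
#' @return Named numeric vector.
#' @export
pore_dielectric_table <- function() {
  c("NF90" = 33.4, "NF270" = 35.7, "VNF2-8040" = 33.7, "TMN20H-400" = 36.4)
}

#' Assign the pore dielectric constant
#'
#' Default mode looks the membrane up in [pore_dielectric_table()] (or a
#' user-supplied table); correlation mode applies a user function of the pore
#' radius.
#'
#' @param membrane Membrane name (table mode) or NULL.
#' @param rp Pore radius, m (used by correlation mode).
#' @param table Named vector of per-membrane values.
#' @param correlation Optional function `eps_p(rp)`.
#' @return Pore dielectric constant.
#' @examples
#' assign_pore_dielectric("NF90")  # 33.4
#' @export
assign_pore_dielectric <- function(membrane = NULL, rp = NULL,
                                   table = pore_dielectric_table(),
                                   correlation = NULL) {
  if (!is.null(correlation)) {
    if (is.null(rp) || rp <= 0) stop("correlation mode needs a positive 'rp'", call. = FALSE)
    return(correlation(rp))
  }
  if (is.null(membrane) || !membrane %in% names(table))
    stop(sprintf("membrane '%s' not in the dielectric table and no correlation supplied",
                 if (is.null(membrane)) "<NULL>" else membrane), call. = FALSE)
  unname(table[membrane])
}

#' Tabulated per-tracer size ratios of the bundled membranes
#'
#' Fitted `lambda = rs/rp` for dioxane, erythritol and xylose on the four
#' characterized membranes. These values summarize the tracer-rejection
#' experiments; feeding them through `rp = rs/lambda` and averaging
#' reproduces the reported mean pore radii (0.34, 0.42, 0.35 and 0.44 nm).
#'
#' @return Data frame with columns `membrane`, `tracer`, `rs_nm`, `lambda`.
#' @export
tracer_lambda_table <- function() {
  rs <- c(dioxane = 0.234, erythritol = 0.263, xylose = 0.290)
  lam <- list(
    "NF90" = c(0.691, 0.790, 0.820),
    "NF270" = c(0.509, 0.584, 0.829),
    "VNF2-8040" = c(0.616, 0.731, 0.935),
    "TMN20H-400" = c(0.498, 0.598, 0.707)
  )
  do.call(rbind, lapply(names(lam), function(m)
    data.frame(membrane = m, tracer = names(rs), rs_nm = unname(rs),
               lambda = lam[[m]], row.names = NULL)))
}

#' Full pore characterization report
#'
#' Builds the characterization table for one or more membranes: per-tracer
#' size ratio, pore radius, membrane mean radius and pore dielectric
#' constant. Input is either a table of pre-fitted lambdas (default: the
#' bundled [tracer_lambda_table()]) or raw tracer rejection curves, which are
#' first reduced to lambdas with [limiting_rejection_from_curve()].
#'
#' @param lambdas Data frame with columns `membrane`, `tracer`, `rs_nm`,
#'   `lambda`.
#' @param eps_table Named vector of pore dielectric constants.
#' @return Data frame with columns `membrane`, `tracer`, `rs_nm`, `lambda`,
#'   `rp_nm`, `rp_mean_nm`, `eps_p`; radii at full precision.
#' @examples
#' characterize_pores()
#' @export
characterize_pores <- function(lambdas = tracer_lambda_table(),
                               eps_table = pore_dielectric_table()) {
  need <- c("membrane", "tracer", "rs_nm", "lambda")
  if (!all(need %in% names(lambdas)))
    stop("'lambdas' must have columns ", paste(need, collapse = ", "), call. = FALSE)
  lambdas$rp_nm <- pore_radius_from_lambda(lambdas$lambda, lambdas$rs_nm)
  means <- tapply(lambdas$rp_nm, lambdas$membrane, average_pore_radius)
  lambdas$rp_mean_nm <- as.numeric(means[lambdas$membrane])
  lambdas$eps_p <- vapply(lambdas$membrane, function(m)
    tryCatch(assign_pore_dielectric(m, table = eps_table),
             error = function(e) NA_real_), numeric(1))
  rownames(lambdas) <- NULL
  lambdas
}

#' Characterize pore size from raw tracer rejection curves
#'
#' Reduces a table of observed tracer rejection curves (one curve per
#' membrane x tracer) to per-tracer lambdas and pore radii.
#'
#' @param obs Data frame with columns `membrane`, `tracer`, `flux_m_per_s`,
#'   `rejection`, plus `rs_nm` giving each tracer's Stokes radius.
#' @param method Passed to [limiting_rejection_from_curve()].
#' @return Data frame as in [characterize_pores()].
#' @export
characterize_pores_from_curves <- function(obs, method = "fit") {
  need <- c("membrane", "tracer", "flux_m_per_s", "rejection", "rs_nm")
  if (!all(need %in% names(obs)))
    stop("'obs' must have columns ", paste(need, collapse = ", "), call. = FALSE)
  keys <- unique(obs[c("membrane", "tracer", "rs_nm")])
  keys$lambda <- mapply(function(m, t) {
    d <- obs[obs$membrane == m & obs$tracer == t, ]
    d <- d[order(d$flux_m_per_s), ]
    fit <- limiting_rejection_from_curve(d$flux_m_per_s, d$rejection, method = method)
    if (is.na(fit$lambda)) invert_lambda(fit$R_inf, warn = FALSE) else fit$lambda
  }, keys$membrane, keys$tracer)
  characterize_pores(keys[c("membrane", "tracer", "rs_nm", "lambda")])
}
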