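# Independent oracles, coded separately from the package implementation.

# term-by-term summation of the Bungay-Brenner centerline series using the
# exposed coefficient sets (deliberately different code path: explicit loops)
bb_oracle <- function(lam) {
  cf <- bb_coefficients()
  pre <- 2.25 * pi^2 * sqrt(2) * (1 - lam)^(-5 / 2)
  kt <- pre
  ks <- pre
  for (k in 1:2) {
    kt <- kt + pre * cf$a[k] * (1 - lam)^k
    ks <- ks + pre * cf$b[k] * (1 - lam)^k
  }
  for (k in 0:4) {
    kt <- kt + cf$a[k + 3] * lam^k
    ks <- ks + cf$b[k + 3] * lam^k
  }
  phi <- (1 - lam)^2
  list(Kd = 6 * pi / kt, Kc = (2 - phi) * ks / (2 * kt), phi = phi)
}

# ideal-Donnan partition of a 1:1 salt (feed c, fixed charge X < 0), no
# steric/Born factors: counterion*coion = c^2, counterion - coion = -X
donnan_quadratic <- function(c_salt, X) {
  coion <- (X + sqrt(X^2 + 4 * c_salt^2)) / 2
  c(cation = coion - X, anion = coion)
}

# high-Peclet limiting rejection of a 1:1 salt with equal diffusivities and
# no hindrance through a homogeneous membrane of charge X (hand-derived:
# interior pinned at the entrance-partitioned state, exit Donnan layer)
donnan_limiting_rejection <- function(c_salt, X) {
  1 - 2 * c_salt / sqrt(X^2 + 4 * c_salt^2)
}

# point-like monovalent ions with equal diffusivities (steric and Born
# factors negligible), for ideal-Donnan comparisons
ideal_salt <- function(conc = 10) {
  solution_state(
    list(species("M+", 1, 1.3e-9, r_stokes = 1e-18),
         species("X-", -1, 1.3e-9, r_stokes = 1e-18)),
    conc = c(conc, conc))
}

# uncharged single-solute feed at lambda = rs/rp
neutral_feed <- function(conc = 5) {
  solution_state(list(species("tracer", 0, 6e-10, r_stokes = 0.2e-9)),
                 conc = conc)
}

uncharged_membrane <- function(rp = 0.4e-9, dx_eff = 1e-5) {
  membrane(rp, dx_eff, 78.4, charge_profile(0, 0), name = "uncharged")
}

quiet_ctl <- function(...) sede_control(warn_cap = FALSE, ...)
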