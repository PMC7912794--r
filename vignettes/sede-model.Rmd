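---
title: "Modelling antibiotic rejection by bipolar-charged nanofiltration membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling antibiotic rejection by bipolar-charged nanofiltration membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedenf)
```

## The problem

Sulfadiazine (SDZ) is an amphoteric sulfonamide antibiotic (pKa 2.00/6.50,
molar mass 250.28 g/mol) that is predominantly a mono-anion at neutral pH and
is poorly removed by conventional water treatment. Nanofiltration (NF)
membranes reject it by a combination of three mechanisms: steric exclusion
(the 0.40 nm solute in sub-nanometre pores), electric (Donnan) exclusion by
the membrane's fixed charge, and dielectric (Born) exclusion by the lowered
dielectric constant of pore-confined water. Polyamide active layers are
moreover *bipolar*: interfacial polymerization leaves deprotonated carboxyl
groups on the outer (feed) face and protonated amine groups on the inner
face, so the volumetric fixed charge runs from negative at the pore entrance
to positive at the exit. This package implements the full
steric + electric + dielectric exclusion (SEDE) transport model for such
bipolar nanopores and applies it to SDZ rejection by four commercial
membranes (NF90, NF270, VNF2-8040, TMN20H-400).

## The model

The active layer is a bundle of straight cylindrical pores of radius $r_p$;
all quantities are radially averaged (uniform-potential approximation) and
expressed on the normalized axial coordinate $x \in [0,1]$. Solute transport
follows the extended Nernst-Planck equation with hindered diffusion and
convection,

$$\frac{dc_i}{dx} = \frac{J_v\,\Delta x_\mathrm{eff}}{K_{i,d} D_{i,\infty}}
  \left(K_{i,c} c_i - c_i^\mathrm{perm}\right)
  - z_i c_i \frac{F}{RT} \frac{d\psi}{dx},$$

where $\Delta x_\mathrm{eff} = \Delta w / A_k$ lumps active-layer thickness,
porosity and tortuosity into a single effective thickness. The Poisson
equation is replaced by local electroneutrality against the axial fixed
charge,

$$\sum_i z_i c_i(x) + C_\mathrm{Loc}(x) = 0,$$

which, differentiated along $x$, yields the axial electric field including
the inhomogeneous-charge term:

$$E(x) = -\frac{d\psi}{dx} = -\frac{RT}{F}\,
  \frac{\sum_i z_i \frac{J_v \Delta x_\mathrm{eff}}{K_{i,d}D_{i,\infty}}
        (K_{i,c}c_i - c_i^\mathrm{perm}) + \frac{dC_\mathrm{Loc}}{dx}}
       {\sum_i z_i^2 c_i}.$$

At both pore mouths solutes partition by the product of three factors,

$$\frac{c_i^\mathrm{pore}}{c_i^\mathrm{bulk}} =
  \phi_i\, e^{-z_i F \Delta\psi_D / RT}\, e^{-\Delta W_{i,\mathrm{Born}}},
  \qquad \phi_i = (1-\lambda_i)^2,\quad \lambda_i = r_{i,s}/r_p,$$

with the Donnan potential $\Delta\psi_D$ the root of interfacial
electroneutrality and the Born penalty

$$\Delta W_{i,\mathrm{Born}} = \frac{(z_i e)^2}{8\pi\varepsilon_0 k_B T\,
  r_{i,\mathrm{cav}}}\left(\frac{1}{\varepsilon_p} -
  \frac{1}{\varepsilon_b}\right).$$

Hindrance factors $K_{i,d}$, $K_{i,c}$ use the Bungay-Brenner centerline
series, valid over the whole $\lambda$ range; rejection is
$R_i = 1 - c_i^\mathrm{perm}/c_i^\mathrm{feed}$. For an uncharged solute all
of this collapses to the closed form
$R = 1 - \phi K_c / \left(1 - (1-\phi K_c)e^{-Pe}\right)$ with
$Pe = K_c J_v \Delta x_\mathrm{eff}/(K_d D)$, which the solver reproduces to
machine precision and which is used both to size pores from neutral-tracer
data and as a solver oracle in the tests.

Two printed-form corrections are applied deliberately. The Gouy-Chapman
conversion is implemented with $\mathrm{sign}(\sigma) =
\mathrm{sign}(\zeta)$ (a negative zeta potential means a negatively charged
surface), and rejection is reported as $1 - c^\mathrm{perm}/c^\mathrm{feed}$
so that it lies in $[0,1]$ and increases with better removal.

## Membrane characterization

Pore radii come from neutral-tracer limiting rejections: for each tracer
(dioxane, erythritol, xylose, with tabulated Stokes radii 0.234/0.263/0.290
nm), the limiting rejection $R_\infty = 1 - \phi K_c$ is inverted for
$\lambda$ by bracketed root search and $r_p = r_s/\lambda$; per-membrane
radii are arithmetic means over tracers. The bundled per-tracer $\lambda$
table reproduces mean radii of 0.34, 0.42, 0.35 and 0.44 nm for NF90, NF270,
VNF2-8040 and TMN20H-400. When raw rejection-versus-flux curves are supplied
instead, a two-parameter fit of the closed-form curve (free $\lambda$ and
free Peclet-per-flux slope) extracts $R_\infty$; a highest-flux plateau
average is available as an alternative strategy. The pore dielectric
constant cannot be measured directly and is treated as a tabulated membrane
property (33.4, 35.7, 33.7, 36.4), with a pluggable correlation
$\varepsilon_p(r_p)$ hook for users who prefer a model.

## Charge-profile calibration

The bipolar profile is a logistic smooth step between an entrance plateau
$c_\mathrm{ent} < 0$ and an exit plateau $c_\mathrm{exit} > 0$, rescaled so
the endpoint values are exact, with midpoint $x_0$ and width $w$ (defaults
0.65 and 0.08; the closed-form profile expressions used in the original
analysis are not publicly available, so a pluggable parametric family is
used instead). Endpoint charges derive from zeta potentials via
Gouy-Chapman and $C_\mathrm{Loc} = 2\sigma/(F r_p)$: the strong-base zeta
(carboxyls, outer face) sets the entrance charge, the strong-acid zeta
(amines, inner face) the exit charge. When an average-charge target is
given, $x_0$ is fitted by root search so the profile mean matches it
exactly.

The numerical zeta values of the four membranes are not published; the
bundled fixtures use +18/+10/+9/+14 mV at pH 2 and -12.5/-22/-11.5/-18 mV at
pH 9 (NF90/NF270/VNF2-8040/TMN20H-400), chosen once to satisfy every
reported ordering simultaneously: the pH-2 amine ordering, the pH-9 carboxyl
ordering, and — after division by $r_p$ — the entrance-charge ordering
NF270 > TMN20H-400 > NF90 > VNF2-8040 and exit-charge ordering
NF90 > TMN20H-400 > VNF2-8040 > NF270. Average-charge targets are
-25.8 mmol/L (NF90) and -33.0 mmol/L (VNF2-8040, TMN20H-400) as reported;
no NF270 average is published, so the fixture uses -30.0 mmol/L, an
intermediate value consistent with NF270's strong entrance charge and weak
exit charge.

## Parameters that matter

| parameter | default | units | meaning / why this value |
|---|---|---|---|
| `rp` | per membrane (0.34-0.44) | nm | tracer-characterized pore radius |
| `eps_p` | per membrane (33.4-36.4) | - | pore dielectric constant (tabulated) |
| `dx_eff` | 1e-5 | m | effective thickness $\Delta w/A_k$; unreported for these membranes, 10 um is in the range fitted for polyamide NF in transport studies and is a pure scaling of the flux-pressure relation |
| `w` | 0.08 | - | charge-transition width; sharp transition in the back half of the pore |
| `lambda_max` | 0.95 | - | steric cap: SDZ ($r_s$ = 0.40 nm) nominally exceeds the NF90/VNF2-8040 pore radius, where Ferry partitioning is undefined; capped values carry a warning |
| feed | 4 umol/L SDZ + Na+ + 10 mM NaCl | mol/m^3 | 1 mg/L SDZ over 250.28 g/mol; background electrolyte represents the ionic strength of the pH-adjusted feed (see below) |
| `mu` | 8.9e-4 | Pa s | water viscosity at 25 C |
| `eps_b` | 78.4 | - | bulk dielectric constant at 25 C |
| `r_cav` | = $r_s$ | m | Born cavity radius; no independent values available |

The SDZ feed's exact ionic composition is not published (pH was adjusted
with trace NaOH/HCl). The background electrolyte level changes rejection
ordering not at all (verified at 1 and 10 mol/m^3 over the whole pressure
grid) but controls the ion content of the charge-transition zone and hence
how the intrapore field responds to flux: at 1 mM the transition zone is so
depleted that the built-in junction field dominates and one membrane's field
minimum stops responding to flux; at 10 mM all four fixtures show the
monotone flux-deepening of the field pit that the mechanism predicts. The
default is therefore 10 mol/m^3.

## Numerics

The boundary-value problem is solved by shooting from the permeate side,
which is the stable integration direction of this convection-dominated
system (forward integration has modes growing like $e^{Pe\,x}$ and a
forward permeate iteration diverges for $Pe \gtrsim 1$). Each outer
iteration: (i) partition the current permeate guess into the pore at $x=1$
(Donnan root by bracketed search within $|\Delta\psi_D| \le 1$ V, residual
polished to $10^{-12}$ of the charge scale); (ii) integrate the ENP system
backward with `deSolve::lsoda` (relative tolerance 1e-10, per-species
absolute tolerances scaled to the boundary concentrations); (iii) invert the
feed-side partition at $x=0$ to get the feed that would produce this
permeate; (iv) update the permeate by the ratio (actual feed)/(implied
feed), clamped per step, until the implied feed matches to 1e-8 relative.
For uncharged solutes the update is exact after one iteration. Output
profiles are reported on a fixed 401-point grid; the axial field is
evaluated from the converged profiles with the same electroneutrality
closure used during integration. $J_v = 0$ is returned analytically (zero
rejection, local-equilibrium profiles). Degenerate inputs fail loudly:
non-electroneutral feeds, fixed charge with no mobile ions, and Donnan
brackets outside $\pm 1$ V are errors, and non-convergence is flagged on
the returned object rather than silently accepted.

Pressure-driven operating points convert to flux by Hagen-Poiseuille,
$J_v = r_p^2 (\Delta P - \Delta\pi)/(8\mu\,\Delta x_\mathrm{eff})$, with a
one-pass van 't Hoff osmotic correction (negligible at micromolar feeds).

## Synthetic data and what the tests show

The generators produce every input the pipeline consumes, with known truth
and a fixed seed: tracer rejection curves from the closed-form law on a
log-spaced flux grid spanning $Pe \approx 0.1$-$20$; sigmoidal zeta-pH
curves crossing zero exactly at the chosen isoelectric point; and noisy
SDZ rejection-pressure datasets from the forward SEDE solver. Noise is
multiplicative lognormal on the rejection complement $1-R$ (default
$\sigma = 0.02$), which keeps rejections in $[0,1)$ and mirrors how
strongly-rejecting measurements err. Recovery tests demonstrate: pore radius
within 0.02 nm from 1%-noise tracer data; isoelectric point within 0.1 pH
at 1 mV noise; entrance-charge amplitude within 15% from 2%-noise rejection
curves (fitted on $\log(1-R)$, the natural scale for this noise model).
The generators emulate curve shapes and noise, not real-data pathologies —
no fouling drift, pore-size distributions, concentration polarization or
adsorption — so passing recovery tests show the inference machinery is
self-consistent, not that field data will be this clean.

## Known limitations

* **The steric cap.** SDZ is nominally larger than the NF90 and VNF2-8040
  pores ($\lambda > 1$); the model proceeds with $\lambda_\mathrm{eff} =
  0.95$, so its SDZ predictions for the two tight membranes inherit that
  approximation (real membranes pass solute through the wide tail of their
  pore-size distribution, which is not modelled).
* **Very high predicted rejections.** With zeta-derived fixed charges of
  tens of mol/m^3 against a micromolar-to-10 mM feed, Donnan plus Born
  exclusion is extreme and predicted SDZ rejections sit within a percent of
  100% across 0.4-2.0 MPa; the experimentally observed spread (rejections
  well below 100%) reflects pore-size distributions and polarization that
  the model excludes. The reported membrane *ordering* is reproduced.
* **Field positivity near the exit.** At high flux the model yields a thin,
  weakly positive field tail near the pore exit (about 0.4% of the pit
  magnitude): the anion cloud balancing the positive exit charge always
  exceeds the nearly-fully-rejected permeate, so the anion convective term
  dominates once the charge gradient has decayed. The dominant negative
  screen and its pit in the transition zone are unaffected.
* **Flux response of the pit.** The field minimum sits at the fixed-charge
  zero crossing, whose ion content is suppressed by the steric and Born
  partition factors; the flux-independent charge-gradient term therefore
  remains a large share of the pit, and the pit deepens monotonically but
  sub-proportionally with flux (factor ~2-4 over a tenfold flux increase
  under the bundled conditions).
* Charge regulation, activity coefficients, image-charge dielectric
  exclusion, concentration polarization and transient operation are out of
  scope.

## A worked run

```{r example}
fx <- suppressWarnings(nf_membranes())
rejection_vs_pressure(fx$NF90, c(0.4e6, 1.2e6, 2.0e6),
                      control = sede_control(warn_cap = FALSE))
```

```{r field}
sol <- solve_transport(fx$NF90, operating_point(sdz_feed(), Jv = 6e-4),
                       control = sede_control(warn_cap = FALSE))
min(sol$E)                      # field pit, V/m
sol$x_grid[which.min(sol$E)]    # sits in the charge-transition zone
```
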