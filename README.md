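# sedenf

Steric + electric + dielectric exclusion (SEDE) transport modelling of
nanofiltration, applied to removal of the antibiotic sulfadiazine (SDZ) by
polyamide membranes with **bipolar** fixed-charge distributions — negative
(carboxylate) at the pore entrance, positive (protonated amine) at the exit.

The package is for membrane scientists and environmental engineers who want
to go from routine characterization data (neutral-tracer rejections, zeta
potentials) to mechanistic predictions: rejection-versus-pressure curves,
intrapore axial electric fields and ion concentration profiles.

## Model core

Transport in a cylindrical nanopore (radius `r_p`, effective thickness
`Δx_eff = Δw/A_k`) follows the extended Nernst–Planck equation under the
uniform-potential approximation,

    dc_i/dx = (J_v Δx_eff / (K_id D_i)) (K_ic c_i − c_i^perm) − z_i c_i (F/RT) dψ/dx,

closed by local electroneutrality `Σ z_i c_i(x) + C_Loc(x) = 0` against the
axial fixed-charge profile `C_Loc(x)`, whose gradient generates the axial
electric field that screens ion passage. Solutes partition at both pore
mouths by the product of steric (`φ = (1−λ)²`), Donnan
(`exp(−zFΔψ_D/RT)`) and Born (`exp(−ΔW_Born)`) factors; hindrance factors
`K_d`, `K_c` are Bungay–Brenner. Membrane fixed charge is calibrated from
zeta potentials by Gouy–Chapman theory and `C_Loc = 2σ/(F r_p)`; pore radii
come from inverting the neutral-solute limiting rejection `R_∞ = 1 − φK_c`.

## Worked example

```r
library(sedenf)

# pore sizing from the bundled per-tracer size ratios
head(characterize_pores(), 4)
#>   membrane     tracer rs_nm lambda     rp_nm rp_mean_nm eps_p
#> 1     NF90    dioxane 0.234  0.691 0.3386397  0.3417365  33.4
#> 2     NF90 erythritol 0.263  0.790 0.3329114  0.3417365  33.4
#> 3     NF90     xylose 0.290  0.820 0.3536585  0.3417365  33.4
#> 4    NF270    dioxane 0.234  0.509 0.4597250  0.4199622  35.7

# calibrated membrane fixtures (zeta -> bipolar charge profile)
fx <- nf_membranes()
fx$NF90
#> <membrane> NF90: rp=0.340 nm  dx_eff=1e-05 m  eps_p=33.4
#> <charge_profile> logistic-step: -55.6 -> 80.9 mol/m^3, x0=0.806, w=0.080 (avg -25.8)

# SDZ rejection vs pressure (feed: 1 mg/L SDZ, 10 mM NaCl background)
rejection_vs_pressure(fx$NF90, c(0.4e6, 1.2e6, 2.0e6))
#>   dP_MPa       Jv_m_s     R_SDZ     R_Na+     R_Cl-
#> 1    0.4 6.494382e-07 0.9999978 0.9988879 0.9977936
#> 2    1.2 1.867920e-06 0.9999978 0.9995856 0.9991780
#> 3    2.0 3.166712e-06 0.9999978 0.9997373 0.9994790
```

The per-tracer radii average to 0.34 nm (NF90), 0.42 (NF270), 0.35
(VNF2-8040) and 0.44 (TMN20H-400); SDZ rejection across 0.4–2.0 MPa ranks
`NF90 > VNF2-8040 > NF270 > TMN20H-400` — the two tight membranes separate
from the loose ones sterically, and within each pair the membrane with the
stronger entrance charge wins.

The intrapore electric field shows the screening mechanism:

```r
sol <- solve_transport(fx$NF90, operating_point(sdz_feed(), Jv = 6e-4))
min(sol$E)                    # -7.93e6 V/m: the field "pit"
sol$x_grid[which.min(sol$E)]  # 0.765 — inside the charge-transition zone
```

The pit sits where the fixed charge flips sign, deepens monotonically with
volume flux, and drives the drop in cation (and rise in anion)
concentration across the transition.

Synthetic-data generators (`gen_tracer_rejections()`, `gen_zeta_curve()`,
`gen_rejection_dataset()`) produce seeded datasets with known ground truth
for recovery studies; `load_config()` / `read_rejection_csv()` /
`write_report()` handle the CSV/YAML interfaces, with bundled fixtures under
`inst/extdata/`.

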