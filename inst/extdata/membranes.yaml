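# Bundled membrane fixtures: characterized pore radii and pore dielectric
# constants, with bipolar charge profiles calibrated from strong-acid /
# strong-base zeta potentials and per-membrane average-charge targets
# (mol/m^3). dx_eff_m is the lumped effective active-layer thickness.
membranes:
  NF90:
    rp_nm: 0.34
    dx_eff_m: 1.0e-5
    eps_p: 33.4
    zeta_acid_mV: 18.0
    zeta_base_mV: -12.5
    avg_target: -25.8
  NF270:
    rp_nm: 0.42
    dx_eff_m: 1.0e-5
    eps_p: 35.7
    zeta_acid_mV: 10.0
    zeta_base_mV: -22.0
    avg_target: -30.0
  VNF2-8040:
    rp_nm: 0.35
    dx_eff_m: 1.0e-5
    eps_p: 33.7
    zeta_acid_mV: 9.0
    zeta_base_mV: -11.5
    avg_target: -33.0
  TMN20H-400:
    rp_nm: 0.44
    dx_eff_m: 1.0e-5
    eps_p: 36.4
    zeta_acid_mV: 14.0
    zeta_base_mV: -18.0
    avg_target: -33.0
species:
  SDZ:
    z: -1
    D_inf: 6.14e-10
    pKa1: 2.00
    pKa2: 6.50
  Na:
    z: 1
    D_inf: 1.33e-9
  Cl:
    z: -1
    D_inf: 2.03e-9
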