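tracer,mw_g_mol,D_m2_per_s,rs_nm
dioxane,88,9.1e-10,0.234
erythritol,120,8.1e-10,0.263
xylose,150,7.4e-10,0.290
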