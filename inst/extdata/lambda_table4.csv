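membrane,tracer,rs_nm,lambda
NF90,dioxane,0.234,0.691
NF90,erythritol,0.263,0.790
NF90,xylose,0.290,0.820
NF270,dioxane,0.234,0.509
NF270,erythritol,0.263,0.584
NF270,xylose,0.290,0.829
VNF2-8040,dioxane,0.234,0.616
VNF2-8040,erythritol,0.263,0.731
VNF2-8040,xylose,0.290,0.935
TMN20H-400,dioxane,0.234,0.498
TMN20H-400,erythritol,0.263,0.598
TMN20H-400,xylose,0.290,0.707
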