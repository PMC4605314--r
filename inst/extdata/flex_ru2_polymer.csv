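# Extensible WLC parameters of bare and ligand-saturated DNA constructs
# (fit values with standard errors). Units: contour nm/bp, persistence nm,
# stretch modulus pN.
polymer,contour_per_bp,contour_se,persistence,persistence_se,stretch_modulus,stretch_se
dsDNA,0.340,0.001,47,2,1270,200
dsDNA_Ru1,0.41,0.01,14.3,0.8,320,17
dsDNA_flexRu2,0.49,0.01,2.9,0.8,800,50
ssDNA,0.680,0.002,1.2,0.1,1220,70
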