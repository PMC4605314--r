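# Zero-force kinetic and equilibrium parameters of flex-Ru2 bis-intercalation,
# from the kinetic route (Bell extrapolation of elementary rates) and the
# independent equilibrium route (amplitude analysis). value/x0 pairs carry the
# zero-force constant and its equilibrium elongation or transition distance (nm).
# Units: Kd, Kd1 nM; K2 dimensionless; k1 nM^-1 s^-1; k_m1, k2, k_m2 s^-1.
parameter,kinetic_value,kinetic_se,kinetic_x0,kinetic_x0_se,equilibrium_value,equilibrium_se,equilibrium_x0,equilibrium_x0_se
Kd,15,6,0.44,0.04,4.1,1.4,0.33,0.04
Kd1,35,9,0.24,0.02,11,4,0.25,0.04
K2,1.8,0.6,0.22,0.03,2.7,0.8,0.08,0.05
k1,1.8e-3,0.4e-3,0.19,0.02,NA,NA,NA,NA
k_m1,68e-3,4e-3,-0.06,0.01,NA,NA,NA,NA
k2,5.8e-3,1.0e-3,0.08,0.01,NA,NA,NA,NA
k_m2,3.6e-3,1.0e-3,-0.15,0.03,NA,NA,NA,NA
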