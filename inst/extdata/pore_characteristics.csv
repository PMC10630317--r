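layer,statistic,values
L-1,total_full_pores,78;102;103;101;111
L-2,total_full_pores,72;120;154;133;103
L-3,total_full_pores,40;38;56;66;59
L-1,fraction_dominant,0.49;0.58;0.45;0.52;0.48
L-2,fraction_dominant,0.42;0.34;0.53;0.49;0.43
L-3,fraction_dominant,0.32;0.27;0.31;0.47;0.24
L-1,fraction_small,0.72;0.78;0.67;0.71;0.68
L-2,fraction_small,0.59;0.60;0.82;0.71;0.60
L-3,fraction_small,0.59;0.42;0.56;0.63;0.59
L-1,porosity,0.52;0.50;0.47;0.50;0.61
L-2,porosity,0.60;0.46;0.48;0.53;0.52
L-3,porosity,0.68;0.65;0.63;0.61;0.66
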