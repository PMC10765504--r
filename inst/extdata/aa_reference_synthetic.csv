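amino_acid,abbrev,mean_molpct,sd_molpct,factor_coef,carbon_atoms,in_di_set,source
aspartic_acid,Asp,11.0,2.0,-0.10,4,TRUE,synthetic stand-in patterned after the published degradation-index calibration
glutamic_acid,Glu,9.0,2.5,0.13,5,TRUE,synthetic stand-in patterned after the published degradation-index calibration
serine,Ser,8.5,1.5,-0.14,3,TRUE,synthetic stand-in patterned after the published degradation-index calibration
glycine,Gly,21.0,5.0,-0.25,2,TRUE,synthetic stand-in patterned after the published degradation-index calibration
threonine,Thr,7.0,1.5,-0.12,4,TRUE,synthetic stand-in patterned after the published degradation-index calibration
alanine,Ala,13.0,2.5,0.02,3,TRUE,synthetic stand-in patterned after the published degradation-index calibration
tyrosine,Tyr,1.5,0.8,0.16,9,TRUE,synthetic stand-in patterned after the published degradation-index calibration
methionine,Met,1.0,0.6,0.08,5,TRUE,synthetic stand-in patterned after the published degradation-index calibration
valine,Val,6.5,1.2,0.09,5,TRUE,synthetic stand-in patterned after the published degradation-index calibration
phenylalanine,Phe,3.0,1.0,0.16,9,TRUE,synthetic stand-in patterned after the published degradation-index calibration
isoleucine,Ile,4.5,1.0,0.16,6,TRUE,synthetic stand-in patterned after the published degradation-index calibration
leucine,Leu,7.0,1.8,0.17,6,TRUE,synthetic stand-in patterned after the published degradation-index calibration
histidine,His,2.0,0.9,0.04,6,TRUE,synthetic stand-in patterned after the published degradation-index calibration
arginine,Arg,5.0,1.6,0.07,6,TRUE,synthetic stand-in patterned after the published degradation-index calibration
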