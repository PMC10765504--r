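priority,class,c_min,c_max,hc_min,hc_max,oc_min,oc_max,ai_min,ai_max,n_min,n_max,s_min,s_max,p_min,p_max,dbec_min,dbec_max,dbeh_min,dbeh_max,dbeo_min,dbeo_max
1,black carbon,15,NA,NA,NA,NA,NA,0.66,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
2,condensed hydrocarbons,NA,NA,NA,NA,NA,NA,0.66,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
3,polyphenols,NA,NA,NA,NA,NA,NA,0.5,0.66,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
4,sugars,NA,NA,1.5,NA,0.8,NA,NA,NA,NA,0,NA,0,NA,NA,NA,NA,NA,NA,NA,NA
5,carbohydrates,NA,NA,1.5,NA,0.67,NA,NA,NA,NA,0,NA,0,NA,NA,NA,NA,NA,NA,NA,NA
6,proteins,NA,NA,1.5,NA,0.3,0.67,NA,NA,2,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
7,peptides,NA,NA,1.5,NA,0.3,0.67,NA,NA,1,1,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
8,protein maya,NA,NA,1.5,NA,0.67,NA,NA,NA,1,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
9,saturated fatty acids,NA,NA,1.9,NA,NA,0.3,NA,NA,NA,0,NA,0,NA,NA,NA,NA,NA,NA,NA,NA
10,lipids,NA,NA,1.5,NA,NA,0.3,NA,NA,NA,0,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
11,unsaturated aliphatic compounds,NA,NA,1.5,NA,0.3,0.67,NA,NA,NA,0,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
12,CRAM,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,0.3,0.68,0.2,0.95,0.77,1.75
13,lignin,NA,NA,0.7,1.5,0.1,0.67,NA,0.5,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
14,highly unsaturated compounds,NA,NA,NA,1.5,NA,NA,NA,0.5,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
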