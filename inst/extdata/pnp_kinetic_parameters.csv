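enzyme_form,variable_substrate,constant_substrate,constant_conc_mM,fitted_here,mm_sufficient,Km1,Km1_err,Km1_dp,Km1_approx,Vmax1,Vmax1_err,Vmax1_dp,Vmax1_approx,Km2,Km2_err,Km2_dp,Vmax2,Vmax2_err,Vmax2_dp,a,a_err,a_dp,a_approx,b,b_err,b_dp,b_approx
non-recombinant,phosphate,m7Guo,0.25,FALSE,FALSE,0.015,0.002,3,FALSE,16,1,0,FALSE,0.135,0.045,3,11,1,0,9,NA,0,FALSE,0.69,NA,2,FALSE
WT,phosphate,m7Guo,0.25,TRUE,FALSE,0.015,0.004,3,FALSE,10.8,0.7,1,FALSE,4.0,3.7,1,8.2,0.6,1,267,232,0,FALSE,0.76,0.06,2,FALSE
DM,phosphate,m7Guo,0.25,TRUE,FALSE,0.066,0.014,3,FALSE,32.5,2.0,1,FALSE,6.8,1.9,1,44.2,2.3,1,103,26,0,FALSE,1.4,0.1,1,FALSE
WT,phosphate,Ado,0.22,TRUE,FALSE,0.23,0.10,2,FALSE,20.8,3.6,1,FALSE,3.6,2.6,1,19.3,0.9,1,15.9,8.2,1,FALSE,0.93,0.14,2,FALSE
DM,phosphate,Ado,0.22,TRUE,FALSE,0.28,0.17,2,FALSE,0.021,0.006,3,FALSE,15.2,8.3,1,0.050,0.009,3,55,29,0,FALSE,2.4,0.5,1,FALSE
non-recombinant,m7Guo,phosphate,50,FALSE,TRUE,0.036,0.006,3,FALSE,30.2,1.7,1,FALSE,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
WT,m7Guo,phosphate,50,TRUE,TRUE,0.027,0.002,3,FALSE,22.7,0.3,1,FALSE,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
DM,m7Guo,phosphate,50,TRUE,FALSE,0.110,NA,3,TRUE,18,NA,0,TRUE,0.024,0.008,3,29.2,1.5,1,0.22,0.20,2,FALSE,1.5,NA,1,TRUE
WT,Ado,phosphate,50,TRUE,TRUE,0.028,0.004,3,FALSE,51.1,2.3,1,FALSE,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
DM,Ado,phosphate,50,TRUE,FALSE,0.013,0.009,3,FALSE,0.011,0.025,3,FALSE,0.005,0.007,3,0.043,0.020,3,0.38,0.24,2,FALSE,4.0,NA,1,TRUE
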