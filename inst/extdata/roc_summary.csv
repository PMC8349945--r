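table,parameter,contrast,n_pos,n_neg,sens,spec,acc_printed
4,I_Df,malignant_vs_benign,74,35,0.932,0.943,0.936
4,ADC,malignant_vs_benign,74,35,0.892,0.914,0.899
3,Dprime,other_vs_haemangioma,86,23,0.988,0.913,0.972
3,fprime,other_vs_FNH,97,12,0.907,1.000,0.917
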