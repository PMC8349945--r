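map,session,assessment,tn,fn,fp,tp
I_ADC,investigator1,definite,28,2,3,65
I_ADC,investigator1,probable,1,2,3,5
I_D,investigator1,definite,22,1,13,73
I_D,investigator1,probable,0,0,0,0
I_f,investigator1,definite,6,1,23,73
I_f,investigator1,probable,4,0,2,0
I_Df,investigator1,definite,26,2,1,66
I_Df,investigator1,probable,6,0,2,6
I_ADC,investigator1_repeat,definite,28,2,3,65
I_ADC,investigator1_repeat,probable,1,2,3,5
I_Df,investigator1_repeat,definite,26,2,1,66
I_Df,investigator1_repeat,probable,6,0,2,6
I_ADC,investigator2,definite,28,2,3,65
I_ADC,investigator2,probable,1,2,3,5
I_Df,investigator2,definite,26,2,1,66
I_Df,investigator2,probable,6,0,2,6
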