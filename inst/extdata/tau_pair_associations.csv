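region_a,region_b,beta_full,p_full,p_full_censored,beta_ba,p_ba,p_ba_censored,beta_nhw,p_nhw,p_nhw_censored,interaction_p
L inferior temporal gyrus,R parahippocampal gyrus,-2.26,0.0008,FALSE,-2.40,0.001,FALSE,-1.98,0.01,FALSE,NA
L fusiform,R entorhinal cortex,-1.89,0.0003,FALSE,-1.85,0.007,FALSE,-2.22,0.01,FALSE,NA
L amygdala,L fusiform gyrus,-0.97,0.008,FALSE,-0.98,0.06,FALSE,-1.43,0.01,FALSE,0.94
L amygdala,L inferior temporal gyrus,-0.95,0.006,FALSE,-0.76,0.12,FALSE,-1.39,0.01,FALSE,0.38
L inferior temporal gyrus,L parahippocampal gyrus,-0.66,0.06,FALSE,-0.30,0.54,FALSE,-0.91,0.08,FALSE,NA
L fusiform,L middle temporal gyrus,-0.64,0.03,FALSE,-0.14,0.73,FALSE,-1.37,0.003,FALSE,0.15
L fusiform,L parahippocampal gyrus,-0.46,0.13,FALSE,0.39,0.39,FALSE,-1.14,0.009,FALSE,0.06
L amygdala,R fusiform gyrus,0.23,0.09,FALSE,0.33,0.06,FALSE,0.14,0.52,FALSE,NA
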