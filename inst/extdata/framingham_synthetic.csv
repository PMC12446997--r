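sex,term,value
male,log_age,3.06117
male,log_total_chol,1.12370
male,log_hdl_chol,-0.93263
male,log_sbp_untreated,1.93303
male,log_sbp_treated,1.99881
male,smoker,0.65451
male,diabetes,0.57367
male,s0_annual,0.98834
male,lp_mean,23.9802
female,log_age,2.32888
female,log_total_chol,1.20904
female,log_hdl_chol,-0.70833
female,log_sbp_untreated,2.76157
female,log_sbp_treated,2.82263
female,smoker,0.52873
female,diabetes,0.69154
female,s0_annual,0.99489
female,lp_mean,26.1931
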