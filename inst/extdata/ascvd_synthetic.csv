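sex,race_group,term,value
male,other,log_age,3.20
male,other,log_total_chol,1.00
male,other,log_hdl_chol,-0.90
male,other,log_sbp_untreated,1.80
male,other,log_sbp_treated,1.90
male,other,smoker,0.65
male,other,diabetes,0.66
male,other,s0_10yr,0.91
male,other,lp_mean,23.67
male,black,log_age,2.50
male,black,log_total_chol,0.30
male,black,log_hdl_chol,-0.30
male,black,log_sbp_untreated,1.90
male,black,log_sbp_treated,2.00
male,black,smoker,0.55
male,black,diabetes,0.80
male,black,s0_10yr,0.89
male,black,lp_mean,19.93
female,other,log_age,2.70
female,other,log_total_chol,1.10
female,other,log_hdl_chol,-0.80
female,other,log_sbp_untreated,2.60
female,other,log_sbp_treated,2.70
female,other,smoker,0.55
female,other,diabetes,0.85
female,other,s0_10yr,0.95
female,other,lp_mean,26.37
female,black,log_age,2.80
female,black,log_total_chol,0.50
female,black,log_hdl_chol,-0.40
female,black,log_sbp_untreated,2.80
female,black,log_sbp_treated,2.90
female,black,smoker,0.50
female,black,diabetes,0.95
female,black,s0_10yr,0.93
female,black,lp_mean,26.05
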