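outcome,term,value
cost,intercept,400
cost,age,75
cost,female,300
cost,cvd_history,4800
cost,diabetes,2600
cost,smoker,650
cost,bmi,40
cost,income_poor,400
cost,income_near_poor,300
cost,income_low,200
cost,income_medium,100
cost,income_high,0
cost,edu_no_degree,250
cost,edu_ged_hs,150
cost,edu_associate_bachelor,50
cost,edu_master_doctorate,0
cost,race_Asian,-100
cost,race_Black,150
cost,race_Hispanic,100
cost,race_Other,50
cost,race_White,0
cost,event_mi,0
cost,event_stroke,0
utility,intercept,0.945
utility,age,-0.0012
utility,female,-0.010
utility,cvd_history,-0.070
utility,diabetes,-0.045
utility,smoker,-0.020
utility,bmi,-0.002
utility,income_poor,-0.030
utility,income_near_poor,-0.020
utility,income_low,-0.012
utility,income_medium,-0.005
utility,income_high,0
utility,edu_no_degree,-0.020
utility,edu_ged_hs,-0.012
utility,edu_associate_bachelor,-0.005
utility,edu_master_doctorate,0
utility,race_Asian,0
utility,race_Black,-0.010
utility,race_Hispanic,-0.005
utility,race_Other,-0.005
utility,race_White,0
utility,event_mi,-0.060
utility,event_stroke,-0.110
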