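event,sex,intercept,slope_age
mi,male,-4.3,0.045
mi,female,-4.6,0.045
stroke,male,-4.8,0.050
stroke,female,-5.0,0.050
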