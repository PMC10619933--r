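roi,mean_exam1,sd_exam1,mean_exam2,sd_exam2,loa_neg,loa_pos,rc,cov_percent,icc
WC,28.0,1.1,28.3,1.5,-2.3,1.7,1.4,1.8,0.85
WM,30.1,1.1,30.4,1.7,-2.0,1.3,1.1,1.4,0.91
GM,19.7,3.1,19.9,2.1,-4.6,4.2,2.9,5.3,0.84
DC,35.3,3.4,34.1,2.2,-1.5,4.0,2.1,2.0,0.91
LCST,29.3,3.2,29.9,2.1,-5.6,4.3,3.5,4.3,0.78
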