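roi,mean_exam1,sd_exam1,mean_exam2,sd_exam2,loa_neg,loa_pos,rc,cov_percent,icc
WM and GM,6.4,0.8,6.3,0.8,-0.3,0.4,0.2,1.3,0.99
WM,8.8,1.4,8.7,1.4,-0.7,1.1,0.6,2.4,0.97
All JHU,11.6,1.8,11.0,2.1,-1.0,2.1,1.0,3.3,0.94
Genu CC,11.9,2.4,11.5,2.3,-1.2,2.0,1.0,3.3,0.96
Splenium CC,13.2,1.9,12.3,2.3,-0.6,2.6,1.4,4.2,0.92
Whole CC,12.0,1.9,11.4,2.3,-1.0,2.3,1.2,4.0,0.94
Posterior internal capsule,16.3,1.5,15.7,1.5,0.2,1.0,0.8,1.9,0.96
Frontal WM,7.3,1.2,7.5,1.0,-0.7,0.5,0.4,2.1,0.98
Occipital WM,9.1,1.5,9.0,1.8,-0.8,1.1,0.6,2.5,0.98
Parietal WM,8.7,1.6,8.5,1.6,-0.7,1.2,0.6,2.7,0.97
Temporal WM,6.5,1.1,6.1,1.2,-0.1,1.0,0.6,3.8,0.95
GM,3.9,0.5,3.9,0.4,-0.3,0.3,0.2,1.8,0.97
Cortical GM,3.5,0.5,3.4,0.4,-0.3,0.4,0.2,2.1,0.97
Caudate,5.8,0.7,5.3,0.7,-1.8,2.8,1.3,8.1,0.60
Thalamus,9.5,1.1,9.5,0.8,-1.7,1.8,0.9,3.8,0.82
Putamen,4.7,0.6,4.6,0.5,-0.7,1.1,0.6,4.5,0.84
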