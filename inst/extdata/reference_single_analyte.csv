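analyte,handedness,cal_mM,exp_mM,diff_printed
Leu,L,8.00,8.00,0
Leu,L,13.00,14.00,7.7
Leu,L,18.00,19.00,5.6
Leu,D,8.00,8.00,0
Leu,D,13.00,14.00,7.7
Leu,D,18.00,19.00,5.6
Pro,L,40.00,40.00,0
Pro,L,25.00,24.00,4.2
Pro,L,32.00,31.00,3.1
Pro,D,40.00,40.00,0
Pro,D,25.00,26.00,4.0
Pro,D,32.00,33.00,3.1
Met,L,4.00,4.00,0
Met,L,6.00,6.00,0
Met,L,7.00,7.00,0
Met,D,4.00,4.00,0
Met,D,6.00,6.00,0
Met,D,7.00,7.00,0
Trp,L,0.20,0.20,0
Trp,L,0.40,0.40,0
Trp,L,0.55,0.52,5.5
Trp,D,0.20,0.20,0
Trp,D,0.40,0.40,0
Trp,D,0.55,0.55,0
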