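analyte,stock_mM,ratio_L,cal_L,cal_D,exp_L,exp_D,diff_L_printed,diff_D_printed
Leu,8,0.60,4.80,3.20,4.80,3.50,0,9.4
Leu,8,0.80,6.40,1.60,6.40,1.60,0,0
Leu,8,0.20,1.60,6.40,1.60,6.50,0,1.6
Leu,8,0.55,4.40,3.60,4.40,3.80,0,5.6
Leu,13,0.60,7.80,5.20,8.20,5.60,5.1,7.7
Leu,13,0.80,10.40,2.60,10.80,2.70,3.8,3.8
Leu,13,0.20,2.60,10.40,2.80,10.90,7.7,4.8
Leu,13,0.55,7.15,5.85,7.38,6.24,3.2,6.7
Leu,18,0.60,10.80,7.20,11.60,7.70,7.4,6.9
Leu,18,0.80,14.40,3.60,14.90,3.50,3.5,2.8
Leu,18,0.20,3.60,14.40,3.50,14.80,2.8,2.8
Leu,18,0.55,9.90,8.10,10.50,8.70,6.1,7.4
Pro,25,0.60,15.00,10.00,15.00,10.00,0,0
Pro,25,0.80,20.00,5.00,20.00,5.00,0,0
Pro,25,0.20,5.00,20.00,5.00,20.00,0,0
Pro,25,0.55,13.75,11.25,14.11,11.18,2.6,0.6
Pro,32,0.60,19.20,12.80,19.30,13.00,1.6,1.6
Pro,32,0.80,25.60,6.40,25.40,7.00,0.8,9.4
Pro,32,0.20,6.40,25.60,6.50,25.60,1.6,0
Pro,32,0.55,17.60,14.40,17.90,14.30,1.7,0.7
Pro,40,0.60,24.00,16.00,24.00,16.00,0,0
Pro,40,0.80,32.00,8.00,31.00,8.00,3.1,0
Pro,40,0.20,8.00,32.00,8.00,32.00,0,0
Pro,40,0.55,22.00,18.00,22.00,18.00,0,0
Met,7,0.60,4.20,2.80,4.30,2.70,2.4,3.6
Met,7,0.80,5.60,1.40,5.40,1.50,3.6,7.1
Met,7,0.20,1.40,5.60,1.50,5.50,7.1,1.8
Met,7,0.55,3.85,3.15,3.73,3.28,3.1,4.1
Met,4,0.60,2.40,1.60,2.20,1.70,8.3,6.3
Met,4,0.80,3.20,0.80,2.90,0.80,9.4,0
Met,4,0.20,0.80,3.20,0.80,3.10,0,3.1
Met,4,0.55,2.20,1.80,2.00,1.90,9.1,5.6
Met,6,0.60,3.60,2.40,3.50,2.50,2.8,4.2
Met,6,0.80,4.80,1.20,4.60,1.30,4.2,8.3
Met,6,0.20,1.20,4.80,1.20,4.80,0,0
Met,6,0.55,3.30,2.70,3.20,2.80,3.0,3.7
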