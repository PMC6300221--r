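analyte,method,window_low,window_high,rmsec,r2_cal,rmsep,r2_pred,n_factors
IAA,none,4000,10000,6.23,0.829,7.58,0.746,5
IAA,none,4000,6000,6.94,0.7877,12.8,0.276,5
IAA,msc,4000,10000,4.27,0.91,5.84,0.85,7
IAA,msc,4000,6000,6.54,0.80,8.59,0.67,5
IAA,sg1d,4000,10000,0.470,0.99,2.97,0.94,7
IAA,sg1d,4000,5000,5.10,0.86,9.69,0.58,4
GA,none,4000,10000,4.46,0.91,8.20,0.70,7
GA,none,4000,7000,5.300,0.877,12.8,0.34,7
GA,msc,4000,10000,4.31,0.91,4.51,0.91,7
GA,msc,4000,7000,8.31,0.69,7.37,0.76,5
GA,sg1d,4000,10000,0.903,0.99,1.29,0.98,7
GA,sg1d,4000,7000,4.31,0.89,6.85,0.79,7
SA,none,4000,10000,0.08,0.99,1.36,0.92,7
SA,none,4000,6000,5.98,0.10,5.89,0.1291,1
SA,msc,4000,10000,0.9697,0.97,0.9880,-6.94,5
SA,msc,4000,6000,1.78,0.65,12.16,-8.36,3
SA,sg1d,4000,10000,0.85,0.92,12.48,-8.85,4
SA,sg1d,4000,6000,1.61,0.71,13.02,-9.13,4
kinetin,none,4000,10000,0.715,0.99,1.45,0.92,7
kinetin,none,4000,6000,3.71,0.93,11.66,0.4018,1
kinetin,msc,4000,10000,5.94,0.84,8.59,0.67,4
kinetin,msc,4000,6000,4.37,0.91,14.52,0.07,4
kinetin,sg1d,4000,10000,2.63,0.96,7.93,0.72,5
kinetin,sg1d,4000,7000,5.99,0.84,9.63,0.59,3
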