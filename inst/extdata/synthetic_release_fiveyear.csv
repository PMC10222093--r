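time,time_unit,observation_type,value,se,n
0,day,amount,0.732,0.435,5
91.25,day,amount,7.203,0.879,5
182.5,day,amount,11.932,0.88,5
273.75,day,amount,13.992,0.709,5
365,day,amount,19.149,0.916,5
547.5,day,amount,23.974,0.731,5
730,day,amount,32.722,0.321,5
912.5,day,amount,37.762,0.83,5
1095,day,amount,43.375,0.812,5
1277.5,day,amount,45.186,0.593,5
1460,day,amount,50.624,0.573,5
1642.5,day,amount,53.703,0.52,5
1825,day,amount,55.609,0.665,5
1,month,rate,0.0594,,
12,month,rate,0.044,,
24,month,rate,0.0316,,
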