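label,start_age,stop_age,criterion,cost,qaly
no_screening,NA,NA,NA,552.87,15.64662
s1,65,74,30,600.45,15.64870
s2,65,79,30,614.10,15.64928
s3,65,74,20,639.36,15.65034
s4,65,79,20,664.10,15.65136
s5,60,79,20,718.69,15.65341
s6,55,79,20,775.74,15.65504
s7,50,79,20,834.48,15.65598
s8,45,79,20,898.24,15.65627
s9,40,79,20,986.37,15.65663
guideline_2018,50,74,20,809.74,15.65496
guideline_2021,50,74,30,693.13,15.65132
guideline_2022,45,74,20,873.51,15.65525
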