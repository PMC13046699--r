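"well","role","agent","concentration","unit","replicate"
"A1","blank",NA,NA,NA,NA
"A2","blank",NA,NA,NA,NA
"A3","blank",NA,NA,NA,NA
"B1","control",NA,NA,NA,NA
"B2","control",NA,NA,NA,NA
"B3","control",NA,NA,NA,NA
"B4","control",NA,NA,NA,NA
"B5","control",NA,NA,NA,NA
"B6","control",NA,NA,NA,NA
"C1","treated","examplinib",0.125,"uM",1
"C2","treated","examplinib",0.125,"uM",2
"C3","treated","examplinib",0.125,"uM",3
"C4","treated","examplinib",0.5,"uM",1
"C5","treated","examplinib",0.5,"uM",2
"C6","treated","examplinib",0.5,"uM",3
"C7","treated","examplinib",2,"uM",1
"C8","treated","examplinib",2,"uM",2
"C9","treated","examplinib",2,"uM",3
"C10","treated","examplinib",8,"uM",1
"C11","treated","examplinib",8,"uM",2
"C12","treated","examplinib",8,"uM",3
"C13","treated","examplinib",32,"uM",1
"C14","treated","examplinib",32,"uM",2
"C15","treated","examplinib",32,"uM",3
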