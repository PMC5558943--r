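region,term,quoted,class,n_months,missing_pct
US,suicide,FALSE,pro_suicide,84,0
US,depression,FALSE,depression,84,0
US,how to kill yourself,FALSE,pro_suicide,72,0
US,how to kill yourself,TRUE,pro_suicide,68,1.69
US,how to overdose,FALSE,pro_suicide,61,5.64
US,how to overdose,TRUE,pro_suicide,37,0
US,online suicide,FALSE,pro_suicide,47,2.93
US,painless suicide,FALSE,pro_suicide,83,1.38
US,painless suicide,TRUE,pro_suicide,44,5.73
US,suicide chat,TRUE,pro_suicide,49,0
US,suicide methods,FALSE,pro_suicide,83,0
US,suicide methods,TRUE,pro_suicide,76,5.74
US,suicide help,FALSE,prevention,83,1.37
US,suicide help,TRUE,prevention,62,5.19
US,suicide hotline,FALSE,prevention,71,0
US,suicide hotline,TRUE,prevention,68,3.04
US,suicide prevention,FALSE,prevention,84,0
US,suicide prevention,TRUE,prevention,84,0
US,suicide survivors,TRUE,prevention,62,0
DE,Suizid,FALSE,pro_suicide,108,0
DE,Selbstmord,FALSE,pro_suicide,108,0
DE,Depressionen,FALSE,depression,108,0
DE,Freitod,FALSE,pro_suicide,38,0
DE,Selbstmord Forum,FALSE,pro_suicide,108,0
AT,Suizid,FALSE,pro_suicide,37,4.94
AT,Selbstmord,FALSE,pro_suicide,98,4.92
AT,Depressionen,FALSE,depression,75,2.14
CH,Selbstmord,FALSE,pro_suicide,48,2.39
CH,Depressionen,FALSE,depression,40,8.62
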