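"study_id","quantile","measure","point","ci_lower","ci_upper","outcome_prevalence","rare_outcome","tag"
"synth01","Q2","hr",0.9428,0.8683,1.0236,NA,TRUE,"owob"
"synth02","Q2","or",1.0446,0.909,1.2003,0.05,NA,"owob"
"synth03","Q2","rr",1.0262,0.9576,1.0998,NA,NA,"owob"
"synth04","Q2","rr",1.0101,0.8952,1.1397,NA,NA,"weightgain"
"synth05","Q2","rr",0.9949,0.8886,1.114,NA,NA,"weightgain"
"synth01","Q3","hr",1.055,0.9312,1.1953,NA,TRUE,"owob"
"synth02","Q3","or",1.1568,1.0531,1.2707,0.05,NA,"owob"
"synth03","Q3","rr",1.286,1.1436,1.4462,NA,NA,"owob"
"synth04","Q3","rr",1.1097,1.0288,1.197,NA,NA,"weightgain"
"synth05","Q3","rr",1.0303,0.8926,1.1891,NA,NA,"weightgain"
"synth01","Q4","hr",1.0695,0.9692,1.1802,NA,TRUE,"owob"
"synth02","Q4","or",1.2226,1.1045,1.3534,0.05,NA,"owob"
"synth03","Q4","rr",1.2194,1.0667,1.3939,NA,NA,"owob"
"synth04","Q4","rr",1.2282,1.1335,1.3309,NA,NA,"weightgain"
"synth05","Q4","rr",1.1611,1.0781,1.2506,NA,NA,"weightgain"
"synth01","Q1","rr",1,1,1,NA,NA,"owob"
"synth02","Q1","rr",1,1,1,NA,NA,"owob"
"synth03","Q1","rr",1,1,1,NA,NA,"owob"
"synth04","Q1","rr",1,1,1,NA,NA,"weightgain"
"synth05","Q1","rr",1,1,1,NA,NA,"weightgain"
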