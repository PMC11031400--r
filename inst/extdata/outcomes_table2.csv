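patient_id,cohort,prev_response,current_response,prev_pfs_weeks,current_pfs_weeks,censored,treatment_dss
EV013,FPM_guided,CR,CR,60,112,TRUE,NA
EV009,FPM_guided,SD,CR,17,84,FALSE,NA
EV010,FPM_guided,CR,CR,58,61,FALSE,NA
EV002,FPM_guided,PD,CR,NA,48,FALSE,NA
EV004,FPM_guided,PD,PR,2,24,FALSE,NA
EV008,FPM_guided,PD,SD,NA,15,FALSE,NA
EV011,TPC,PD,PR,NA,28,FALSE,NA
EV021,TPC,SD,SD,45,18,FALSE,NA
EV005,TPC,CR,PD,7,NA,FALSE,NA
EV007,TPC,PD,PD,NA,NA,FALSE,NA
EV019,TPC,PD,PD,NA,NA,FALSE,NA
EV022,TPC,PD,PD,NA,NA,FALSE,NA
EV023,TPC,PD,PD,NA,NA,FALSE,NA
EV025,TPC,PD,PD,NA,NA,FALSE,NA
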