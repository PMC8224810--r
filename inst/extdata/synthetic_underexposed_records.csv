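patient_id,dose_mg,tau_h,days_on,days_off,sample_time_after_dose_h,analyte,conc_ng_ml,blq_flag,toxicity_grade2plus,clinical_benefit,empirical_new_dose_mg
1,50,24,28,14,24,parent,10,FALSE,FALSE,FALSE,50
1,50,24,28,14,24,metabolite,NA,TRUE,FALSE,FALSE,50
2,50,24,28,14,24,parent,30,FALSE,FALSE,TRUE,50
2,50,24,28,14,24,metabolite,13,FALSE,FALSE,TRUE,50
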