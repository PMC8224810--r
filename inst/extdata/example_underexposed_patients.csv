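initial_dose,trough_ng_ml,auc_ng_ml_h,model_dose,clinical_dose,clinical_benefit,early_severe_toxicity
50,13,491,100,50,FALSE,FALSE
50,43,1264,87.5,50,TRUE,FALSE
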