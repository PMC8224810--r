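initial_dose,clinical_dose,cmin_dose,auc_dose,early_severe_toxicity
50,37.5,25,25,TRUE
50,50,50,37.5,FALSE
50,50,25,25,TRUE
50,50,100,100,FALSE
62.5,50,62.5,50,TRUE
50,37.5,25,25,TRUE
50,25,50,37.5,FALSE
50,50,25,25,FALSE
50,50,25,25,TRUE
50,37.5,12.5,12.5,TRUE
62.5,62.5,50,37.5,TRUE
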