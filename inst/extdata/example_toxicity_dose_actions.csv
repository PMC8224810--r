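initial_dose,clinical_dose,cmin_dose,auc_dose
50,37.5,25,25
50,50,25,25
37.5,37.5,25,25
62.5,50,62.5,50
50,50,37.5,25
50,50,87.5,62.5
50,37.5,25,25
50,37.5,25,25
50,50,37.5,25
50,37.5,25,25
50,50,25,25
50,37.5,25,12.5
50,50,25,25
50,50,62.5,50
50,37.5,12.5,12.5
62.5,62.5,50,37.5
50,50,25,25
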