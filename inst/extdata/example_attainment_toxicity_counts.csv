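name,k,n
trough_within,14,31
trough_below,2,31
trough_above,15,31
auc_within,8,31
auc_below,1,31
auc_above,22,31
tox_trough_within,5,9
tox_trough_above,11,14
tox_auc_within,2,4
tox_auc_above,15,20
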