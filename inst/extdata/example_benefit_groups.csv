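metric,group,n,benefit_n
trough,adequate,9,7
trough,abnormal_changed,8,5
trough,abnormal_unchanged,6,1
auc,adequate,4,3
auc,abnormal_changed,11,8
auc,abnormal_unchanged,8,1
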