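perpetrator,study,observed_fold_auc
cimetidine,metformin_250mg,1.46
cimetidine,metformin_500mg,1.54
trimethoprim,metformin_500mg,1.37
trimethoprim,metformin_850mg,1.30
pyrimethamine,metformin_250mg,1.39
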