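perpetrator,study,dose_mg,mw,fu,cmax_total,igut_max
cimetidine,metformin_250mg,400,252.34,0.80,9.6,528
cimetidine,metformin_500mg,400,252.34,0.80,5.1,528
trimethoprim,metformin_500mg,200,290.32,0.56,14,230
trimethoprim,metformin_850mg,200,290.32,0.56,7.6,230
pyrimethamine,metformin_250mg,50,248.71,0.13,2.29,67
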