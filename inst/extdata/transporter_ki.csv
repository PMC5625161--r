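inhibitor,transporter,ic50_mean,ic50_sd,ki
cimetidine,OCT1,275,32.2,275
cimetidine,OCT2,207,19.6,207
cimetidine,MATE1,1.22,0.0870,1.22
cimetidine,MATE2K,3.34,1.02,3.34
trimethoprim,OCT1,27.7,3.80,27.7
trimethoprim,OCT2,137,58.0,137
trimethoprim,MATE1,2.64,0.271,2.64
trimethoprim,MATE2K,0.353,0.0584,0.353
pyrimethamine,OCT1,4.46,0.770,4.46
pyrimethamine,OCT2,4.55,1.12,4.55
pyrimethamine,MATE1,0.131,0.0401,0.131
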