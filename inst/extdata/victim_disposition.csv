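route_label,renal_fraction_of_total_clearance,active_fraction_of_renal_clearance
iv,0.88,0.75
oral,0.52,0.75
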