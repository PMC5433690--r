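quantity,value
total_patients,125
multi_compartment,59
igh_qc_failed,52
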