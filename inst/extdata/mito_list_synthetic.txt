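CS
SDHA
MT-CO1
MT-CYB
CPT1B
ACSS1
NDUFA9
UQCRC1
ATP5F1A
COX4I1
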