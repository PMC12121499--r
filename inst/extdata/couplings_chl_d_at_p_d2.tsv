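pigment_i	pigment_j	value	unit
P_D1	P_D2	180	cm-1
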