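pigment_id	value	unit
P_D1	1.943	eV
P_D2	1.943	eV
Chl_D1	1.897	eV
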