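pigment_id	vee_gas_at_gas_geom	vee_gas_at_protein_geom	vee_protein_monomer	vee_multimer	unit
chl_d	1.910	1.904	1.901	1.869	eV
chl_f	1.820	1.841	1.897	1.897	eV
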