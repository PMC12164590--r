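quantity	value	unit
psb28_fraction_of_total_protein	0.0034	percent
total_protein_per_cell	25	pg
psb28_molar_mass	12.5	kDa
psii_amount	5.2	amol_per_cell
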