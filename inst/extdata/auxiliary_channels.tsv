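# Non-antibody channels of the reference assay. The EQ four-element
# calibration beads additionally light up 151Eu/153Eu/165Ho/175Lu, which are
# antibody channels; 140Ce is the only bead-exclusive channel and is the one
# listed here to keep auxiliary channels metal-disjoint from the panel.
metal	name	role
NA	Time	time
NA	Event_length	length
191Ir	DNA1	dna
193Ir	DNA2	dna
194Pt	Cisplatin194	viability
195Pt	Cisplatin195	viability
140Ce	Bead140	bead
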