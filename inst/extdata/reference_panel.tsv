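# 33-antibody reference panel for broad immune monitoring by mass cytometry.
# metal_assigned = "printed" where the isotope is stated in the reagent table;
# "inferred" where the reagent table omits or garbles the metal and the tag
# was placed on an open lanthanide channel (CD235ab, CD61, CD3) or corrected
# from the catalog number (CD8a on 146Nd).
metal	antigen	clone	category	compartment	metal_assigned
89Y	CD45	H130	lineage	surface	printed
141Pr	CD235ab	HIR2	exclusion	surface	inferred
142Nd	CD19	HIB19	lineage	surface	printed
143Nd	CD117	104D2	lineage	surface	printed
144Nd	CD11b	ICRF44	lineage	surface	printed
145Nd	CD4	RPA-T4	lineage	surface	printed
146Nd	CD8a	RPA-T8	lineage	surface	inferred
147Sm	CD11c	BU15	lineage	surface	printed
148Nd	CD14	RMO52	lineage	surface	printed
150Nd	FceRI	AER-37	lineage	surface	printed
151Eu	CD123	6H6	lineage	surface	printed
152Sm	TCRgd	11F2	lineage	surface	printed
153Eu	CD45RA	HI100	subset	surface	printed
154Sm	Tim-3	F38-2E2	checkpoint	surface	printed
156Gd	PD-L1	29E.2A3	checkpoint	surface	printed
158Gd	CD27	L128	subset	surface	printed
160Gd	Tbet	4B10	activation	intracellular	printed
161Dy	CD152	14D3	checkpoint	surface	printed
162Dy	FoxP3	PCH101	subset	intracellular	printed
163Dy	CD33	WM53	lineage	surface	printed
164Dy	CD45RO	UCHL1	subset	surface	printed
165Ho	CD127	A019D5	subset	surface	printed
167Er	CCR7	G043H7	subset	surface	printed
168Er	Ki-67	B56	activation	intracellular	printed
169Tm	CD25	2A3	subset	surface	printed
170Er	TCRVa24-Ja18	6B11	lineage	surface	printed
171Yb	CD61	VI-PL2	exclusion	surface	inferred
172Yb	CD38	HIT2	subset	surface	printed
173Yb	CD3	UCHT1	lineage	surface	inferred
174Yb	HLA-DR	L243	lineage	surface	printed
175Lu	PD-1	EH12.2H7	checkpoint	surface	printed
176Yb	CD56	NCAM16.2	lineage	surface	printed
209Bi	CD16	3G8	lineage	surface	printed
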