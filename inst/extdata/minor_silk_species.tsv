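species	source	diameter_um	modulus_GPa	strength_MPa	extensibility	toughness_J_cm3	gpg_percent
Latrodectus hesperus	this_study	1.12	3.9	245.4	0.57	66.7	0.07
Latrodectus geometricus	this_study	1.09	2.6	174.4	0.54	43.6	3.48
Steatoda grossa	this_study	1.07	2.1	251.3	0.74	57.3	12.79
Nephila clavipes	a	2.5	3.0	346	0.30	150	0
Nephila clavipes	b	2.5	NA	960	0.25	NA	0
Nephila inaurata	c	1.8	11.2	1500	0.46	300	NA
Argiope trifasciata	d,e	0.69	8.9	751.5	0.44	150	NA
Argiope trifasciata	c	1.8	10	1040	0.45	240	NA
Argiope argentata	e	1.1	10.6	923	0.33	137	NA
Araneus diadematus	f	NA	NA	NA	0.29	NA	0
Araneus gemmoides	b	2.0	NA	1400	0.22	NA	NA
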