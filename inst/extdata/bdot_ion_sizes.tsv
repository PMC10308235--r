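species	charge	a_angstrom	provenance
H+	1	9.0	Kielland (1937) effective ion-size parameter
OH-	-1	3.5	Kielland (1937)
HCO3-	-1	4.5	Kielland (1937)
CO3-2	-2	4.5	Kielland (1937)
CH3COO-	-1	4.5	Kielland (1937), acetate
Na+	1	4.0	Kielland (1937)
K+	1	3.0	Kielland (1937)
Cl-	-1	3.5	Kielland (1937)
SO4-2	-2	4.0	Kielland (1937)
Ca+2	2	6.0	Kielland (1937)
Mg+2	2	8.0	Kielland (1937)
Mn+2	2	6.0	Kielland (1937)
NH4+	1	2.5	Kielland (1937)
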