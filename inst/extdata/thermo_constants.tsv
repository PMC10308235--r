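key	value	unit	provenance
pK1_CO2	6.13	-	first dissociation of CO2(aq) at 25 degC corrected from 6.35 (1 bar, infinite dilution) to 500 bar with deltaV = -25.4 cm3/mol (Millero 1982 lineage)
pK2_CO2	10.10	-	second dissociation at 25 degC corrected from 10.33 (1 bar) to 500 bar with deltaV = -25.6 cm3/mol
pKa_acetic	4.66	-	acetic-acid dissociation at 25 degC corrected from 4.756 (1 bar) to 500 bar with deltaV = -11.2 cm3/mol
A_gamma	0.5092	kg^0.5 mol^-0.5	Debye-Huckel A slope at 25 degC (Helgeson 1969 lineage)
B_gamma	0.3283	kg^0.5 mol^-0.5 Angstrom^-1	Debye-Huckel B denominator constant at 25 degC
bdot	0.041	kg mol^-1	extended-term (B-dot) coefficient at 25 degC (Helgeson 1969)
R_J_mol_K	8.314	J mol^-1 K^-1	universal gas constant
ratio_33S_32S_VCDT	0.0078777	-	VCDT absolute 33S/32S (Ding et al. 2001 lineage); abundance mixing results are insensitive to the absolute scale
ratio_34S_32S_VCDT	0.0441626	-	VCDT absolute 34S/32S (Ding et al. 2001 lineage)
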