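name	equation	stoichiometry	dG0_kJ_mol	provenance
hydrogenotrophic_methanogenesis	4H2(aq) + CO2(aq) = CH4(aq) + 2H2O(l)	H2:-4,CO2:-1,CH4:1,H2O:2	-193.72	Standard-state Gibbs energies of formation of the aqueous species at 25 degC from the SUPCRT-lineage compilation of Amend & Shock (2001, FEMS Microbiol. Rev. 25, 175-243): H2(aq) +17.72, CO2(aq) -385.97, CH4(aq) -34.45, H2O(l) -237.18 kJ/mol. Pressure dependence over 1-500 bar (about -3 kJ/mol) is below the provenance uncertainty and is not applied.
homoacetogenesis	4H2(aq) + 2CO2(aq) = CH3COOH(aq) + 2H2O(l)	H2:-4,CO2:-2,CH3COOH:1,H2O:2	-169.78	Same formation-energy set with CH3COOH(aq) -396.48 kJ/mol (Shock 1995 lineage). Pressure dependence over 1-500 bar (about -4 kJ/mol) is below the provenance uncertainty and is not applied.
acetate_exchange	CH4(aq) + CO2(aq) = CH3COOH(aq)	CH4:-1,CO2:-1,CH3COOH:1	23.94	Hess combination of the two reactions above (homoacetogenesis minus hydrogenotrophic methanogenesis); its reverse is acetoclastic methanogenesis.
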