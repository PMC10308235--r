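key	value	unit	provenance
Cl	560	mM	mean ocean water chloride
SO4	28	mM	standard seawater sulfate (28-29 mM); used as the conservative contamination tracer
K	10.2	mM	standard seawater potassium
Ca	10.3	mM	standard seawater calcium
Mg	53	mM	standard seawater magnesium
Mn	0	mM	open-ocean dissolved Mn is sub-micromolar; taken as 0 at mM precision
NH4	0	mM	open-ocean ammonium is sub-micromolar; taken as 0 at mM precision
dD_H2O	0	permil_VSMOW	ocean water defines the VSMOW zero point
d18O_H2O	0	permil_VSMOW	ocean water defines the VSMOW zero point
d34S_SO4	21.3	permil_VCDT	modern seawater sulfate d34S
D33S_SO4	0.050	permil_VCDT	modern seawater sulfate capital-delta-33S
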