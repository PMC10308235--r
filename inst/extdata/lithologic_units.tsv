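unit	top_mbsf	bottom_mbsf	cores	note
U1	176.5	185.2	1R	shallow slope sediment
U2	648.0	688.5	2R-3R	upper prism sediment
U3	688.5	820.1	4R-16R	terrigenous prism sediment with pyrite-like grains
U4	821.5	822.5	17R	sheared clay; plate-boundary decollement
U5	824.0	832.9	18R-20R	underthrust incoming plate sediment
U6	832.9	836.8	20R-21R	incoming plate sediment (printed jointly with the unit below it; not separable by depth)
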