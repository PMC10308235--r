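pair	a	b	c	t_min_C	t_max_C	provenance
H2-H2O	2.239190178945	-1.614732599463	0.162637258968	0	100	Quadratic in 1000/T(K) refit of the D/H equilibrium fractionation between H2(g) and liquid water after Horibe & Craig (1995, Geochim. Cosmochim. Acta 59, 5209-5217), anchored at alpha = 0.23, 0.26, 0.31 for 4, 25, 55 degC; ln(alpha) = a + b*(1000/T) + c*(1000/T)^2
CH4-H2O	1.659472749785	-1.036341330942	0.138312791535	0	100	Quadratic in 1000/T(K) refit of the product of the Horibe & Craig (1995) CH4-H2 calibration (alpha = 0.8994 + 183540/T^2) with the H2-H2O(l) curve above, anchored at 0, 25, 50 degC; ln(alpha) = a + b*(1000/T) + c*(1000/T)^2
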