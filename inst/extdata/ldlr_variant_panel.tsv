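protein_change	dna_change	role	control_class	surface_percent	internalization_percent	ratio	surface_severity	internalization_severity	ratio_severity	expression_call	prior_classification	source_surface	source_internalization	source_ratio
p.(Ala391Thr)	c.1171G>A	control	benign	100	100	2.5	NORMAL	NORMAL	NORMAL	NORMAL	B	reported	reported	estimated
p.(Thr726Ile)	c.2177C>T	control	benign	80	96	2.2	GRAY	NORMAL	NORMAL	NORMAL	B	reported	estimated	estimated
p.(Ser691Ter)	c.2072C>A	control	class1	1	18	NA	SEVERE	SEVERE	NA	TRUNCATED_ONLY	P	reported	reported	reported
p.(Ile441Thr)	c.1322T>C	control	class2a	5	25	0.05	SEVERE	SEVERE	SEVERE	NORMAL	P	estimated	estimated	estimated
p.(Gly565Val)	c.1694G>T	control	class2a	5	30	0.05	SEVERE	SEVERE	SEVERE	NORMAL	P	estimated	estimated	estimated
p.(Arg406Trp)	c.1216C>T	control	class2b	35	60	0.7	MODERATE	MODERATE	MODERATE	NORMAL	P	estimated	estimated	reported
p.(Cys155Tyr)	c.464G>A	control	class3	26	35	1.5	MODERATE	SEVERE	MODERATE	NORMAL	P	reported	estimated	estimated
p.(Asn825Lys)	c.2475C>A	control	class4	80	35	2.3	GRAY	SEVERE	NORMAL	NORMAL	P	reported	estimated	reported
p.(Arg416Trp)	c.1246C>T	control	class5	40	60	0.7	MODERATE	MODERATE	MODERATE	NORMAL	P	estimated	estimated	reported
p.(Val429Met)	c.1285G>A	control	class2b5	5	30	0.05	SEVERE	SEVERE	SEVERE	NORMAL	P	reported	estimated	reported
p.(Leu16Pro)	c.47T>C	studied	NA	3	35	NA	SEVERE	SEVERE	NA	NEARLY_ABSENT	VUS	reported	reported	reported
p.(Asp90Tyr)	c.268G>T	studied	NA	40	55	1.5	MODERATE	MODERATE	MODERATE	NORMAL	LP	estimated	estimated	estimated
p.(Glu140Asp)	c.420G>C	studied	NA	40	30	1.5	MODERATE	SEVERE	MODERATE	NORMAL	LP	estimated	reported	estimated
p.(Cys143Trp)	c.429C>G	studied	NA	40	30	1.5	MODERATE	SEVERE	MODERATE	NORMAL	LP	estimated	reported	estimated
p.(Gly149Cys)	c.445G>T	studied	NA	40	30	1.5	MODERATE	SEVERE	MODERATE	NORMAL	VUS	estimated	reported	estimated
p.(Gly219del)	c.654_656del	studied	NA	40	30	1.5	MODERATE	SEVERE	MODERATE	NORMAL	P	estimated	reported	estimated
p.(Asn272Thr)	c.815A>C	studied	NA	90	97	2.5	GRAY	NORMAL	NORMAL	NORMAL	VUS	reported	reported	reported
p.(Cys364Ser)	c.1091G>C	studied	NA	40	55	1.5	MODERATE	MODERATE	MODERATE	NORMAL	LP	estimated	estimated	estimated
p.(Gln384_Asp386del)	c.1151_1159del	studied	NA	40	55	1.5	MODERATE	MODERATE	MODERATE	NORMAL	LP	estimated	estimated	estimated
p.(Phe403del)	c.1207_1209del	studied	NA	1	30	0.05	SEVERE	SEVERE	SEVERE	NORMAL	LP	reported	reported	reported
p.(Ala431Thr)	c.1291G>A	studied	NA	40	55	1.5	MODERATE	MODERATE	MODERATE	NORMAL	P	estimated	estimated	estimated
p.(Val523Met)	c.1567G>A	studied	NA	33	67	0.13	MODERATE	MODERATE	SEVERE	NORMAL	P	reported	reported	reported
p.(Ala540Thr)	c.1618G>A	studied	NA	100	75	1.33	NORMAL	MODERATE	MODERATE	NORMAL	P	reported	reported	reported
p.(Arg574Leu)	c.1721G>T	studied	NA	95	98	2.5	NORMAL	NORMAL	NORMAL	NORMAL	VUS	reported	estimated	reported
p.(Pro608Ser)	c.1822C>T	studied	NA	40	55	1.5	MODERATE	MODERATE	MODERATE	NORMAL	LP	estimated	estimated	estimated
p.(Cys803Arg)	c.2407T>C	studied	NA	25	55	NA	MODERATE	MODERATE	NA	FAINT	LP	reported	estimated	reported
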