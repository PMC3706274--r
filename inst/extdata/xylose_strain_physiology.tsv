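# Measured physiology of six recombinant xylose-fermenting S. cerevisiae
# strains: hosts CTY and INV carrying the wild-type (WT) fungal xylose
# pathway or a promoter-optimized pathway (CTYp: optimized in the CTY host;
# INVp: optimized in the INV host).
# mu: specific growth rate (1/h); q_xylose: specific xylose uptake rate
# (mmol/gDCW/h); y_*: product yields (g/g). uncertainty: stated +/- value.
strain	metric	value	uncertainty
CTY-WT	mu	0.007	0.005
CTY-CTYp	mu	0.024	0.002
CTY-INVp	mu	0.016	0.006
INV-WT	mu	0.015	0.003
INV-CTYp	mu	0.028	0.002
INV-INVp	mu	0.031	0.006
CTY-WT	q_xylose	0.16	0.02
CTY-CTYp	q_xylose	0.60	0.02
CTY-INVp	q_xylose	0.44	0.00
INV-WT	q_xylose	0.28	0.01
INV-CTYp	q_xylose	0.43	0.05
INV-INVp	q_xylose	0.55	0.04
CTY-WT	y_xylitol	0.04	0.00
CTY-CTYp	y_xylitol	0.12	0.01
CTY-INVp	y_xylitol	0.00	0.00
INV-WT	y_xylitol	0.05	0.00
INV-CTYp	y_xylitol	0.07	0.00
INV-INVp	y_xylitol	0.02	0.01
CTY-WT	y_glycerol	0.00	0.00
CTY-CTYp	y_glycerol	0.00	0.00
CTY-INVp	y_glycerol	0.05	0.04
INV-WT	y_glycerol	0.06	0.00
INV-CTYp	y_glycerol	0.06	0.00
INV-INVp	y_glycerol	0.05	0.00
CTY-WT	y_acetate	0.00	0.00
CTY-CTYp	y_acetate	0.00	0.00
CTY-INVp	y_acetate	0.00	0.00
INV-WT	y_acetate	0.00	0.00
INV-CTYp	y_acetate	0.00	0.00
INV-INVp	y_acetate	0.02	0.00
CTY-WT	y_etoh	0.00	0.00
CTY-CTYp	y_etoh	0.25	0.01
CTY-INVp	y_etoh	0.00	0.00
INV-WT	y_etoh	0.15	0.06
INV-CTYp	y_etoh	0.21	0.01
INV-INVp	y_etoh	0.29	0.04
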