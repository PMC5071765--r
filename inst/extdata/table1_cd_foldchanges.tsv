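biological_function	description	evalue	accession	fc_24h	fc_48h	fc_96h
Stress response	universal stress protein A-like protein	1e-53	XP_011429497	17.39	4.09	24.88
Stress response	core histone macro-H2A	0.0	XP_011454400	0.19	0.39	0.33
Stress response	histone H2A isoform 2	3e-79	ACJ12611	0.22	0.39	0.53
Antioxidant defense	Cu/Zn superoxide dismutase	4e-40	AFQ32467	10.29	10.43	11.81
Antioxidant defense	glutathione S-transferase	6e-83	AGN03945	NA	1.90	3.16
Calcium-binding protein	neuronal calcium sensor (EF-hand motif)	4e-05	P36608	6.36	11.47	2.20
Calcium-binding protein	sarcoplasmic calcium-binding protein	2e-80	BAA89417	5.43	5.30	3.27
Calcium-binding protein	calmodulin	4e-18	XP_010966045	6.36	11.47	2.20
Sulfur compounds metabolism	sulfotransferase	4e-92	XP_004633325	6.39	7.40	5.06
Sulfur compounds metabolism	protein disulfide-isomerase	8e-49	ERE68284	NA	2.03	2.72
Cell structure	tenascin-X	0.24	XP_006537513	3.95	4.23	3.00
Cell structure	mucin-17-like	2e-136	XP_011425282	3.25	4.12	4.91
Cell structure	tropomyosin	3e-28	XP_011437747	3.20	4.14	3.41
Metabolic process	retinal dehydrogenase	0.0	XP_006743256	4.00	6.23	4.29
Metabolic process	isocitrate dehydrogenase	0.0	EKC40376	3.37	2.08	3.05
Metabolic process	phosphohistidine phosphatase	8e-47	XP_004848882	3.14	2.93	2.55
Metabolic process	annexin	5e-137	XP_004561320	3.07	2.96	5.47
Metabolic process	protein mab-21	9e-58	XP_004549366	3.00	4.62	3.66
Metabolic process	1,4-alpha-glucan-branching enzyme-like	0.0	XP_011434285	2.85	3.20	3.30
Metabolic process	glyceraldehyde-3-phosphate dehydrogenase	0.0	XP_010609934	2.51	2.45	3.06
Metabolic process	hemoglobin I	3e-37	AGA03854	2.45	2.23	2.21
Metabolic process	thioredoxin	6e-33	XP_002504076	2.41	4.63	3.85
Metabolic process	dipeptidase 1-like	3e-110	XP_011438699	2.31	2.38	2.51
Metabolic process	enolase-like	5e-115	XP_011436227	2.10	2.05	2.33
Metabolic process	pyruvate carboxylase	0.0	EKC30574	2.05	2.89	2.22
Metabolic process	complement C1q tumor necrosis factor-related protein	2e-14	XP_011436150	0.09	0.43	0.28
Metabolic process	collagen alpha-1	1e-08	XP_006792865	0.21	0.32	0.29
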