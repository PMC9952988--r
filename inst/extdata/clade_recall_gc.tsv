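domain	clade	median_gc	precise_match	archaeal_match	eukaryotic_match	bacterial_match
archaea	DPANN	34.05	5.07	41.11	9.76	49.12
archaea	Thaumarchaeota	34.20	25.12	37.68	5.68	56.64
archaea	Methanomicrobia	47.40	18.50	55.49	7.52	36.99
archaea	Thermoprotei	49.00	65.94	76.56	7.19	16.25
archaea	Halobacteriaceae	63.70	65.39	75.20	4.86	19.94
eukaryote	Coelomata	40.72	10.74	50.93	15.96	33.11
eukaryote	Pezizomycotina	48.90	14.80	33.42	39.63	26.95
bacteria	Lactobacillales	37.70	18.90	24.56	12.01	63.43
bacteria	Cytophagales	40.60	13.24	10.29	7.35	82.35
bacteria	Bacillaceae	42.15	11.84	36.93	11.15	51.92
bacteria	Alteromonadaceae	45.90	7.33	13.56	6.31	80.13
bacteria	Selenomonadales	48.90	14.68	28.67	9.35	61.82
bacteria	Enterobacteriaceae	52.18	18.28	18.52	6.98	74.50
bacteria	Oceanospirillales	54.40	1.52	17.81	7.47	74.72
bacteria	Chromatiales	62.15	21.06	21.62	6.50	71.88
bacteria	Rhodospirillales	65.03	29.77	14.91	7.37	77.72
bacteria	Comamonadaceae	65.38	18.29	9.84	6.71	83.46
bacteria	Xanthomonadacae	66.03	9.62	11.70	10.78	77.51
bacteria	Micrococcineae	69.65	36.26	15.36	5.32	79.32
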