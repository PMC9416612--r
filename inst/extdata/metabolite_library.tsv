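metabolite	group	shift_ppm	pattern	couplings_hz	protons	note
Lactate/lactic acid	CH3	1.31	d	6.98	3
Lactate/lactic acid	CH	4.10	q	7.0	1
Threonine	CH3	1.32	d	6.98	3	overlapped with lactate; J taken from the overlapping lactate doublet
Threonine	CH	3.56	d	5.0	1
Threonine	CH2	4.23	dd	4.9;6.6	2	overlapped with acylglycerol
Leucine	CH3	0.94	d	6.24	3
Leucine	CH3	0.95	d	6.24	3
Valine	CH3	0.97	d	7.00	3
Valine	CH3	1.03	d	7.00	3
Valine	CH	3.59	d	4.39	1
Glutamine	CH2	2.12	m		2
Glutamine	CH2	2.44	m		2
Glutamate/glutamic acid	CH2	2.04	m		1
Glutamate/glutamic acid	CH2	2.11	m		1
Citrate/citric acid	CH2	2.51	d	16.0	2	AB pair
Citrate/citric acid	CH2	2.68	d	16.0	2	AB pair
Aspartate/aspartic acid	CH2	2.66	dd	8.8;17.5	1
Aspartate/aspartic acid	CH2	2.80	dd	3.8;17.4	1
Asparagine	CH2	2.82	dd	4.2;17.0	1	ABX
Asparagine	CH2	2.93	dd	7.8;16.6	1	ABX
Alanine	CH3	1.46	d	7.26	3
3-Hydroxybutyric acid	CH3	1.19	d	6.4	3
3-Hydroxybutyric acid	CH2	2.40	dd	7.2;14.4	1
3-Hydroxybutyric acid	CH2	2.29	dd	6.4;14.4	1
Gamma-aminobutyric acid	CH2	3.04	t	7.6	2
Choline	CH2	4.05	m		2
Acylglycerols	CH2	4.10	m		1	overlapped
Acylglycerols	CH2	4.23	m		1	overlapped
Glucose	CH-4	3.40	m		1
Glucose	CH-2	3.52	dd	3.7;9.7	1
Glucose	CH-3	3.70	m		1	overlapped
Glucose	CH2-6	3.75	dd	5.1;12.0	1
Glucose	CH2-6	3.83	m		1
Glucose	CH-5	3.82	m		1
Glucose	CH-1	5.22	d	3.9	1	anomeric
Arginine	CH2	3.23	t	6.6	2
Arginine	CH2	1.70	m		1
Arginine	CH2	1.64	m		1	unused_tocsy: 4.07;4.27;5.20 repeats acylglycerol shifts
Lysine	CH2	1.91	m		2
2-Hydroxybutyric acid	CH3	0.88	t	7.50	3
2-Hydroxybutyric acid	CH2	1.70	m		1	or arginine
2-Hydroxybutyric acid	CH2	1.64	m		1	or arginine
Isoleucine	CH3	0.92	t	7.4	3
Isoleucine	CH3	0.99	d	7.0	3
Isoleucine	CH	3.65	d	4.04	1
Serin	CH2	3.97	dd	3.8;12.2	1
Serin	CH2	3.92	dd	5.7;12.2	1
Serin	CH	3.82	m		1	overlapped
Mannose	CH	3.55	t	9.4	1
Mannose	CH	3.79	m		1
Mannose	CH	3.84	dd	2.2;4.0	1
Mannose	CH	3.95	m		1
Mannose	CH	5.17	d	1.4	1
Glycine	CH2	3.54	s		2
Glycerol	CH2	3.64	m		1
Glycerol	CH2	3.55	m		1
Glycerol	CH	3.70	m		1	overlapped
Tyrosine	CH	3.96	dd	5.0;8.1	1	or phenylalanine
Tyrosine	Ar	6.88	m		2
Tyrosine	Ar	7.18	m		2
Phenylalanine	Ar	7.30	m		2
Phenylalanine	Ar	7.37	m		2
Phenylalanine	Ar	7.41	m		1
PABA	Ar	6.93	m		2	2DJ absent; TOCSY shift
PABA	Ar	7.80	m		2	2DJ absent; TOCSY shift
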