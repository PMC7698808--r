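# Published CPZ quantification: good substrates, weak substrates and products
# identified in the tryptic peptide library (4-plex TMAB design: D0=no
# enzyme, D3=1 nM, D6=10 nM, D9=100 nM CPZ). mass_check=skip marks rows whose
# transcribed theoretical mass is internally inconsistent in the original
# report (disagrees with its own ppm column) and is excluded from mass
# validation.
type	precursor	sequence	cleaved_aa	z	t	obs_m	theor_m	ppm	ratio_100nM	ratio_10nM	ratio_1nM	mass_check
good_substrate	Thyroglobulin	GQEFTITGQKR	-	2	2	1263.66	1263.60	-2	0.38	1.13	0.97	skip
weak_substrate	Thyroglobulin	ALEQATR	-	2	1	787.42	787.42	3	0.57	1.04	1.00	ok
weak_substrate	Thyroglobulin	AVKQFEESQGR	-	3	2	1277.64	1277.64	0	0.68	0.86	0.95	ok
weak_substrate	Bovine serum albumin	KVPQVSTPTLVEVSR	-	3	2	1638.93	1638.93	-2	0.70	0.90	0.95	ok
weak_substrate	Bovine serum albumin	KQTALVELLK	-	3	3	1141.69	1141.71	-22	0.73	0.80	0.89	ok
weak_substrate	Thyroglobulin	LPESK	-	2	2	572.31	572.32	-24	0.77	0.83	0.83	ok
product	Thyroglobulin	GQEFTITGQK	R	2	2	1107.56	1107.56	-4	1.52	0.78	1.04	ok
product	Thyroglobulin	LF	R	1	1	278.16	278.15	14	1.56	0.88	0.88	skip
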