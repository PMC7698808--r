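# Published CPZ quantification: good and weak substrates identified in the
# HEK293T cellular peptide library (5-plex TMAB design: D0=100 nM, D3=10 nM,
# D6=1 nM, D9=0.1 nM CPZ, D12=no enzyme). Ratios are peak intensity with
# enzyme / without enzyme; n.d. = not detected.
type	precursor	sequence	z	t	obs_m	theor_m	ppm	ratio_100nM	ratio_10nM	ratio_1nM	ratio_0.1nM
good_substrate	Histidine triad nucleotide-binding protein 1	Ac-ADEIAKAQVAR	2	1	1212.66	1212.65	14	0.02	0.94	1.08	1.00
good_substrate	Eukaryotic translation initiation factor 5A	SAMoxTEEAAVAIKAMAK	3	3	1636.81	1636.82	-5	0.07	0.15	0.95	0.95
good_substrate	Vimentin	AELEQLKGQGKSR	4	3	1442.78	1442.78	-3	0.18	1.00	1.03	0.95
good_substrate	Hematological and neurological expressed 1 protein	Ac-TTTTTFKGVDPNSRNSSR	3	1	2010.00	2009.98	13	0.31	0.89	1.24	1.07
weak_substrate	Eukaryotic translation initiation factor 5A	NMDVPNIKR	3	2	1085.56	1085.57	-6	0.45	n.d.	n.d.	0.82
weak_substrate	Ubiquitin-60S ribosomal protein L40	IIEPSLR	2	1	826.49	826.49	0	0.60	1.00	1.13	1.04
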