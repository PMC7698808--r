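# Published kinetic constants for hydrolysis of dansyl-Phe-Ala-Arg by
# B-type-specific metallocarboxypeptidases. Km in uM, kcat in 1/s,
# kcat_over_km in 1/(uM s); *_se are the reported uncertainties (NA where
# none was reported).
enzyme	km	km_se	kcat	kcat_se	kcat_over_km	kcat_over_km_se
CPZ	1905	360	5.3	0.6	0.0028	0.0008
CPZdFz	1667	385	6.2	0.8	0.0039	0.0014
CPD domain I	319	37	8.5	0.5	0.027	0.003
CPD domain II	844	139	7.0	0.9	0.008	0.001
CPE	34	NA	13	NA	0.38	NA
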