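genome_id	size_bp	cds_count	trna_count	gc_percent	integrase	family
AS7	41572	53	0	57	no	Podoviridae
51	43551	84	0	55	low_confidence	Myoviridae
56	43551	84	0	55	low_confidence	Myoviridae
59.1	46057	87	0	54	yes	Myoviridae
3	46349	83	0	57	yes	Myoviridae
Asp37	47977	83	0	57	yes	Myoviridae
32	48252	83	0	57	yes	Myoviridae
Aes508	160646	230	10	41	no	Myoviridae
25	161475	232	11	41	no	Myoviridae
AS4	163875	268	15	41	no	Myoviridae
44RR2.8t.2	173590	253	16	44	no	Myoviridae
31.2	172957	245	16	44	no	Myoviridae
SW69-9	173097	249	16	44	no	Myoviridae
L9-6	173578	251	16	44	no	Myoviridae
Riv-10	174311	249	16	44	no	Myoviridae
PX29	222006	322	24	42	no	Myoviridae
AS5	225268	333	25	43	no	Myoviridae
65.2	236567	410	18	37	no	Myoviridae
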