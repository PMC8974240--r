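qtl	trait	chr	start_bp	end_bp	peak_bp	panel	minus_log10_p	peak_effect	common_allele	alt_allele	n_common	n_alt
qSi1-1	Si	1	4482438	7015096	6965096	All	5.73	29.55	A	G	65	22
qSi3-2	Si	3	8622496	9364210	9208990	indica	5.43	-20.50	C	T	52	15
qSi10-2	Si	10	7349091	10066729	9034052	All	5.08	40.40	G	A	51	24
qSi10-3	Si	10	9900070	12000965	10773399	All	6.18	-32.86	G	A	77	16
qStHD1-3	StHD	1	22692755	24617484	23395696	All	5.57	1.75	C	G	67	11
qStHD8-2	StHD	8	5081786	9426592	6013173	All	6.59	1.49	C	T	59	19
qStHD9-1	StHD	9	1520138	5186402	2993757	All	6.35	2.88	A	G	41	34
qAs1-1	As	1	13461779	13617444	13533400	All	5.56	-0.26	C	T	60	46
qAs1-2	As	1	21981983	24449843	23757196	All	5.17	-0.11	G	T	71	39
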